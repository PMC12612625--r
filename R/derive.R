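#' Derive leaf traits from raw leaf measurements
#'
#' Computes the six leaf traits from per-leaf raw measurements. Ratios are
#' computed per individual leaf; average replicate leaves to the tree level
#' afterwards (ratio-of-means is deliberately not used).
#'
#' Unit conventions: `LMA = LDM / LA` converted from g cm^-2 to g m^-2
#' (factor 1e4); `LDMC = LDM / LFM` converted from g g^-1 to mg g^-1
#' (factor 1e3); `LT` is the unweighted mean of the four lamina readings.
#'
#' @param lfm Fully hydrated leaf fresh mass, g (petiole removed).
#' @param ldm Leaf dry mass, g.
#' @param la Leaf area, cm^2.
#' @param ll,lw Leaf length and width, cm.
#' @param lt_readings Leaf thickness readings, um: a vector of 4 (one leaf)
#'   or a matrix with one row per leaf and 4 columns.
#' @return Data frame with columns `LA`, `LW`, `LL_LW`, `LMA`, `LDMC`, `LT`.
#' @export
derive_leaf_traits <- function(lfm, ldm, la, ll, lw, lt_readings) {
  if (is.vector(lt_readings)) lt_readings <- matrix(lt_readings, nrow = 1L)
  stopifnot(ncol(lt_readings) == 4L)
  check_positive(c(lfm, ldm, la, ll, lw, lt_readings), "leaf measurement")
  if (any(ldm > lfm)) stop("leaf dry mass exceeds fresh mass")
  data.frame(
    LA = la,
    LW = lw,
    LL_LW = ll / lw,
    LMA = ldm / la * 1e4,
    LDMC = ldm / lfm * 1e3,
    LT = rowMeans(lt_readings)
  )
}

#' Derive stem traits from raw twig measurements
#'
#' Sapwood cross-sectional area is taken as the ellipse through the two
#' perpendicular bark-removed diameters, `A_S = pi/4 * d1 * d2` (mm^2,
#' converted to cm^2); `AS_AL = A_S / A_L` in cm^2 m^-2; specific stem
#' length `SSL = length / dry mass` in cm g^-1.
#'
#' @param d1,d2 Perpendicular bark-removed twig diameters, mm.
#' @param al Twig leaf area, m^2.
#' @param length Twig length, cm.
#' @param dry_mass Twig dry mass, g.
#' @return Data frame with columns `SSL` and `AS_AL`.
#' @export
derive_stem_traits <- function(d1, d2, al, length, dry_mass) {
  check_positive(c(d1, d2, al, length, dry_mass), "twig measurement")
  as_cm2 <- (pi / 4) * d1 * d2 / 100  # mm^2 -> cm^2
  data.frame(
    SSL = length / dry_mass,
    AS_AL = as_cm2 / al
  )
}

#' Derive branch traits from raw branch measurements
#'
#' Relative bark thickness is twice the mean of the four bark-thickness
#' readings divided by the mean of the two perpendicular branch diameters
#' (mm mm^-1, dimensionless). Branch wood density, measured upstream by
#' densitometry, is passed through unchanged.
#'
#' @param bark_readings Bark thickness readings, mm: vector of 4 or matrix
#'   with 4 columns, one row per branch.
#' @param diam_readings Branch diameters, mm: vector of 2 or matrix with 2
#'   columns.
#' @param bwd Branch wood density, g cm^-3.
#' @return Data frame with columns `RBT` and `BWD`.
#' @export
derive_branch_traits <- function(bark_readings, diam_readings, bwd) {
  if (is.vector(bark_readings)) bark_readings <- matrix(bark_readings, nrow = 1L)
  if (is.vector(diam_readings)) diam_readings <- matrix(diam_readings, nrow = 1L)
  stopifnot(ncol(bark_readings) == 4L, ncol(diam_readings) == 2L)
  if (any(bark_readings < 0) || any(diam_readings <= 0) || any(bwd <= 0)) {
    stop("branch measurements must be positive (bark thickness may be zero)")
  }
  bark <- rowMeans(bark_readings)
  diam <- rowMeans(diam_readings)
  if (any(bark >= diam / 2)) {
    stop("mean bark thickness must be less than half the mean branch diameter")
  }
  data.frame(
    RBT = 2 * bark / diam,
    BWD = bwd
  )
}

check_positive <- function(x, what) {
  if (any(is.na(x)) || any(x <= 0)) {
    stop(what, " values must be strictly positive and non-missing")
  }
  invisible(TRUE)
}
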