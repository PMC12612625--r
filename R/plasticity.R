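#' Standardize traits over the pooled common-variety trees
#'
#' Per trait, `z = (x - mean) / sd`, with mean and sample SD computed over
#' all trees of the supplied table pooled across both sites. The
#' standardization parameters are returned for provenance so downstream
#' indices can record the space they were computed in.
#'
#' @param table A `trait_table` (normally the common-variety subset
#'   spanning both sites).
#' @return List: `table` (standardized `trait_table`-shaped data frame;
#'   values may be negative so it is returned unclassed), `center`, `scale`
#'   (named per-trait vectors).
#' @export
standardize_traits <- function(table) {
  stopifnot(inherits(table, "trait_table"))
  traits <- attr(table, "trait_names")
  out <- as.data.frame(table)
  center <- scale_ <- stats::setNames(numeric(length(traits)), traits)
  for (tr in traits) {
    v <- out[[tr]]
    center[tr] <- mean(v, na.rm = TRUE)
    scale_[tr] <- stats::sd(v, na.rm = TRUE)
    if (is.na(scale_[tr]) || scale_[tr] == 0) {
      stop("trait '", tr, "' has zero variance; cannot standardize")
    }
    out[[tr]] <- (v - center[tr]) / scale_[tr]
  }
  attr(out, "trait_names") <- traits
  attr(out, "design") <- attr(table, "design")
  list(table = out, center = center, scale = scale_)
}

#' Phenotypic dissimilarity index for one variety and one trait
#'
#' Quantifies how dissimilar the trees of a single (clonal) variety are
#' between two sites, discounted by the trait's variability among trees
#' within each site. With `B` the mean over all cross-site tree pairs of
#' the absolute difference in (standardized) trait value, and `W` the mean
#' absolute pairwise difference pooled over within-site pairs of both sites
#' (0 when neither site has two trees), the default index is
#' `PhD = max(0, (B - W) / B)`, and 0 when `B = 0`. It ranges from 0 (no
#' plasticity: cross-site differences no larger than within-site noise) to
#' 1 (maximum plasticity: sites fully separated with no within-site
#' spread).
#'
#' Variants: `"overlap"` is the complement of the relative overlap of the
#' two sites' value ranges (1 - intersection length / union length);
#' `"rdpi"` is the relative distance plasticity index, the mean over
#' cross-site pairs of `|x_i - x_j| / (x_i + x_j)`, defined for positive
#' raw trait values only.
#'
#' @param xA,xB Trait values of the variety's trees at site A and site B
#'   (standardized values for the default and overlap variants, raw
#'   positive values for `rdpi`); at least one tree per site.
#' @param variant `"bw"` (default between/within form), `"overlap"` or
#'   `"rdpi"`.
#' @return A value in `[0, 1]`.
#' @export
phd_index <- function(xA, xB, variant = c("bw", "overlap", "rdpi")) {
  variant <- match.arg(variant)
  xA <- xA[!is.na(xA)]
  xB <- xB[!is.na(xB)]
  if (length(xA) < 1L || length(xB) < 1L) {
    stop("each site needs at least one tree")
  }
  if (variant == "bw") {
    B <- mean(abs(outer(xA, xB, "-")))
    within <- c(if (length(xA) >= 2L) abs(utils::combn(xA, 2L, diff)),
                if (length(xB) >= 2L) abs(utils::combn(xB, 2L, diff)))
    W <- if (length(within) > 0L) mean(within) else 0
    if (B == 0) return(0)
    return(max(0, (B - W) / B))
  }
  if (variant == "overlap") {
    rA <- range(xA)
    rB <- range(xB)
    union_len <- max(rA[2L], rB[2L]) - min(rA[1L], rB[1L])
    if (union_len == 0) return(0)  # all values identical
    inter_len <- max(0, min(rA[2L], rB[2L]) - max(rA[1L], rB[1L]))
    return(1 - inter_len / union_len)
  }
  # rdpi
  if (any(xA <= 0) || any(xB <= 0)) {
    stop("rdpi variant requires strictly positive raw trait values")
  }
  s <- outer(xA, xB, "+")
  d <- abs(outer(xA, xB, "-"))
  mean(d / s)
}

#' Variety x trait matrix of phenotypic dissimilarity indices
#'
#' Applies [phd_index()] to every common variety and trait. For the `bw`
#' and `overlap` variants the table is first standardized per trait over
#' the pooled common-variety trees of both sites ([standardize_traits()]);
#' the `rdpi` variant uses raw values. Entries are `NA` where a site has no
#' non-missing tree for that variety and trait.
#'
#' @param table A `trait_table` containing both sites; internally
#'   restricted to the common varieties.
#' @param variant Index variant, see [phd_index()].
#' @return Numeric matrix (varieties x traits) with attributes `variant`
#'   and `standardization` (center/scale provenance, `NULL` for rdpi).
#' @export
phd_matrix <- function(table, variant = c("bw", "overlap", "rdpi")) {
  variant <- match.arg(variant)
  stopifnot(inherits(table, "trait_table"))
  common <- subset_trait_table(table, "common")
  d <- attr(common, "design")
  if (length(d$sites) != 2L) stop("exactly two sites are required")
  prov <- NULL
  dat <- if (variant == "rdpi") {
    as.data.frame(common)
  } else {
    std <- standardize_traits(common)
    prov <- std[c("center", "scale")]
    std$table
  }
  traits <- attr(common, "trait_names")
  varieties <- d$common
  m <- matrix(NA_real_, length(varieties), length(traits),
              dimnames = list(varieties, traits))
  for (v in varieties) {
    at_A <- dat$variety == v & dat$site == d$sites[1L]
    at_B <- dat$variety == v & dat$site == d$sites[2L]
    for (tr in traits) {
      xA <- dat[[tr]][at_A]
      xB <- dat[[tr]][at_B]
      xA <- xA[!is.na(xA)]
      xB <- xB[!is.na(xB)]
      if (length(xA) >= 1L && length(xB) >= 1L) {
        m[v, tr] <- phd_index(xA, xB, variant)
      }
    }
  }
  structure(m, variant = variant, standardization = prov)
}

#' Rank traits by mean phenotypic dissimilarity
#'
#' Mean PhD per trait over varieties, a one-way ANOVA with trait as factor
#' on the variety-level PhD values, a Tukey HSD post-hoc test, and a
#' compact letter display. Output is ordered by descending mean PhD.
#'
#' @param phd A matrix from [phd_matrix()].
#' @param alpha Significance level for the post-hoc letters.
#' @return Data frame (`trait`, `mean_phd`, `n`, `letters`) ordered by
#'   descending `mean_phd`, with attributes `anova` and `tukey`.
#' @export
rank_traits_by_phd <- function(phd, alpha = 0.05) {
  stopifnot(is.matrix(phd), ncol(phd) >= 2L, nrow(phd) >= 2L)
  long <- data.frame(
    trait = rep(colnames(phd), each = nrow(phd)),
    value = as.vector(phd),
    stringsAsFactors = FALSE
  )
  long <- long[!is.na(long$value), , drop = FALSE]
  an <- oneway_anova(long$value, long$trait)
  tk <- tukey_hsd(long$value, long$trait, alpha = alpha)
  cld <- compact_letter_display(tk)
  means <- sort(colMeans(phd, na.rm = TRUE), decreasing = TRUE)
  out <- data.frame(
    trait = names(means),
    mean_phd = unname(means),
    n = unname(colSums(!is.na(phd))[names(means)]),
    letters = unname(cld[names(means)]),
    stringsAsFactors = FALSE
  )
  structure(out, anova = an, tukey = tk)
}

#' Multivariate plasticity index
#'
#' For each common variety, the mean Euclidean distance between its trees
#' at the two sites, measured in the space of the first `n_components`
#' principal components of a single PCA fitted on the pooled standardized
#' tree x trait matrix (both sites together; correlation-matrix PCA,
#' unscaled scores). Trees missing any trait are dropped with a warning
#' (complete-case for this index only).
#'
#' @param table A `trait_table` containing both sites; internally
#'   restricted to the common varieties.
#' @param n_components Number of leading components to project on
#'   (default 3; must not exceed the number of traits).
#' @return Named numeric vector of MVPi per variety, with attribute
#'   `provenance` (standardization parameters, PCA rotation and sdev,
#'   number of components).
#' @export
mvpi <- function(table, n_components = 3L) {
  stopifnot(inherits(table, "trait_table"))
  common <- subset_trait_table(table, "common")
  d <- attr(common, "design")
  if (length(d$sites) != 2L) stop("exactly two sites are required")
  traits <- attr(common, "trait_names")
  if (n_components > length(traits)) {
    stop("n_components exceeds the number of traits")
  }
  cc <- stats::complete.cases(as.data.frame(common)[, traits, drop = FALSE])
  if (any(!cc)) {
    warning(sum(!cc), " tree(s) with missing traits dropped for MVPi")
  }
  dat <- as.data.frame(common)[cc, , drop = FALSE]
  std <- standardize_traits(
    trait_table(dat, traits, validate = FALSE)
  )
  z <- as.matrix(std$table[, traits, drop = FALSE])
  pc <- stats::prcomp(z, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  out <- stats::setNames(rep(NA_real_, length(d$common)), d$common)
  for (v in d$common) {
    iA <- which(dat$variety == v & dat$site == d$sites[1L])
    iB <- which(dat$variety == v & dat$site == d$sites[2L])
    if (length(iA) < 1L || length(iB) < 1L) next
    dist_sum <- 0
    for (i in iA) for (j in iB) {
      dist_sum <- dist_sum + sqrt(sum((scores[i, ] - scores[j, ])^2))
    }
    out[v] <- dist_sum / (length(iA) * length(iB))
  }
  attr(out, "provenance") <- list(
    center = std$center, scale = std$scale,
    rotation = pc$rotation, sdev = pc$sdev,
    n_components = n_components, pooled_sites = d$sites
  )
  out
}
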