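#' De Martonne aridity index
#'
#' `I = (MAP + irrigation) / (MAT + 10)` where MAP is mean annual
#' precipitation (mm), irrigation any supplementary water supply (mm), and
#' MAT mean annual temperature (degrees C). Supplementary irrigation is
#' counted as water supply so that managed plantations are classified by
#' the water the trees actually receive. Lower values are more arid.
#'
#' @param mat Mean annual temperature, degrees C; must exceed -10.
#' @param map Mean annual precipitation, mm (>= 0).
#' @param irrigation Supplementary water supply, mm (>= 0, default 0).
#' @return The aridity index (full precision; round for display).
#' @export
de_martonne <- function(mat, map, irrigation = 0) {
  if (any(mat <= -10)) stop("De Martonne index undefined for MAT <= -10")
  if (any(map < 0) || any(irrigation < 0)) {
    stop("precipitation and irrigation must be nonnegative")
  }
  (map + irrigation) / (mat + 10)
}

#' Classify a De Martonne aridity index
#'
#' Standard class boundaries: arid below 10, semi-arid from 10 to below
#' 20, subhumid from 20 up to and including 30, humid above 30 (the humid
#' class is open at 30).
#'
#' @param index Nonnegative aridity index (vectorized).
#' @return Character vector: `"Arid"`, `"Semi-arid"`, `"Subhumid"` or
#'   `"Humid"`.
#' @export
classify_aridity <- function(index) {
  if (any(index < 0)) stop("aridity index must be nonnegative")
  ifelse(index < 10, "Arid",
         ifelse(index < 20, "Semi-arid",
                ifelse(index <= 30, "Subhumid", "Humid")))
}
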