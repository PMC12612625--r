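#' Per-site correlation-matrix PCA of tree-level traits
#'
#' Eigendecomposition of the correlation matrix of the site's complete-case
#' tree x trait data. Components are ordered by descending eigenvalue with
#' a deterministic sign convention: within each component, the trait with
#' the largest absolute loading loads positive. Loadings are reported both
#' as raw eigenvectors and as trait-component correlations (eigenvectors
#' scaled by the square root of the eigenvalue).
#'
#' @param table A `trait_table`.
#' @param site Site label to analyse.
#' @return Object of class `ordination`: `site`, `traits`, `eigenvalues`,
#'   `var_pct` (percent variance per component, summing to 100),
#'   `eigenvectors`, `loadings` (scaled), `scores` (tree-level, unscaled
#'   `z %*% V`), `tree_info` (site/variety/tree of each score row),
#'   `rotation` (`NULL` until [varimax_rotate()]), `fast_slow` (`NULL`
#'   until [identify_fast_slow_axis()]).
#' @export
pca_site <- function(table, site) {
  stopifnot(inherits(table, "trait_table"))
  site <- normalize_label(site)
  d <- attr(table, "design")
  if (!site %in% d$sites) stop("unknown site label: ", site)
  traits <- attr(table, "trait_names")
  dat <- as.data.frame(table)[table$site == site, , drop = FALSE]
  cc <- stats::complete.cases(dat[, traits, drop = FALSE])
  dat <- dat[cc, , drop = FALSE]
  if (nrow(dat) < length(traits) + 1L) {
    stop("need at least n_traits + 1 complete-case trees")
  }
  X <- as.matrix(dat[, traits, drop = FALSE])
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("constant trait at site ", site, ": ",
         paste(traits[sds == 0], collapse = ", "))
  }
  Z <- scale(X, center = TRUE, scale = TRUE)
  C <- stats::cor(X)
  eig <- eigen(C, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  V <- eig$vectors
  # sign convention: dominant trait of each component loads positive
  for (j in seq_len(ncol(V))) {
    i_star <- which.max(abs(V[, j]))
    if (V[i_star, j] < 0) V[, j] <- -V[, j]
  }
  dimnames(V) <- list(traits, paste0("PC", seq_along(lambda)))
  scores <- Z %*% V
  structure(list(
    site = site,
    traits = traits,
    eigenvalues = lambda,
    var_pct = 100 * lambda / sum(lambda),
    eigenvectors = V,
    loadings = V %*% diag(sqrt(lambda), length(lambda)),
    scores = scores,
    tree_info = dat[, c("site", "variety", "tree"), drop = FALSE],
    rotation = NULL,
    fast_slow = NULL
  ), class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat("ordination (correlation PCA), site ", x$site, ": ",
      nrow(x$scores), " trees x ", length(x$traits), " traits\n", sep = "")
  k <- min(3L, length(x$eigenvalues))
  cat("  first ", k, " components: ",
      paste(sprintf("%.1f%%", x$var_pct[seq_len(k)]), collapse = " + "),
      " = ", sprintf("%.1f%%", sum(x$var_pct[seq_len(k)])), "\n", sep = "")
  if (!is.null(x$rotation)) {
    cat("  varimax-rotated components: ", x$rotation$k, "\n", sep = "")
  }
  if (!is.null(x$fast_slow)) {
    cat("  fast-slow axis: rotated component ", x$fast_slow$component,
        " (LMA loads positive; higher score = slower/more conservative)\n",
        sep = "")
  }
  invisible(x)
}

#' Varimax rotation of the leading components
#'
#' Orthogonal varimax rotation with Kaiser (row) normalization applied to
#' the first `k` columns of the scaled loadings. Rotated components are
#' re-ordered by descending explained variance (column sum of squared
#' rotated loadings) and re-signed so the dominant trait loads positive.
#' Scores are re-derived with the same orthogonal rotation, so tree
#' configurations (distances in the k-dimensional space) are unchanged and
#' communalities (row sums of squared loadings) are preserved exactly.
#'
#' @param result An `ordination` from [pca_site()].
#' @param k Number of leading components to rotate (default 3).
#' @param eps Convergence tolerance on the relative improvement of the
#'   varimax criterion.
#' @return The `ordination` with a `rotation` element: `k`, `loadings`
#'   (rotated, scaled), `rotmat`, `var_pct`, `scores` (rotated tree
#'   scores).
#' @export
varimax_rotate <- function(result, k = 3L, eps = 1e-8) {
  stopifnot(inherits(result, "ordination"))
  if (k > length(result$eigenvalues)) stop("k exceeds number of components")
  if (k < 2L) stop("rotation needs at least two components")
  L <- result$loadings[, seq_len(k), drop = FALSE]
  vr <- stats::varimax(L, normalize = TRUE, eps = eps)
  R <- vr$rotmat
  Lr <- L %*% R
  Sr <- result$scores[, seq_len(k), drop = FALSE] %*% R
  # order rotated components by explained variance, then fix signs
  expl <- colSums(Lr^2)
  ord <- order(expl, decreasing = TRUE)
  Lr <- Lr[, ord, drop = FALSE]
  Sr <- Sr[, ord, drop = FALSE]
  R <- R[, ord, drop = FALSE]
  expl <- expl[ord]
  for (j in seq_len(k)) {
    i_star <- which.max(abs(Lr[, j]))
    if (Lr[i_star, j] < 0) {
      Lr[, j] <- -Lr[, j]
      Sr[, j] <- -Sr[, j]
      R[, j] <- -R[, j]
    }
  }
  dimnames(Lr) <- list(result$traits, paste0("RC", seq_len(k)))
  colnames(Sr) <- paste0("RC", seq_len(k))
  result$rotation <- list(
    k = k,
    loadings = Lr,
    rotmat = R,
    var_pct = 100 * expl / sum(result$eigenvalues),
    scores = Sr
  )
  result
}

#' Identify the fast-slow strategy axis
#'
#' Among the first (up to) three rotated components, selects the one
#' maximizing `|loading(LMA)| + |loading(LDMC)|` — the leaf-economics
#' traits that define the acquisitive-conservative continuum — and orients
#' it so LMA loads positive: higher scores mean denser, more conservative
#' ("slow") phenotypes. Ties are reported and resolved in favour of the
#' first component.
#'
#' @param result A rotated `ordination` (see [varimax_rotate()]).
#' @param traits Pair of trait names defining the axis (default LMA, LDMC).
#' @return The `ordination` with a `fast_slow` element: `component`
#'   (index into the rotated components), `sign` (+1/-1 applied), and
#'   `scores` (oriented tree scores on the axis).
#' @export
identify_fast_slow_axis <- function(result, traits = c("LMA", "LDMC")) {
  stopifnot(inherits(result, "ordination"))
  if (is.null(result$rotation)) stop("run varimax_rotate() first")
  L <- result$rotation$loadings
  if (!all(traits %in% rownames(L))) {
    stop("traits ", paste(traits, collapse = ", "), " must be present")
  }
  k <- min(3L, ncol(L))
  crit <- colSums(abs(L[traits, seq_len(k), drop = FALSE]))
  best <- which(crit == max(crit))
  if (length(best) > 1L) {
    warning("tie in fast-slow axis selection; keeping component ", best[1L])
  }
  j <- best[1L]
  sgn <- if (L[traits[1L], j] < 0) -1 else 1
  result$fast_slow <- list(
    component = unname(j),
    sign = sgn,
    criterion = crit,
    scores = sgn * result$rotation$scores[, j]
  )
  result
}

#' Variety mean scores on the fast-slow axis
#'
#' @param result An `ordination` with an identified fast-slow axis.
#' @return Data frame: `site`, `variety`, `n_trees`, `score` (mean of the
#'   oriented tree projections; higher = slower/more conservative).
#' @export
fast_slow_scores <- function(result) {
  stopifnot(inherits(result, "ordination"))
  if (is.null(result$fast_slow)) stop("run identify_fast_slow_axis() first")
  sc <- result$fast_slow$scores
  vt <- result$tree_info$variety
  agg <- tapply(sc, vt, mean)
  n <- tapply(sc, vt, length)
  out <- data.frame(
    site = result$site,
    variety = names(agg),
    n_trees = as.integer(n),
    score = as.numeric(agg),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out[order(out$variety), , drop = FALSE]
}

#' Plasticity vs resource-use strategy correlations
#'
#' For each site, Pearson correlations (with two-sided p and Fisher-z
#' confidence intervals) between variety fast-slow scores and (a) the PhD
#' index of each trait and (b) the MVPi. No multiple-testing correction is
#' applied by default; Holm adjustment across each site's tests is
#' available.
#'
#' @param scores Data frame as from [fast_slow_scores()], possibly
#'   row-bound over sites (columns `site`, `variety`, `score`).
#' @param phd Variety x trait matrix from [phd_matrix()].
#' @param mvpi_values Named vector from [mvpi()], or `NULL` to skip.
#' @param conf_level Confidence level for the intervals.
#' @param adjust `"none"` (default) or `"holm"`.
#' @return Data frame: `site`, `variable` (trait name or `"MVPi"`), `n`,
#'   `r`, `p.value`, `conf_low`, `conf_high`, `significant` (at 0.05 on
#'   the, possibly adjusted, p).
#' @export
plasticity_strategy_correlations <- function(scores, phd, mvpi_values = NULL,
                                             conf_level = 0.95,
                                             adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  stopifnot(all(c("site", "variety", "score") %in% names(scores)))
  out <- list()
  for (s in sort(unique(scores$site))) {
    sc <- scores[scores$site == s, , drop = FALSE]
    targets <- c(stats::setNames(lapply(colnames(phd), function(tr) {
      stats::setNames(phd[, tr], rownames(phd))
    }), colnames(phd)),
    if (!is.null(mvpi_values)) list(MVPi = mvpi_values))
    rows <- do.call(rbind, lapply(names(targets), function(nm) {
      y <- targets[[nm]]
      common_v <- intersect(sc$variety, names(y)[!is.na(y)])
      if (length(common_v) < 3L) {
        stop("fewer than 3 overlapping varieties for ", nm, " at site ", s)
      }
      ct <- pearson_correlation(sc$score[match(common_v, sc$variety)],
                                y[common_v], conf_level = conf_level)
      data.frame(site = s, variable = nm, n = ct$n, r = ct$r,
                 p.value = ct$p.value, conf_low = ct$conf.int[1L],
                 conf_high = ct$conf.int[2L], stringsAsFactors = FALSE)
    }))
    if (adjust == "holm") {
      rows$p.value <- stats::p.adjust(rows$p.value, method = "holm")
    }
    out[[s]] <- rows
  }
  out <- do.call(rbind, out)
  out$significant <- out$p.value < 0.05
  rownames(out) <- NULL
  out
}
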