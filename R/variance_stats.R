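#' Coefficient of variation
#'
#' `100 * sd(x) / mean(x)` with the sample (n-1) standard deviation.
#'
#' @param x Numeric vector, `n >= 2`; missing values dropped.
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) stop("coefficient of variation requires n >= 2")
  m <- mean(x)
  if (m == 0) stop("coefficient of variation undefined for zero mean")
  100 * stats::sd(x) / m
}

# p-value floor to avoid log/report underflow
P_FLOOR <- 1e-300

#' One-way analysis of variance
#'
#' Between/within sums-of-squares decomposition computed directly from group
#' means; F from the ratio of mean squares, p from the F distribution.
#'
#' @param values Numeric response vector (missing values dropped pairwise
#'   with their group labels).
#' @param groups Group labels, same length as `values`.
#' @return An object of class `anova_table`: a data frame with rows for the
#'   factor and residuals (`df`, `sumsq`, `meansq`, `statistic`, `p.value`)
#'   and attributes `total_ss`, `group_means`, `group_n`.
#' @export
oneway_anova <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  keep <- !is.na(values) & !is.na(groups)
  y <- values[keep]
  g <- factor(groups[keep])
  k <- nlevels(g)
  n <- length(y)
  if (k < 2L) stop("one-way ANOVA requires at least two groups")
  if (n - k < 1L) stop("no residual degrees of freedom")
  gm <- tapply(y, g, mean)
  gn <- tapply(y, g, length)
  grand <- mean(y)
  ssb <- sum(gn * (gm - grand)^2)
  sst <- sum((y - grand)^2)
  ssw <- sst - ssb
  df1 <- k - 1L
  df2 <- n - k
  msb <- ssb / df1
  msw <- ssw / df2
  f <- if (msw > 0) msb / msw else if (msb == 0) 0 else Inf
  p <- max(stats::pf(f, df1, df2, lower.tail = FALSE), P_FLOOR)
  out <- data.frame(
    term = c("group", "Residuals"),
    df = c(df1, df2),
    sumsq = c(ssb, ssw),
    meansq = c(msb, msw),
    statistic = c(f, NA_real_),
    p.value = c(p, NA_real_),
    stringsAsFactors = FALSE
  )
  structure(out, total_ss = sst,
            group_means = gm, group_n = gn,
            class = c("anova_table", "data.frame"))
}

# residual sum of squares of the least-squares fit of y on X
rss_fit <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

#' Two-way site x variety ANOVA (Type II sums of squares)
#'
#' Fits the crossed site x variety model to tree-level values of one trait
#' for the common varieties. Sums of squares are Type II, obtained by
#' least-squares model comparison: each main effect is tested against the
#' model containing the other main effect, the interaction against the
#' additive model. With balanced tree counts Type II coincides with
#' sequential SS; tree counts of 2-3 make the design mildly unbalanced.
#'
#' @param table A `trait_table` restricted to varieties present at both
#'   sites (see [subset_trait_table()]).
#' @param trait Trait name.
#' @return An `anova_table` with rows site, variety, site:variety and
#'   residuals.
#' @export
twoway_anova_site_variety <- function(table, trait) {
  stopifnot(inherits(table, "trait_table"))
  if (!trait %in% attr(table, "trait_names")) stop("unknown trait: ", trait)
  keep <- !is.na(table[[trait]])
  y <- table[[trait]][keep]
  site <- factor(table$site[keep])
  variety <- factor(table$variety[keep])
  if (nlevels(site) != 2L) stop("exactly two sites are required")
  occ <- table(variety, site)
  bad <- rownames(occ)[apply(occ == 0L, 1L, any)]
  if (length(bad) > 0L) {
    stop("variety missing at one site: ", paste(bad, collapse = ", "))
  }
  n <- length(y)
  v <- nlevels(variety)
  X_s <- stats::model.matrix(~site)
  X_v <- stats::model.matrix(~variety)
  X_sv <- stats::model.matrix(~ site + variety)
  X_full <- stats::model.matrix(~ site * variety)
  ss_site <- rss_fit(X_v, y) - rss_fit(X_sv, y)
  ss_var <- rss_fit(X_s, y) - rss_fit(X_sv, y)
  ss_int <- rss_fit(X_sv, y) - rss_fit(X_full, y)
  ss_res <- rss_fit(X_full, y)
  df <- c(1L, v - 1L, v - 1L, n - 2L * v)
  if (df[4L] < 1L) stop("no residual degrees of freedom")
  ss <- c(ss_site, ss_var, ss_int, ss_res)
  ms <- ss / df
  f <- c(ms[1:3] / ms[4L], NA_real_)
  p <- c(pmax(stats::pf(f[1:3], df[1:3], df[4L], lower.tail = FALSE), P_FLOOR),
         NA_real_)
  out <- data.frame(
    term = c("site", "variety", "site:variety", "Residuals"),
    df = df, sumsq = ss, meansq = ms,
    statistic = f, p.value = p,
    stringsAsFactors = FALSE
  )
  structure(out, total_ss = sum((y - mean(y))^2),
            class = c("anova_table", "data.frame"))
}

#' Partition trait variance into genetic, plastic and residual shares
#'
#' Percentage contributions computed from the sums of squares of one-way
#' ANOVAs on tree-level values: the genetic share is the between-variety SS
#' over total SS with variety as factor across both sites and all
#' varieties; the plastic share is the between-site SS over total SS with
#' site as factor across the common varieties only; the residual share is
#' the within-variety SS over total SS of the variety ANOVA. The three
#' shares come from two different models and therefore carry their own
#' denominators and are not forced to sum to 100.
#'
#' @param all_table `trait_table` with every variety at both sites.
#' @param common_table `trait_table` restricted to the common varieties.
#' @param trait Trait name.
#' @return List of class `variance_partition`: `genetic_pct`,
#'   `plasticity_pct`, `residual_pct`, and the parent `anova_variety` and
#'   `anova_site` tables.
#' @export
variance_components <- function(all_table, common_table, trait) {
  for (tab in list(all_table, common_table)) {
    if (!trait %in% attr(tab, "trait_names")) stop("unknown trait: ", trait)
  }
  a_var <- oneway_anova(all_table[[trait]], all_table$variety)
  a_site <- oneway_anova(common_table[[trait]], common_table$site)
  structure(list(
    trait = trait,
    genetic_pct = 100 * a_var$sumsq[1L] / attr(a_var, "total_ss"),
    plasticity_pct = 100 * a_site$sumsq[1L] / attr(a_site, "total_ss"),
    residual_pct = 100 * a_var$sumsq[2L] / attr(a_var, "total_ss"),
    anova_variety = a_var,
    anova_site = a_site
  ), class = "variance_partition")
}

#' @export
print.variance_partition <- function(x, ...) {
  cat(sprintf("%s: genetic %.2f%% | plasticity %.2f%% | residual %.2f%%\n",
              x$trait, x$genetic_pct, x$plasticity_pct, x$residual_pct))
  cat("  (genetic & residual: variety one-way ANOVA; plasticity: site",
      "one-way ANOVA on common varieties)\n")
  invisible(x)
}

#' Tukey HSD all-pairs comparisons
#'
#' All pairwise group-mean comparisons after a one-way ANOVA, with
#' family-wise adjusted p-values from the studentized range distribution
#' and Tukey-Kramer standard errors for unequal group sizes.
#'
#' @param values Numeric response.
#' @param groups Group labels.
#' @param alpha Family-wise significance level for the `significant` flag.
#' @return Data frame of class `tukey_hsd`: `group1`, `group2`, `diff`
#'   (mean of group2 minus group1), `se`, `q`, `p.adj`, `significant`;
#'   attributes `group_means`, `df_resid`, `alpha`.
#' @export
tukey_hsd <- function(values, groups, alpha = 0.05) {
  an <- oneway_anova(values, groups)
  gm <- attr(an, "group_means")
  gn <- attr(an, "group_n")
  k <- length(gm)
  mse <- an$meansq[2L]
  df2 <- an$df[2L]
  if (mse <= 0) stop("zero residual variance; Tukey HSD undefined")
  pairs <- utils::combn(names(gm), 2L)
  diff <- gm[pairs[2L, ]] - gm[pairs[1L, ]]
  se <- sqrt((mse / 2) * (1 / gn[pairs[1L, ]] + 1 / gn[pairs[2L, ]]))
  q <- abs(diff) / se
  p <- pmax(stats::ptukey(q, nmeans = k, df = df2, lower.tail = FALSE),
            P_FLOOR)
  out <- data.frame(
    group1 = pairs[1L, ], group2 = pairs[2L, ],
    diff = unname(diff), se = unname(se), q = unname(q),
    p.adj = unname(p), significant = unname(p < alpha),
    stringsAsFactors = FALSE
  )
  structure(out, group_means = gm, df_resid = df2, alpha = alpha,
            class = c("tukey_hsd", "data.frame"))
}

#' Compact letter display
#'
#' Assigns letters to groups so that two groups share at least one letter
#' if and only if they are not significantly different, using the
#' insert-and-absorb algorithm: start from one letter covering all groups;
#' for every significant pair split each letter containing both, then drop
#' letters whose group set is contained in another's. Letters are ordered
#' by descending group mean.
#'
#' @param comparisons A [tukey_hsd()] result, or any data frame with
#'   columns `group1`, `group2`, `significant`.
#' @param group_means Optional named vector of group means used to order
#'   groups and letters; taken from the `tukey_hsd` attribute when present.
#' @return Named character vector: letter string per group, names ordered
#'   by descending mean.
#' @export
compact_letter_display <- function(comparisons, group_means = NULL) {
  req <- c("group1", "group2", "significant")
  if (!all(req %in% names(comparisons))) {
    stop("comparisons must have columns group1, group2, significant")
  }
  if (is.null(group_means)) group_means <- attr(comparisons, "group_means")
  groups <- unique(c(comparisons$group1, comparisons$group2))
  n_pairs <- choose(length(groups), 2L)
  if (nrow(comparisons) != n_pairs) {
    stop("comparisons must cover all ", n_pairs, " pairs")
  }
  if (!is.null(group_means)) {
    groups <- names(sort(group_means[groups], decreasing = TRUE))
  } else {
    groups <- sort(groups)
  }
  sets <- list(groups)
  sig <- comparisons[comparisons$significant, , drop = FALSE]
  for (i in seq_len(nrow(sig))) {
    a <- sig$group1[i]
    b <- sig$group2[i]
    new_sets <- list()
    for (s in sets) {
      if (a %in% s && b %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
      } else {
        new_sets <- c(new_sets, list(s))
      }
    }
    # absorb: drop duplicates and sets contained in a strictly larger set
    new_sets <- new_sets[!duplicated(lapply(new_sets, sort))]
    keep <- vapply(seq_along(new_sets), function(p) {
      !any(vapply(seq_along(new_sets), function(q) {
        q != p && length(new_sets[[p]]) < length(new_sets[[q]]) &&
          all(new_sets[[p]] %in% new_sets[[q]])
      }, TRUE))
    }, TRUE)
    sets <- new_sets[keep]
  }
  # order letter sets by the best (highest-mean) group they contain
  rank_of <- stats::setNames(seq_along(groups), groups)
  set_rank <- vapply(sets, function(s) min(rank_of[s]), 1)
  sets <- sets[order(set_rank)]
  letters_out <- stats::setNames(rep("", length(groups)), groups)
  for (i in seq_along(sets)) {
    lab <- make_letter(i)
    for (g in sets[[i]]) letters_out[g] <- paste0(letters_out[g], lab)
  }
  letters_out
}

make_letter <- function(i) {
  out <- ""
  i <- i - 1L
  repeat {
    out <- paste0(letters[(i %% 26L) + 1L], out)
    i <- i %/% 26L
    if (i == 0L) break
    i <- i - 1L
  }
  out
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length; pairs with missing values
#'   dropped. Requires `n >= 3` complete pairs and nonconstant inputs.
#' @param conf_level Confidence level for the Fisher-z interval.
#' @return List: `r`, `statistic` (t with n-2 df), `p.value` (two-sided),
#'   `conf.int` (Fisher z), `n`.
#' @export
pearson_correlation <- function(x, y, conf_level = 0.95) {
  stopifnot(length(x) == length(y))
  keep <- stats::complete.cases(x, y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("Pearson correlation requires n >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- max(2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE), P_FLOOR)
  ci <- c(NA_real_, NA_real_)
  if (n > 3L && abs(r) < 1) {
    z <- atanh(r)
    hw <- stats::qnorm(1 - (1 - conf_level) / 2) / sqrt(n - 3)
    ci <- tanh(c(z - hw, z + hw))
  }
  list(r = r, statistic = tstat, p.value = p, conf.int = ci, n = n)
}

#' Per-site trait summary
#'
#' Mean, sample SD and n per site for one trait, at the tree level or the
#' variety-mean level.
#'
#' @param table A `trait_table`.
#' @param trait Trait name.
#' @param level `"tree"` (raw tree values) or `"variety"` (variety means).
#' @return Data frame: `site`, `level`, `n`, `mean`, `sd` (`NA` when
#'   `n < 2`), `cv_pct`.
#' @export
site_summary <- function(table, trait, level = c("tree", "variety")) {
  stopifnot(inherits(table, "trait_table"))
  level <- match.arg(level)
  if (!trait %in% attr(table, "trait_names")) stop("unknown trait: ", trait)
  dat <- if (level == "tree") {
    data.frame(site = table$site, value = table[[trait]],
               stringsAsFactors = FALSE)
  } else {
    vm <- variety_means(table)
    data.frame(site = vm$site, value = vm[[trait]], stringsAsFactors = FALSE)
  }
  dat <- dat[!is.na(dat$value), , drop = FALSE]
  sites <- sort(unique(dat$site))
  out <- do.call(rbind, lapply(sites, function(s) {
    v <- dat$value[dat$site == s]
    data.frame(site = s, level = level, n = length(v), mean = mean(v),
               sd = if (length(v) >= 2L) stats::sd(v) else NA_real_,
               cv_pct = if (length(v) >= 2L && mean(v) != 0) {
                 coefficient_of_variation(v)
               } else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
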