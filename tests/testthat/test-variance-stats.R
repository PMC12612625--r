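test_that("coefficient of variation: closed form, invariance, errors", {
  expect_equal(coefficient_of_variation(c(1, 2, 3)), 50)
  expect_equal(coefficient_of_variation(rep(4, 5)), 0)
  x <- rlnorm(20)
  expect_equal(coefficient_of_variation(3.7 * x),
               coefficient_of_variation(x))
  expect_error(coefficient_of_variation(5), "n >= 2")
  expect_error(coefficient_of_variation(c(-1, 1)), "zero mean")
})

test_that("one-way ANOVA reproduces the hand-worked decomposition", {
  an <- oneway_anova(c(1, 2, 3, 4), c("g1", "g1", "g2", "g2"))
  expect_equal(an$sumsq, c(4, 1))
  expect_equal(an$df, c(1, 2))
  expect_equal(an$statistic[1], 8)
  expect_equal(attr(an, "total_ss"), 5)
  # identical group means
  an2 <- oneway_anova(c(1, 3, 1, 3), c("a", "a", "b", "b"))
  expect_equal(an2$sumsq[1], 0)
  expect_equal(an2$statistic[1], 0)
})

test_that("one-way ANOVA agrees with stats::aov on random unbalanced data", {
  set.seed(42)
  for (i in 1:100) {
    k <- sample(2:5, 1)
    n <- sample((k + 1):25, 1)
    g <- sample(letters[1:k], n, replace = TRUE)
    while (length(unique(g)) < k) g <- sample(letters[1:k], n, replace = TRUE)
    y <- rnorm(n, mean = as.integer(factor(g)))
    mine <- oneway_anova(y, g)
    ref <- summary(stats::aov(y ~ factor(g)))[[1]]
    expect_equal(mine$sumsq, ref[["Sum Sq"]], tolerance = 1e-10)
    expect_equal(mine$df, ref[["Df"]])
    expect_equal(mine$statistic[1], ref[["F value"]][1], tolerance = 1e-10)
    expect_equal(mine$p.value[1], ref[["Pr(>F)"]][1], tolerance = 1e-10)
    # exact decomposition
    expect_equal(sum(mine$sumsq), attr(mine, "total_ss"), tolerance = 1e-10)
  }
})

test_that("two-way Type II SS matches car::Anova on unbalanced fixtures", {
  skip_if_not_installed("car")
  set.seed(17)
  for (i in 1:25) {
    nv <- sample(3:6, 1)
    reps <- matrix(sample(2:4, 2 * nv, replace = TRUE), nrow = 2)
    rows <- list()
    for (s in 1:2) for (v in 1:nv) {
      rows[[length(rows) + 1]] <- data.frame(
        site = paste0("S", s), variety = paste0("V", v),
        tree = paste0("t", seq_len(reps[s, v])),
        LMA = abs(rnorm(reps[s, v], mean = 100 + 5 * v + 3 * s, sd = 4)) + 1
      )
    }
    tab <- suppressWarnings(trait_table(do.call(rbind, rows)))
    mine <- twoway_anova_site_variety(tab, "LMA")
    fit <- stats::lm(LMA ~ site * variety, data = as.data.frame(tab))
    ref <- car::Anova(fit, type = 2)
    expect_equal(mine$sumsq, ref[["Sum Sq"]], tolerance = 1e-10)
    expect_equal(mine$df, ref[["Df"]])
    expect_equal(mine$p.value[1:3], ref[["Pr(>F)"]][1:3], tolerance = 1e-10)
  }
})

test_that("balanced two-way SS is exhaustive; pure additivity kills the interaction", {
  # balanced: components sum to total SS
  grid <- expand.grid(site = c("S1", "S2"), variety = paste0("V", 1:4),
                      tree = c("t1", "t2"), stringsAsFactors = FALSE)
  set.seed(3)
  grid$LMA <- abs(rnorm(nrow(grid), 100, 10)) + 1
  tab <- suppressWarnings(trait_table(grid))
  an <- twoway_anova_site_variety(tab, "LMA")
  expect_equal(sum(an$sumsq), attr(an, "total_ss"), tolerance = 1e-10)
  # additive data, zero noise: interaction SS = 0
  grid$LMA <- 100 + 2 * as.integer(factor(grid$site)) +
    5 * as.integer(factor(grid$variety))
  tab2 <- suppressWarnings(trait_table(grid))
  an2 <- twoway_anova_site_variety(tab2, "LMA")
  expect_equal(an2$sumsq[3], 0, tolerance = 1e-10)
  expect_error(twoway_anova_site_variety(tab2, "nope"), "unknown trait")
})

test_that("variance partition handles the degenerate single-component cases", {
  p <- default_trait_profiles()[4, ]
  # pure site effect
  p$f_G <- 0; p$f_E <- 1; p$f_I <- 0; p$f_res <- 0
  cfg <- simulation_config(n_common = 6, n_distinct_per_site = 0,
                           trees_per_variety = 2, trait_profiles = p, seed = 2)
  tab <- simulate_trait_table(cfg)$table
  vc <- variance_components(tab, subset_trait_table(tab, "common"), "LMA")
  expect_equal(vc$plasticity_pct, 100, tolerance = 1e-10)
  expect_equal(vc$genetic_pct, 0, tolerance = 1e-10)
  # pure genetic effect
  p$f_G <- 1; p$f_E <- 0
  cfg2 <- simulation_config(n_common = 6, n_distinct_per_site = 0,
                            trees_per_variety = 2, trait_profiles = p, seed = 2)
  tab2 <- simulate_trait_table(cfg2)$table
  vc2 <- variance_components(tab2, subset_trait_table(tab2, "common"), "LMA")
  expect_equal(vc2$genetic_pct, 100, tolerance = 1e-10)
  expect_equal(vc2$residual_pct, 0, tolerance = 1e-10)
})

test_that("Tukey HSD reduces to the pooled t-test for two groups", {
  set.seed(8)
  y <- rnorm(12, mean = rep(c(0, 1), each = 6))
  g <- rep(c("a", "b"), each = 6)
  tk <- tukey_hsd(y, g)
  tt <- stats::t.test(y ~ g, var.equal = TRUE)
  expect_equal(tk$p.adj, tt$p.value, tolerance = 1e-10)
  expect_equal(tk$q, sqrt(2) * abs(tt$statistic[[1]]), tolerance = 1e-10)
})

test_that("Tukey HSD agrees with stats::TukeyHSD on unbalanced groups", {
  set.seed(9)
  for (i in 1:20) {
    k <- sample(3:5, 1)
    g <- unlist(lapply(1:k, function(j) rep(letters[j], sample(3:6, 1))))
    y <- rnorm(length(g), as.integer(factor(g)) * 0.8)
    mine <- tukey_hsd(y, g)
    ref <- stats::TukeyHSD(stats::aov(y ~ factor(g)))[[1]]
    key_mine <- paste(mine$group2, mine$group1, sep = "-")
    expect_equal(mine$p.adj[match(rownames(ref), key_mine)],
                 unname(ref[, "p adj"]), tolerance = 1e-8)
    # adjusted p never below the unadjusted pairwise t-test p
    # (pooled-MSE t statistic is q / sqrt(2))
    praw <- 2 * stats::pt(mine$q / sqrt(2), attr(mine, "df_resid"),
                          lower.tail = FALSE)
    expect_true(all(mine$p.adj + 1e-12 >= praw))
  }
})

test_that("identical groups give adjusted p of 1", {
  y <- c(1, 2, 3, 1, 2, 3, 1, 2, 3)
  g <- rep(c("a", "b", "c"), each = 3)
  tk <- tukey_hsd(y, g)
  expect_true(all(tk$p.adj > 1 - 1e-9))
})

test_that("studentized range CDF matches a Monte-Carlo estimate", {
  # P(q <= 3.5) for k = 4 means, df = 20
  set.seed(123)
  n_mc <- 2e5
  mc <- replicate(50, {
    z <- matrix(rnorm(4 * (n_mc / 50)), ncol = 4)
    s <- sqrt(rchisq(n_mc / 50, 20) / 20)
    q <- (apply(z, 1, max) - apply(z, 1, min)) / s
    mean(q <= 3.5)
  })
  expect_equal(stats::ptukey(3.5, 4, 20), mean(mc), tolerance = 0.003 / 0.9)
})

test_that("compact letter display covers the canonical cases", {
  means <- c(a = 3, b = 2, c = 1)
  cmp <- function(sig) data.frame(group1 = c("a", "a", "b"),
                                  group2 = c("b", "c", "c"),
                                  significant = sig)
  # no significant pairs: one letter
  expect_equal(unname(compact_letter_display(cmp(c(FALSE, FALSE, FALSE)),
                                             means)),
               rep("a", 3))
  # all significant: distinct letters in mean order
  expect_equal(compact_letter_display(cmp(c(TRUE, TRUE, TRUE)), means),
               c(a = "a", b = "b", c = "c"))
  # chain a~b, b~c, a!=c
  expect_equal(compact_letter_display(cmp(c(FALSE, TRUE, FALSE)), means),
               c(a = "a", b = "ab", c = "b"))
})

test_that("letter sharing is equivalent to non-significance (brute force, k <= 6)", {
  set.seed(30)
  for (i in 1:40) {
    k <- sample(3:6, 1)
    groups <- letters[1:k]
    pairs <- utils::combn(groups, 2)
    sig <- runif(ncol(pairs)) < 0.4
    cmp <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                      significant = sig)
    means <- stats::setNames(rev(seq_len(k)), groups)
    cld <- compact_letter_display(cmp, means)
    for (j in seq_len(ncol(pairs))) {
      shared <- length(intersect(strsplit(cld[pairs[1, j]], "")[[1]],
                                 strsplit(cld[pairs[2, j]], "")[[1]])) > 0
      expect_equal(shared, !sig[j])
    }
  }
})

test_that("Pearson correlation: closed forms and cor.test agreement", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  expect_equal(pearson_correlation(x, c(1, 3, 2, 4))$r, 0.8)
  set.seed(4)
  a <- rnorm(15)
  b <- 0.5 * a + rnorm(15)
  mine <- pearson_correlation(a, b)
  ref <- stats::cor.test(a, b)
  expect_equal(mine$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(mine$p.value, ref$p.value, tolerance = 1e-12)
  expect_equal(mine$conf.int, as.numeric(ref$conf.int), tolerance = 1e-12)
  expect_error(pearson_correlation(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("site summaries report both aggregation levels", {
  tab <- toy_table()
  st <- site_summary(tab, "LMA", level = "tree")
  sv <- site_summary(tab, "LMA", level = "variety")
  expect_equal(st$n, c(6, 6))
  expect_equal(sv$n, c(3, 3))
  expect_equal(st$mean[st$site == "A"],
               mean(tab$LMA[tab$site == "A"]))
  # single tree: SD undefined -> NA
  one <- make_table("A", "v", "t1", data.frame(LMA = 100))
  expect_true(is.na(site_summary(one, "LMA")$sd))
})
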