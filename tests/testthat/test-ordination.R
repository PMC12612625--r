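# varimax criterion (raw, unnormalized): variance of squared loadings per column
varimax_criterion <- function(L) {
  sum(apply(L^2, 2, function(col) mean(col^2) - mean(col)^2))
}

test_that("correlation PCA satisfies the trace and orthogonality identities", {
  tab <- random_table(seed = 14, n_common = 12, n_distinct = 4)
  ord <- pca_site(tab, "site1")
  expect_equal(sum(ord$eigenvalues), length(ord$traits), tolerance = 1e-10)
  expect_equal(sum(ord$var_pct), 100, tolerance = 1e-10)
  cc <- stats::cor(ord$scores)
  expect_equal(unname(cc - diag(ncol(cc))), matrix(0, ncol(cc), ncol(cc)),
               tolerance = 1e-8)
})

test_that("PCA agrees with prcomp on random fixtures", {
  set.seed(15)
  for (i in 1:20) {
    n <- 8
    p <- 5
    X <- matrix(abs(rnorm(n * p, 10, 2)) + 0.1, n, p)
    colnames(X) <- c("LMA", "LDMC", "BWD", "SSL", "LA")
    df <- data.frame(site = "S", variety = paste0("v", 1:n), tree = "t1", X)
    tab <- suppressWarnings(trait_table(df))
    ord <- pca_site(tab, "S")
    ref <- stats::prcomp(X, center = TRUE, scale. = TRUE)
    expect_equal(ord$eigenvalues, ref$sdev^2, tolerance = 1e-10)
    # eigenvectors match up to column sign
    for (j in seq_len(p)) {
      v1 <- ord$eigenvectors[, j]
      v2 <- ref$rotation[, j]
      expect_equal(min(sum((v1 - v2)^2), sum((v1 + v2)^2)), 0,
                   tolerance = 1e-10)
    }
  }
})

test_that("PCA rejects rank-deficient and undersized inputs", {
  df <- data.frame(site = "S", variety = paste0("v", 1:8), tree = "t1",
                   LMA = abs(rnorm(8, 100, 5)), LDMC = 400)
  tab <- suppressWarnings(trait_table(df))
  expect_error(pca_site(tab, "S"), "constant trait")
  small <- suppressWarnings(trait_table(df[1:2, ]))
  expect_error(pca_site(small, "S"), "complete-case trees")
})

test_that("varimax preserves communalities and never lowers the criterion", {
  tab <- random_table(seed = 19)
  ord <- pca_site(tab, "site2")
  rot <- varimax_rotate(ord, k = 3)
  L <- ord$loadings[, 1:3]
  Lr <- rot$rotation$loadings
  expect_equal(rowSums(Lr^2), rowSums(L^2), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_gte(varimax_criterion(Lr), varimax_criterion(L) - 1e-12)
  # rotation matrix is orthogonal; scores rotated consistently
  R <- rot$rotation$rotmat
  expect_equal(t(R) %*% R, diag(3), tolerance = 1e-10)
  expect_equal(rot$rotation$scores, ord$scores[, 1:3] %*% R,
               ignore_attr = TRUE)
})

test_that("a permuted-identity loading matrix is a varimax fixed point", {
  L <- diag(4)[, c(2, 4, 1, 3)]
  rownames(L) <- c("LMA", "LDMC", "BWD", "SSL")
  ord <- structure(list(traits = rownames(L),
                        eigenvalues = rep(1, 4),
                        loadings = L,
                        scores = matrix(rnorm(40), 10, 4)),
                   class = "ordination")
  rot <- varimax_rotate(ord, k = 4)
  # criterion already maximal: rotated loadings equal the input up to
  # column order and sign
  expect_equal(abs(rot$rotation$loadings) %*% rep(1, 4),
               abs(L) %*% rep(1, 4), tolerance = 1e-8)
  expect_equal(varimax_criterion(rot$rotation$loadings),
               varimax_criterion(L), tolerance = 1e-10)
})

test_that("k = 2 varimax matches an exhaustive single-angle grid search", {
  set.seed(23)
  for (i in 1:5) {
    L <- matrix(rnorm(12), 6, 2)
    rownames(L) <- paste0("tr", 1:6)
    ord <- structure(list(traits = rownames(L), eigenvalues = rep(1, 2),
                          loadings = L, scores = matrix(rnorm(16), 8, 2)),
                     class = "ordination")
    rot <- varimax_rotate(ord, k = 2)
    # grid over the rotation angle at 1e-4 rad; criterion of the Kaiser-
    # normalized loadings (what varimax with normalize = TRUE maximizes)
    sc <- sqrt(rowSums(L^2))
    Ln <- L / sc
    best <- max(vapply(seq(0, pi / 2, by = 1e-4), function(th) {
      R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2)
      varimax_criterion(Ln %*% R)
    }, 1))
    got <- varimax_criterion((Ln) %*% rot$rotation$rotmat)
    expect_equal(got, best, tolerance = 1e-6)
  }
})

test_that("fast-slow axis selection and orientation follow the loadings", {
  L <- cbind(RC1 = c(LMA = 0.1, LDMC = 0.05, BWD = 0.9, SSL = 0.2),
             RC2 = c(-0.9, -0.8, 0.1, 0.1),
             RC3 = c(0.2, 0.1, 0.1, 0.9))
  scores <- matrix(rnorm(30), 10, 3)
  ord <- structure(list(traits = rownames(L), eigenvalues = rep(1, 4),
                        rotation = list(k = 3, loadings = L, scores = scores),
                        tree_info = data.frame(site = "S",
                                               variety = rep(paste0("v", 1:5), 2),
                                               tree = rep(c("t1", "t2"), each = 5)),
                        site = "S"),
                   class = "ordination")
  got <- identify_fast_slow_axis(ord)
  expect_equal(got$fast_slow$component, 2)
  # LMA loaded negative on RC2, so the axis is flipped
  expect_equal(got$fast_slow$sign, -1)
  expect_equal(got$fast_slow$scores, -scores[, 2])
  # selection is invariant to permuting the components
  perm <- c(3, 1, 2)
  ord2 <- ord
  ord2$rotation$loadings <- L[, perm]
  ord2$rotation$scores <- scores[, perm]
  got2 <- identify_fast_slow_axis(ord2)
  expect_equal(got2$fast_slow$scores, got$fast_slow$scores)
})

test_that("a slow-shifted variety gets the highest fast-slow score", {
  # varieties vary along a latent leaf-economics factor so that LMA and
  # LDMC co-load on one component, as on a real fast-slow axis
  set.seed(61)
  nv <- 12
  f <- rnorm(nv)
  vdf <- data.frame(variety = sprintf("C%02d", 1:nv),
                    lma_v = 277 * (1 + 0.10 * f),
                    ldmc_v = 470 * (1 + 0.08 * f))
  dat <- merge(data.frame(variety = rep(vdf$variety, each = 3),
                          tree = rep(paste0("t", 1:3), nv),
                          site = "site1"), vdf, by = "variety")
  dat$LMA <- abs(dat$lma_v + rnorm(nrow(dat), 0, 8))
  dat$LDMC <- abs(dat$ldmc_v + rnorm(nrow(dat), 0, 10))
  dat$LA <- abs(rnorm(nrow(dat), 5, 0.8))
  dat$SSL <- abs(rnorm(nrow(dat), 25, 3))
  dat$BWD <- abs(rnorm(nrow(dat), 0.75, 0.05))
  dat$RBT <- abs(rnorm(nrow(dat), 0.25, 0.03))
  dat <- dat[, c("site", "variety", "tree", "LA", "LMA", "LDMC",
                 "SSL", "BWD", "RBT")]
  # shift one variety's LMA and LDMC up by 2 pooled SDs
  for (tr in c("LMA", "LDMC")) {
    s <- stats::sd(dat[[tr]])
    dat[[tr]][dat$variety == "C01"] <- dat[[tr]][dat$variety == "C01"] + 2 * s
  }
  tab2 <- suppressWarnings(trait_table(dat))
  ord <- identify_fast_slow_axis(varimax_rotate(pca_site(tab2, "site1"), 3))
  sc <- fast_slow_scores(ord)
  expect_equal(sc$variety[which.max(sc$score)], "C01")
  # duplicating every tree leaves the variety ranking unchanged (scores can
  # shift marginally through the n-1 standardization denominator)
  dup <- dat
  dup$tree <- paste0(dup$tree, "b")
  both <- suppressWarnings(trait_table(rbind(dat, dup)))
  ord2 <- identify_fast_slow_axis(varimax_rotate(pca_site(both, "site1"), 3))
  sc2 <- fast_slow_scores(ord2)
  expect_equal(sc2$variety[which.max(sc2$score)], "C01")
  expect_gt(abs(stats::cor(sc$score, sc2$score)), 0.999)
})

test_that("strategy correlations have the contracted shape and affine r = 1", {
  tab <- random_table(seed = 44, n_common = 17, n_distinct = 0, trees = 3)
  phd <- phd_matrix(tab)
  mv <- mvpi(tab)
  ords <- lapply(c("site1", "site2"), function(s) {
    identify_fast_slow_axis(varimax_rotate(pca_site(tab, s), 3))
  })
  scores <- do.call(rbind, lapply(ords, fast_slow_scores))
  ct <- plasticity_strategy_correlations(scores, phd, mv)
  expect_equal(nrow(ct), 2 * 11)
  expect_setequal(unique(ct$variable), c(colnames(phd), "MVPi"))
  # PhD column that is an affine function of the scores -> r = 1
  s1 <- scores[scores$site == "site1", ]
  phd2 <- phd
  phd2[s1$variety, "LMA"] <- 0.1 + 0.05 * s1$score
  ct2 <- plasticity_strategy_correlations(s1, phd2, mvpi_values = NULL)
  expect_equal(ct2$r[ct2$variable == "LMA"], 1, tolerance = 1e-10)
})
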