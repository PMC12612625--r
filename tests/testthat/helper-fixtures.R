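# Shared fixtures: small trait tables built in code.

# 2 sites x 3 varieties per site (1 shared) x 2 trees x 2 traits
toy_table <- function() {
  df <- expand.grid(tree = c("t1", "t2"),
                    variety = c("shared", NA),
                    site = c("A", "B"),
                    stringsAsFactors = FALSE)
  df <- rbind(
    data.frame(site = "A", variety = rep(c("shared", "onlyA1", "onlyA2"), each = 2),
               tree = rep(c("t1", "t2"), 3)),
    data.frame(site = "B", variety = rep(c("shared", "onlyB1", "onlyB2"), each = 2),
               tree = rep(c("t1", "t2"), 3))
  )
  set.seed(99)
  df$LMA <- round(stats::runif(nrow(df), 200, 300), 4)
  df$BWD <- round(stats::runif(nrow(df), 0.6, 0.9), 4)
  suppressWarnings(trait_table(df))
}

# random two-site table with n_common shared varieties, all 10 traits
random_table <- function(seed, n_common = 8L, n_distinct = 4L,
                         trees = c(2L, 3L)) {
  cfg <- simulation_config(n_common = n_common,
                           n_distinct_per_site = n_distinct,
                           trees_per_variety = trees, seed = seed)
  simulate_trait_table(cfg)$table
}

# build a trait_table directly from site/variety vectors and a value matrix
make_table <- function(site, variety, tree, values) {
  df <- data.frame(site = site, variety = variety, tree = tree,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(values))
  suppressWarnings(trait_table(df))
}
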