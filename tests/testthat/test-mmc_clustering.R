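test_that("correlation matrix matches the covariance formula", {
  ft <- random_table(20, 6, seed = 11)
  r <- correlation_matrix(ft)
  expect_equal(diag(r), rep(1, 20), ignore_attr = TRUE)
  expect_identical(r, t(r))
  set.seed(12)
  for (k in 1:10) {
    i <- sample(20, 1); j <- sample(20, 1)
    expect_equal(r[i, j], pearson_direct(unclass(ft)[i, ],
                                         unclass(ft)[j, ]),
                 tolerance = 1e-12)
  }
  # self and anti-self
  m <- unclass(random_table(1, 8, seed = 2))
  ft2 <- feature_table(rbind(m, -m), feature_ids = c("x", "negx"),
                       sample_ids = colnames(m))
  r2 <- correlation_matrix(ft2)
  expect_equal(r2["x", "negx"], -1)
  # constant feature errors, fewer than 3 samples errors
  ftc <- feature_table(rbind(a = c(1, 1, 1), b = c(1, 2, 3)),
                       sample_ids = c("s1", "s2", "s3"))
  expect_error(correlation_matrix(ftc), "constant")
  expect_error(correlation_matrix(random_table(4, 2, seed = 1)), "3 samples")
})

test_that("sigmoid weights follow the transform formula and limits", {
  set.seed(21)
  ft <- random_table(5, 10, seed = 21)
  r <- correlation_matrix(ft)
  wm <- sigmoid_weights(r, s = 8, t = 0.6)
  direct <- 1 / (1 + exp(-8 * (abs(r) - 0.6)))
  diag(direct) <- 0
  expect_equal(wm$w, direct, tolerance = 1e-15)
  expect_equal(diag(wm$w), rep(0, 5), ignore_attr = TRUE)
  expect_true(all(wm$w >= 0 & wm$w <= 1))
  # midpoint: |r| == t -> 0.5
  r2 <- matrix(c(1, 0.6, 0.6, 1), 2)
  expect_equal(sigmoid_weights(r2, 4, 0.6)$w[1, 2], 0.5)
  # step-function limit
  r3 <- matrix(c(1, 0.9, 0.9, 1), 2)
  expect_equal(sigmoid_weights(r3, 1e4, 0.5)$w[1, 2], 1, tolerance = 1e-12)
  expect_error(sigmoid_weights(r2, -1, 0.5), "s must")
})

test_that("modularity formula: analytic identities and exhaustive optimum", {
  # all-in-one partition has Q = 0
  w <- random_weights(6, seed = 31)
  expect_equal(modularity_q(w, rep(1L, 6)), 0)
  # zero graph defined as Q = 0
  expect_equal(modularity_q(matrix(0, 3, 3), c(1, 2, 3)), 0)
  # two disconnected perfect pairs, correct split -> Q = 1/2
  w4 <- matrix(0, 4, 4)
  w4[1, 2] <- w4[2, 1] <- w4[3, 4] <- w4[4, 3] <- 1
  expect_equal(modularity_q(w4, c(1, 1, 2, 2)), 0.5)
  # spectral result equals the brute-force optimum on a 6-node toy graph
  parts <- enum_partitions(6)
  w6 <- random_weights(6, seed = 32)
  best <- max(vapply(parts, function(p) modularity_q(w6, p), 0))
  expect_equal(modularity_q(w6, partition_weights(w6)), best,
               tolerance = 1e-9)
  # cross-check the formula against igraph's weighted modularity
  g <- igraph::graph_from_adjacency_matrix(w6, mode = "undirected",
                                           weighted = TRUE)
  p <- partition_weights(w6)
  expect_equal(modularity_q(w6, p),
               igraph::modularity(g, p, weights = igraph::E(g)$weight),
               tolerance = 1e-12)
})

test_that("spectral partition handles components and near-empty graphs", {
  # two disconnected cliques -> exactly the components
  w <- matrix(0, 6, 6)
  w[1:3, 1:3] <- 1; w[4:6, 4:6] <- 1
  diag(w) <- 0
  p <- partition_weights(w)
  expect_length(unique(p), 2L)
  expect_length(unique(p[1:3]), 1L)
  expect_length(unique(p[4:6]), 1L)
  # all ~zero off-diagonal weights -> single module
  w0 <- matrix(1e-12, 5, 5); diag(w0) <- 0
  expect_length(unique(partition_weights(w0)), 1L)
})

test_that("spectral+refined Q reaches the enumerated optimum on n=8", {
  parts <- enum_partitions(8)
  hits <- 0L
  for (seed in 1:25) {
    w <- random_weights(8, seed = 400 + seed)
    best <- max(vapply(parts, function(p) modularity_q(w, p), 0))
    q <- modularity_q(w, partition_weights(w))
    expect_lte(q, best + 1e-9)
    if (abs(q - best) <= 1e-9) hits <- hits + 1L
  }
  expect_gte(hits, 23L)  # >= 90%
})

test_that("run_mmc recovers planted blocks and respects |r| clustering", {
  sim <- make_planted_modules(50, c(20, 20, 20), within_r = 0.81,
                              seed = 77)
  res <- run_mmc(sim$table)
  expect_equal(length(res$sizes), 3L)
  expect_equal(mclust::adjustedRandIndex(res$partition, sim$labels), 1)
  # stored Q equals recomputed Q
  wm <- sigmoid_weights(res$corr, res$s, res$t)
  expect_equal(res$Q, modularity_q(wm, res$partition), tolerance = 1e-12)
  # heatmap ordering: modules contiguous, all features present
  expect_setequal(res$ordering, names(res$partition))
  runs <- rle(res$partition[res$ordering])$values
  expect_equal(length(runs), length(unique(runs)))

  # anti-correlated members co-cluster under |r|
  sim2 <- make_planted_modules(30, c(15, 15), within_r = 0.81, seed = 78,
                               negative_fraction = 0.4)
  res2 <- run_mmc(sim2$table)
  expect_equal(mclust::adjustedRandIndex(res2$partition, sim2$labels), 1)
})

test_that("run_mmc on independent features yields only fragmented modules", {
  # with no planted structure the partition must stay fragmented: several
  # modules, none approaching the full feature set (sizes 6-22 of 30 over
  # a 20-seed survey; Q sits near 0.5 by sparse-graph modularity
  # inflation, so Q is asserted bounded, not near zero)
  maxes <- integer(0)
  for (seed in c(11, 12, 13, 14, 15)) {
    sim <- make_planted_modules(100, rep(1L, 30), within_r = 0,
                                seed = seed)
    r <- correlation_matrix(sim$table)
    expect_lt(mean(abs(r[upper.tri(r)])), 0.2)
    res <- run_mmc(sim$table)
    expect_gte(length(res$sizes), 3L)
    expect_lt(max(res$sizes), 25L)
    expect_lt(res$Q, 0.8)
    maxes <- c(maxes, max(res$sizes))
  }
  expect_lte(stats::median(maxes), 15L)
})

test_that("run_mmc is invariant to feature order and module relabeling", {
  sim <- make_planted_modules(24, c(8, 8, 8), within_r = 0.7, seed = 80)
  res <- run_mmc(sim$table)
  set.seed(81)
  perm <- sample(nrow(sim$table))
  shuffled <- feature_table(unclass(sim$table)[perm, ])
  res_p <- run_mmc(shuffled)
  expect_equal(res_p$Q, res$Q, tolerance = 1e-12)
  expect_equal(mclust::adjustedRandIndex(
    res_p$partition[names(res$partition)], res$partition), 1)
  # relabeling leaves Q unchanged
  wm <- sigmoid_weights(res$corr, res$s, res$t)
  relab <- max(res$partition) + 1L - res$partition
  expect_equal(modularity_q(wm, relab), res$Q, tolerance = 1e-12)
  # single feature -> single module with warning
  one <- feature_table(matrix(1:4, 1, dimnames = list("m1", paste0("s", 1:4))))
  expect_warning(r1 <- run_mmc(one), "single module")
  expect_equal(unname(r1$partition), 1L)
})

test_that("module files round-trip through write_mmc/read_modules", {
  sim <- make_planted_modules(12, c(6, 6), within_r = 0.8, seed = 82)
  res <- run_mmc(sim$table)
  path <- withr::local_tempfile(fileext = ".tsv")
  ord <- withr::local_tempfile(fileext = ".tsv")
  write_mmc(res, path, order_path = ord)
  expect_identical(read_modules(path), res$partition)
  expect_identical(readLines(ord)[-1], res$ordering)
})
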