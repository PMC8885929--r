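test_that("dense limit coincides with sequential SVD of the cross-product", {
  set.seed(70)
  X <- matrix(rnorm(12 * 6), 12, 6)
  Y <- matrix(rnorm(12 * 4), 12, 4)
  for (nc in 1:3) {
    m <- fit_spls(X, Y, ncomp = nc)
    oracle <- dense_pls_oracle(X, Y, nc)
    expect_equal(unname(m$loadings_x), oracle$U, tolerance = 1e-8)
    expect_equal(unname(m$loadings_y), oracle$V, tolerance = 1e-8)
    expect_equal(unname(m$scores_x), oracle$TT, tolerance = 1e-8)
  }
  # X-score orthogonality across components
  m <- fit_spls(X, Y, ncomp = 3)
  g <- crossprod(m$scores_x)
  expect_equal(g[upper.tri(g)], rep(0, 3), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("dense fit agrees with an independent sPLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(71)
  X <- matrix(rnorm(15 * 5), 15, 5,
              dimnames = list(NULL, paste0("x", 1:5)))
  Y <- matrix(rnorm(15 * 3), 15, 3,
              dimnames = list(NULL, paste0("y", 1:3)))
  m <- fit_spls(X, Y, ncomp = 2)
  ref <- mixOmics::spls(X, Y, ncomp = 2, keepX = c(5, 5), keepY = c(3, 3),
                        mode = "regression", scale = TRUE)
  for (h in 1:2) {
    a <- m$loadings_x[, h]
    b <- ref$loadings$X[, h]
    expect_equal(abs(sum(a * b)), 1, tolerance = 1e-6)
  }
})

test_that("sparsity selects the right variables, deterministically", {
  set.seed(72)
  X <- matrix(rnorm(10 * 6), 10, 6,
              dimnames = list(NULL, paste0("x", 1:6)))
  # Y equals predictor x3 -> keepX = 1 selects x3
  Y <- X[, 3, drop = FALSE]
  m <- fit_spls(X, Y, ncomp = 1, keepX = 1)
  expect_equal(m$selected[[1]], "x3")
  expect_equal(sum(m$loadings_x[, 1] != 0), 1L)

  # exactly keepX nonzero loadings per component
  set.seed(73)
  Y2 <- matrix(rnorm(10 * 3), 10, 3)
  m2 <- fit_spls(X, Y2, ncomp = 2, keepX = 3)
  expect_equal(colSums(m2$loadings_x != 0), c(3, 3), ignore_attr = TRUE)

  # reruns on identical input are identical
  for (rep in 1:5) {
    again <- fit_spls(X, Y2, ncomp = 2, keepX = 3)
    expect_identical(again$selected, m2$selected)
    expect_identical(again$loadings_x, m2$loadings_x)
  }

  # keepX above p clips with a warning; zero-variance column dropped
  expect_warning(fit_spls(X, Y2, ncomp = 1, keepX = 99), "clipped")
  Xz <- cbind(X, xconst = 1)
  expect_message(mz <- fit_spls(Xz, Y2, ncomp = 1), "zero-variance")
  expect_false("xconst" %in% rownames(mz$loadings_x))
})

test_that("selected sets are invariant to positive predictor rescaling", {
  set.seed(74)
  X <- matrix(rnorm(12 * 8), 12, 8,
              dimnames = list(NULL, paste0("x", 1:8)))
  Y <- matrix(rnorm(12 * 2), 12, 2)
  m1 <- fit_spls(X, Y, ncomp = 2, keepX = 4)
  X2 <- X
  X2[, 2] <- X2[, 2] * 37
  X2[, 5] <- X2[, 5] * 0.01
  m2 <- fit_spls(X2, Y, ncomp = 2, keepX = 4)
  expect_identical(m1$selected, m2$selected)
  expect_equal(m1$loadings_x, m2$loadings_x, tolerance = 1e-10)
})

test_that("heatmap similarities reproduce score correlations", {
  set.seed(75)
  n <- 20
  z <- rnorm(n)
  X <- cbind(drv = z + rnorm(n, sd = 0.05),
             oth = rnorm(n))
  Y <- cbind(pos = z + rnorm(n, sd = 0.05),
             neg = -z + rnorm(n, sd = 0.05))
  m <- fit_spls(X, Y, ncomp = 1)
  hm <- spls_heatmap_data(m)
  expect_gt(hm["drv", "pos"], 0.9)
  expect_lt(hm["drv", "neg"], -0.9)
  # formula oracle from stored scores
  direct <- stats::cor(m$X, m$scores_x) %*% t(stats::cor(m$Y, m$scores_y))
  expect_equal(hm, pmin(pmax(direct[rownames(hm), , drop = FALSE], -1), 1),
               tolerance = 1e-12)
})

test_that("integration fits one model per module and recovers drivers", {
  sizes <- stats::setNames(rep(10L, 6), paste0("pw", 1:6))
  linked <- data.frame(
    metabolite_id = paste0("mA", 1:4),
    pathway_id = "pw2", sign = c(1, 1, -1, 1))
  hits <- 0L
  for (seed in 1:10) {
    sim <- make_pathway_factor_data(sizes, linked, n_unlinked = 4,
                                    n_samples = 10, seed = seed)
    mg <- compute_metagenes(sim$genes, sim$annotation)
    modules <- stats::setNames(
      ifelse(startsWith(rownames(sim$metabolites), "mA"), 1L, 2L),
      rownames(sim$metabolites))
    res <- run_integration(mg, modules, sim$metabolites, ncomp = 2,
                           keepX = 2)
    expect_named(res, c("module_1", "module_2"))
    sel <- unlist(res$module_1$model$selected)
    if (any(grepl("^pw2_", sel))) hits <- hits + 1L
    # driven module shows stronger association than the noise module
    expect_gt(max(abs(res$module_1$heatmap)),
              max(abs(res$module_2$heatmap)))
  }
  expect_gte(hits, 9L)
})

test_that("integration handles singleton modules and 9-module input", {
  sizes <- stats::setNames(rep(8L, 3), paste0("pw", 1:3))
  linked <- data.frame(metabolite_id = paste0("m", 1:9),
                       pathway_id = rep(paste0("pw", 1:3), 3),
                       sign = 1)
  sim <- make_pathway_factor_data(sizes, linked, n_samples = 10, seed = 5)
  modules <- stats::setNames(1:9, rownames(sim$metabolites))  # q = 1 each
  mg <- compute_metagenes(sim$genes, sim$annotation)
  res <- run_integration(mg, modules, sim$metabolites, ncomp = 1,
                         keepX = 2)
  expect_length(res, 9L)
  expect_true(all(vapply(res, function(x)
    nrow(x$model$loadings_y) == 1L, logical(1))))
})
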