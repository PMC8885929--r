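#' Correlation matrix of a feature table
#'
#' Pairwise correlation of feature profiles across samples. Constant
#' features must be removed first (see [drop_constant_features()]); a
#' constant feature reaching this point is an error rather than a silent
#' column of NaN.
#'
#' @param table a [feature_table()] with at least 3 samples.
#' @param method `"pearson"` or `"spearman"`.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(table, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  m <- unclass(table)
  if (ncol(m) < 3L) stop("need at least 3 samples for correlation")
  rng <- apply(m, 1L, function(x) max(x) - min(x))
  if (any(rng == 0))
    stop("constant feature(s): ",
         paste(rownames(m)[rng == 0], collapse = ", "),
         "; remove with drop_constant_features()")
  r <- stats::cor(t(m), method = method)
  r <- (r + t(r)) / 2  # enforce exact symmetry
  diag(r) <- 1
  pmin(pmax(r, -1), 1)
}

#' Sigmoid edge weights from a correlation matrix
#'
#' Maps (absolute) correlations smoothly into `[0, 1]` edge weights:
#' `w_ij = 1 / (1 + exp(-s * (|r_ij| - t)))` for `i != j`, diagonal 0.
#' `t` is the correlation at which a pair gets weight 0.5; `s` controls how
#' sharply the sigmoid separates correlations above and below `t`. As
#' `s -> Inf` the transform becomes a hard threshold at `t`; small `s`
#' keeps the full correlation ordering. Module detection scans a grid of
#' `s` (and `t`), which is what makes the clustering "modulated": the
#' sharpness yielding the most modular weight structure is chosen by the
#' data.
#'
#' @param corr correlation matrix.
#' @param s sharpness, `> 0`.
#' @param t midpoint, in `(0, 1)`.
#' @param signed if TRUE use `r` instead of `|r|` (negative correlations
#'   then get near-zero weight). The default uses `|r|` so anti-correlated
#'   metabolites co-cluster, matching how modules of both signs appear in
#'   correlation heatmaps.
#' @return object of class `weight_matrix`: list with `w` (n x n weights),
#'   `corr`, `s`, `t`.
#' @export
sigmoid_weights <- function(corr, s, t, signed = FALSE) {
  if (!is.numeric(s) || s <= 0) stop("s must be > 0")
  if (!is.numeric(t) || t <= 0 || t >= 1) stop("t must be in (0, 1)")
  x <- if (signed) corr else abs(corr)
  w <- 1 / (1 + exp(-s * (x - t)))
  diag(w) <- 0
  w <- (w + t(w)) / 2
  structure(list(w = w, corr = corr, s = s, t = t), class = "weight_matrix")
}

as_weight_matrix <- function(weights) {
  if (inherits(weights, "weight_matrix")) return(weights)
  w <- as.matrix(weights)
  stopifnot(nrow(w) == ncol(w))
  structure(list(w = w, corr = NULL, s = NA_real_, t = NA_real_),
            class = "weight_matrix")
}

#' Weighted Newman modularity of a partition
#'
#' `Q = (1/2m) * sum_ij (w_ij - k_i k_j / 2m) * [c_i == c_j]` with
#' `k_i = sum_j w_ij` and `2m = sum_ij w_ij`. Q compares the weight inside
#' modules to its expectation under a degree-preserving null; it is 0 for
#' the all-in-one partition and (by convention) 0 when the graph has no
#' weight at all.
#'
#' @param weights a `weight_matrix` (or plain symmetric matrix).
#' @param partition integer module labels, one per node.
#' @return modularity Q in `[-1, 1]`.
#' @export
modularity_q <- function(weights, partition) {
  w <- as_weight_matrix(weights)$w
  n <- nrow(w)
  if (length(partition) != n) stop("partition must cover all nodes")
  m2 <- sum(w)
  if (m2 == 0) return(0)
  k <- rowSums(w)
  q <- 0
  for (c in unique(partition)) {
    idx <- partition == c
    q <- q + sum(w[idx, idx]) / m2 - (sum(k[idx]) / m2)^2
  }
  q
}

# Leading-eigenvector bisection of the generalized modularity matrix,
# with single-node Kernighan-Lin style refinement of each split.
# B_ij = w_ij - k_i k_j / 2m; for a subgraph g the generalized form
# subtracts the row sums on the diagonal so that splitting g changes Q by
# s' Bg s / (2 * 2m).
bisect_modularity <- function(Bg, tol = 1e-12) {
  n <- nrow(Bg)
  if (n < 2L) return(NULL)
  es <- eigen(Bg, symmetric = TRUE)
  v <- es$vectors[, 1L]
  if (es$values[1L] <= tol) return(NULL)
  s <- ifelse(v >= 0, 1, -1)
  # canonical orientation for reproducibility under eigenvector sign flips
  if (s[1L] < 0) s <- -s
  # refine: flip single nodes while the quadratic form improves
  obj <- drop(s %*% Bg %*% s)
  repeat {
    Bs <- drop(Bg %*% s)
    gain <- -4 * s * Bs + 4 * diag(Bg)
    i <- which.max(gain)
    if (gain[i] <= tol) break
    s[i] <- -s[i]
    obj <- obj + gain[i]
  }
  if (all(s == s[1L]) || obj <= tol) return(NULL)
  s
}

#' Partition nodes by spectral modularity maximization
#'
#' Recursive leading-eigenvector bisection of the modularity matrix,
#' stopping when no split increases Q, followed by greedy single-node
#' reassignment (and greedy module merging) until no move increases Q.
#' Fully deterministic: eigenvector sign is canonicalized, nodes are
#' scanned in index order, and the best strictly-improving move is taken.
#'
#' @param weights a `weight_matrix` or symmetric nonnegative matrix.
#' @return integer vector of module labels `1..K`, named by node if the
#'   weight matrix has dimnames.
#' @export
partition_weights <- function(weights) {
  wm <- as_weight_matrix(weights)
  w <- wm$w
  n <- nrow(w)
  labels <- rep(1L, n)
  m2 <- sum(w)
  if (n < 2L || m2 == 0) {
    names(labels) <- rownames(w)
    return(labels)
  }
  k <- rowSums(w)
  B <- w - outer(k, k) / m2

  split_rec <- function(idx) {
    if (length(idx) < 2L) return(list(idx))
    Bg <- B[idx, idx, drop = FALSE]
    diag(Bg) <- diag(Bg) - rowSums(Bg)
    s <- bisect_modularity(Bg)
    if (is.null(s)) return(list(idx))
    c(split_rec(idx[s > 0]), split_rec(idx[s < 0]))
  }
  groups <- split_rec(seq_len(n))
  for (g in seq_along(groups)) labels[groups[[g]]] <- g

  labels <- refine_partition(w, labels)
  names(labels) <- rownames(w)
  labels
}

# Greedy refinement: move single nodes to the neighboring module with the
# largest strictly positive Q gain; then merge module pairs while that
# increases Q; repeat until stable.
refine_partition <- function(w, labels, tol = 1e-12) {
  n <- nrow(w)
  m2 <- sum(w)
  if (m2 == 0) return(rep(1L, n))
  k <- rowSums(w)
  repeat {
    moved <- FALSE
    repeat {
      any_move <- FALSE
      mods <- sort(unique(labels))
      stot <- vapply(mods, function(c) sum(k[labels == c]), 0)
      names(stot) <- mods
      for (i in seq_len(n)) {
        ci <- as.character(labels[i])
        ki_in <- vapply(mods, function(c) sum(w[i, labels == c]), 0)
        names(ki_in) <- mods
        a <- ki_in[[ci]]             # w[i,i] = 0 so this excludes i
        stot_ci <- stot[[ci]] - k[i]
        best_gain <- tol; best_c <- NULL
        for (c in setdiff(mods, labels[i])) {
          gain <- 2 * (ki_in[[as.character(c)]] - a) / m2 -
            2 * k[i] * (stot[[as.character(c)]] - stot_ci) / m2^2
          if (gain > best_gain) { best_gain <- gain; best_c <- c }
        }
        if (!is.null(best_c)) {
          stot[[ci]] <- stot[[ci]] - k[i]
          stot[[as.character(best_c)]] <- stot[[as.character(best_c)]] + k[i]
          labels[i] <- best_c
          any_move <- TRUE; moved <- TRUE
        }
      }
      if (!any_move) break
    }
    # merge phase
    merged <- FALSE
    repeat {
      mods <- sort(unique(labels))
      if (length(mods) < 2L) break
      stot <- vapply(mods, function(c) sum(k[labels == c]), 0)
      wbet <- matrix(0, length(mods), length(mods))
      for (ii in seq_along(mods)) for (jj in seq_along(mods)) if (ii < jj)
        wbet[ii, jj] <- sum(w[labels == mods[ii], labels == mods[jj]])
      gains <- 2 * wbet / m2 -
        2 * outer(stot, stot) / m2^2 * upper.tri(wbet)
      gains[lower.tri(gains, diag = TRUE)] <- -Inf
      if (max(gains) <= tol) break
      ij <- which(gains == max(gains), arr.ind = TRUE)[1L, ]
      labels[labels == mods[ij[2L]]] <- mods[ij[1L]]
      merged <- TRUE; moved <- TRUE
    }
    if (!moved) break
  }
  match(labels, sort(unique(labels)))
}

#' Run modulated modularity clustering
#'
#' Clusters features (typically metabolites) by abundance-pattern
#' correlation. For every `(s, t)` on the grid the correlation matrix is
#' sigmoid-transformed into edge weights, the weights are partitioned by
#' spectral modularity maximization, and Q is recorded; the `(s, t)` with
#' maximal Q wins. Ties are broken toward fewer modules, then smaller `s`,
#' then smaller `t`, so results are deterministic.
#'
#' Modules are relabeled 1..K by decreasing size (ties by first member).
#' The returned ordering places modules contiguously and sorts members
#' within a module by decreasing mean intra-module `|r|`, the order used
#' for correlation heatmaps.
#'
#' @param table a [feature_table()] of metabolites.
#' @param s_grid sharpness grid (default `c(1, 2, 4, 8, 16, 32)`).
#' @param t_grid midpoint grid (default `c(0.3, 0.4, 0.5, 0.6, 0.7)`).
#' @param method correlation method.
#' @param signed passed to [sigmoid_weights()].
#' @return object of class `mmc_result`: list with `partition` (named
#'   integer vector), `Q`, `s`, `t`, `sizes`, `ordering` (feature ids in
#'   heatmap order), `corr`, `method`.
#' @export
run_mmc <- function(table, s_grid = c(1, 2, 4, 8, 16, 32),
                    t_grid = c(0.3, 0.4, 0.5, 0.6, 0.7),
                    method = c("pearson", "spearman"), signed = FALSE) {
  method <- match.arg(method)
  if (!length(s_grid) || !length(t_grid)) stop("empty parameter grid")
  ids <- rownames(table)
  if (nrow(table) < 2L) {
    warning("fewer than 2 features; returning a single module")
    part <- stats::setNames(rep(1L, nrow(table)), ids)
    return(structure(list(partition = part, Q = 0, s = s_grid[1L],
                          t = t_grid[1L], sizes = length(part),
                          ordering = ids, corr = NULL, method = method),
                     class = "mmc_result"))
  }
  corr <- correlation_matrix(table, method = method)
  best <- NULL
  for (t in sort(t_grid)) for (s in sort(s_grid)) {
    wm <- sigmoid_weights(corr, s, t, signed = signed)
    part <- partition_weights(wm)
    q <- modularity_q(wm, part)
    K <- length(unique(part))
    if (is.null(best) ||
        q > best$Q + 1e-12 ||
        (abs(q - best$Q) <= 1e-12 &&
         (K < best$K || (K == best$K &&
                         (s < best$s || (s == best$s && t < best$t)))))) {
      best <- list(Q = q, K = K, s = s, t = t, partition = part)
    }
  }
  part <- relabel_by_size(best$partition)
  names(part) <- ids
  ord <- heatmap_order(corr, part)
  structure(list(partition = part, Q = best$Q, s = best$s, t = best$t,
                 sizes = as.integer(table(part)),
                 ordering = ids[ord], corr = corr, method = method),
            class = "mmc_result")
}

relabel_by_size <- function(part) {
  tab <- table(part)
  first <- vapply(names(tab), function(c) min(which(part == c)), 0L)
  o <- order(-as.integer(tab), first)
  match(as.character(part), names(tab)[o])
}

heatmap_order <- function(corr, part) {
  ord <- integer(0)
  for (c in sort(unique(part))) {
    idx <- which(part == c)
    if (length(idx) == 1L) { ord <- c(ord, idx); next }
    intra <- vapply(idx, function(i)
      mean(abs(corr[i, setdiff(idx, i)])), 0)
    ord <- c(ord, idx[order(-intra, idx)])
  }
  ord
}

#' @export
print.mmc_result <- function(x, ...) {
  cat(sprintf("mmc_result: %d features, K = %d, Q = %.4f (s = %g, t = %g)\n",
              length(x$partition), length(x$sizes), x$Q, x$s, x$t))
  cat("module sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Write module assignments
#'
#' TSV with columns featureID, module, followed by a comment summary line
#' `# K=<K> Q=<Q> s=<s> t=<t>` readable by humans and ignored by parsers.
#' @param mmc an `mmc_result`.
#' @param path output path.
#' @param order_path optional path for the heatmap ordering (one feature id
#'   per line, heatmap order).
#' @export
write_mmc <- function(mmc, path, order_path = NULL) {
  lines <- c("featureID\tmodule",
             sprintf("%s\t%d", names(mmc$partition), mmc$partition),
             sprintf("# K=%d Q=%.6f s=%g t=%g",
                     length(mmc$sizes), mmc$Q, mmc$s, mmc$t))
  writeLines(lines, path, useBytes = TRUE)
  if (!is.null(order_path))
    writeLines(c("featureID", mmc$ordering), order_path, useBytes = TRUE)
  invisible(path)
}

#' Read module assignments written by [write_mmc()]
#' @param path path to the modules TSV.
#' @return named integer vector feature -> module.
#' @export
read_modules <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!startsWith(lines, "#")][-1L]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(as.integer(vapply(parts, `[[`, "", 2L)),
                  vapply(parts, `[[`, "", 1L))
}
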