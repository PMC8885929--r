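# Independent oracles and small fixture builders shared across tests.

# All set partitions of n labeled items, as restricted-growth strings.
enum_partitions <- function(n) {
  out <- list()
  rec <- function(a, mx) {
    if (length(a) == n) {
      out[[length(out) + 1L]] <<- a
      return()
    }
    for (v in seq_len(mx + 1L)) rec(c(a, v), max(mx, v))
  }
  rec(integer(0), 0L)
  out
}

# Symmetric random weight matrix in [0,1], zero diagonal.
random_weights <- function(n, seed) {
  set.seed(seed)
  w <- matrix(stats::runif(n * n), n)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  w
}

# Direct textbook Pearson correlation of two vectors.
pearson_direct <- function(x, y) {
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# A tiny feature table of iid normals.
random_table <- function(nf, ns, seed, prefix = "f") {
  set.seed(seed)
  feature_table(matrix(stats::rnorm(nf * ns), nf, ns),
                feature_ids = sprintf("%s%03d", prefix, seq_len(nf)),
                sample_ids = sprintf("s%02d", seq_len(ns)))
}

# Snapshot fixture in a per-session temp dir, built once.
mini_snapshot <- local({
  snap <- NULL
  function() {
    if (is.null(snap)) {
      dir <- file.path(tempdir(), "gmlink-mini-kegg")
      snap <<- make_mini_kegg(dir)
    }
    snap
  }
})

# Dense PLS oracle: sequential leading singular pairs of the cross-product
# with regression-mode deflation, oriented like fit_spls.
dense_pls_oracle <- function(X, Y, ncomp) {
  Xs <- scale(X)
  Ys <- scale(Y)
  U <- matrix(0, ncol(X), ncomp)
  V <- matrix(0, ncol(Y), ncomp)
  TT <- matrix(0, nrow(X), ncomp)
  for (h in seq_len(ncomp)) {
    sv <- svd(crossprod(Xs, Ys))
    u <- sv$u[, 1L]
    v <- sv$v[, 1L]
    j <- order(-abs(u), seq_along(u))[1L]
    if (u[j] < 0) {
      u <- -u
      v <- -v
    }
    xi <- drop(Xs %*% u)
    cx <- drop(crossprod(Xs, xi)) / sum(xi^2)
    dy <- drop(crossprod(Ys, xi)) / sum(xi^2)
    Xs <- Xs - tcrossprod(xi, cx)
    Ys <- Ys - tcrossprod(xi, dy)
    U[, h] <- u
    V[, h] <- v
    TT[, h] <- xi
  }
  list(U = U, V = V, TT = TT)
}
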