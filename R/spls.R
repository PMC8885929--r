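# Soft-threshold x so exactly `keep` entries remain nonzero: shrink by the
# (keep+1)-th largest |x|. Ranking ties are broken by column order; if
# shrinkage would zero a tied kept entry its unshrunk value is used so the
# selected-set size is always exactly min(keep, length(x)).
soft_threshold_keep <- function(x, keep) {
  p <- length(x)
  keep <- min(keep, p)
  if (keep >= p) return(x)
  ord <- order(-abs(x), seq_along(x))
  kept <- ord[seq_len(keep)]
  lambda <- max(abs(x[ord[(keep + 1L):p]]))
  out <- numeric(p)
  shrunk <- abs(x[kept]) - lambda
  shrunk[shrunk <= 0] <- abs(x[kept])[shrunk <= 0]  # tie at the threshold
  out[kept] <- sign(x[kept]) * shrunk
  out
}

#' Fit a sparse partial least squares model
#'
#' Relates a response block Y (e.g. the metabolite abundances of one
#' module) to a predictor block X (e.g. pathway metagene scores) by PLS
#' regression with per-component variable selection. Columns are centered
#' and unit-scaled internally, so the fit is invariant to positive
#' rescaling of any column.
#'
#' Per component h the leading singular pair (u, v) of the cross-product
#' `M = X_h' Y_h` is found by alternating power iterations; at every
#' iteration u is soft-thresholded so exactly `keepX[h]` predictors keep a
#' nonzero loading (largest absolute values, ties by column order), and
#' likewise v with `keepY[h]`. Scores are `xi = X_h u` and `omega = Y_h v`;
#' both blocks are then deflated by regression on `xi` (regression-mode
#' deflation), which makes X-scores across components mutually orthogonal.
#' Each component is oriented so its largest-|loading| predictor entry is
#' positive, making the fit deterministic across platforms. With
#' `keepX = p` and `keepY = q` the fit coincides with dense PLS.
#'
#' @param X numeric matrix, samples x predictors.
#' @param Y numeric matrix (or vector), samples x responses.
#' @param ncomp number of components, `<= min(dim)`.
#' @param keepX integer(s): predictors kept per component (recycled to
#'   `ncomp`; values above p are clipped with a warning). Default: all.
#' @param keepY responses kept per component; default all.
#' @param tol convergence tolerance on the change in u (default 1e-9).
#' @param max_iter maximum alternating iterations per component (500).
#' @return object of class `spls_model`: list with `loadings_x` (p x
#'   ncomp), `loadings_y`, `scores_x` (n x ncomp), `scores_y`, `selected`
#'   (list of selected predictor names per component), `keepX`, `keepY`,
#'   `X`, `Y` (the scaled blocks), `ncomp`.
#' @export
fit_spls <- function(X, Y, ncomp = 2, keepX = NULL, keepY = NULL,
                     tol = 1e-9, max_iter = 500L) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same samples")
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("Y", seq_len(ncol(Y)))
  drop0 <- function(m, label) {
    s <- apply(m, 2L, stats::sd)
    if (any(s == 0)) {
      message("dropping zero-variance ", label, " column(s): ",
              paste(colnames(m)[s == 0], collapse = ", "))
      m <- m[, s > 0, drop = FALSE]
    }
    m
  }
  X <- drop0(X, "predictor")
  Y <- drop0(Y, "response")
  p <- ncol(X); q <- ncol(Y); n <- nrow(X)
  ncomp <- as.integer(ncomp)
  if (ncomp < 1L || ncomp > min(n - 1L, p))
    stop("ncomp must be in 1..min(n-1, p)")
  if (is.null(keepX)) keepX <- p
  if (is.null(keepY)) keepY <- q
  keepX <- rep_len(as.integer(keepX), ncomp)
  keepY <- rep_len(as.integer(keepY), ncomp)
  if (any(keepX > p)) {
    warning("keepX > number of predictors; clipped to ", p)
    keepX <- pmin(keepX, p)
  }
  keepY <- pmin(keepY, q)
  if (any(keepX < 1L) || any(keepY < 1L)) stop("keepX/keepY must be >= 1")

  Xs <- scale(X)
  Ys <- scale(Y)
  Xh <- Xs; Yh <- Ys
  U <- matrix(0, p, ncomp, dimnames = list(colnames(X), NULL))
  V <- matrix(0, q, ncomp, dimnames = list(colnames(Y), NULL))
  TT <- matrix(0, n, ncomp, dimnames = list(rownames(X), NULL))
  W <- matrix(0, n, ncomp, dimnames = list(rownames(Y), NULL))
  selected <- vector("list", ncomp)

  for (h in seq_len(ncomp)) {
    M <- crossprod(Xh, Yh)
    sv <- svd(M, nu = 1L, nv = 1L)
    u <- sv$u[, 1L]; v <- sv$v[, 1L]
    for (iter in seq_len(max_iter)) {
      u_old <- u
      u <- drop(M %*% v)
      u <- soft_threshold_keep(u, keepX[h])
      nu <- sqrt(sum(u^2)); if (nu == 0) break
      u <- u / nu
      v <- drop(crossprod(M, u))
      v <- soft_threshold_keep(v, keepY[h])
      nv <- sqrt(sum(v^2)); if (nv == 0) break
      v <- v / nv
      if (max(abs(abs(u) - abs(u_old))) < tol) break
    }
    j <- order(-abs(u), seq_along(u))[1L]
    if (u[j] < 0) { u <- -u; v <- -v }
    xi <- drop(Xh %*% u)
    om <- drop(Yh %*% v)
    ss <- sum(xi^2)
    if (ss > 0) {
      cx <- drop(crossprod(Xh, xi)) / ss
      dy <- drop(crossprod(Yh, xi)) / ss
      Xh <- Xh - tcrossprod(xi, cx)
      Yh <- Yh - tcrossprod(xi, dy)
    }
    U[, h] <- u; V[, h] <- v; TT[, h] <- xi; W[, h] <- om
    selected[[h]] <- colnames(X)[u != 0]
  }
  structure(list(loadings_x = U, loadings_y = V, scores_x = TT,
                 scores_y = W, selected = selected, keepX = keepX,
                 keepY = keepY, X = Xs, Y = Ys, ncomp = ncomp),
            class = "spls_model")
}

#' @export
print.spls_model <- function(x, ...) {
  cat(sprintf("spls_model: %d comp, %d predictors (keepX = %s), %d responses\n",
              x$ncomp, nrow(x$loadings_x),
              paste(x$keepX, collapse = ","), nrow(x$loadings_y)))
  invisible(x)
}

#' Predictor-response similarity matrix for heatmaps
#'
#' For selected predictor i and response j,
#' `sim(i, j) = sum_h cor(X_i, xi_h) * cor(Y_j, omega_h)` over the
#' retained components — the product of each variable's correlation with
#' the latent scores, as displayed in sPLS association heatmaps. Values
#' are clipped to `[-1, 1]` for display.
#'
#' @param model a fitted `spls_model`.
#' @return matrix selected-predictors x responses of similarities.
#' @export
spls_heatmap_data <- function(model) {
  sel <- sort(unique(unlist(model$selected)))
  sel <- colnames(model$X)[colnames(model$X) %in% sel]  # stable order
  cx <- stats::cor(model$X[, sel, drop = FALSE], model$scores_x)
  cy <- stats::cor(model$Y, model$scores_y)
  sim <- tcrossprod(cx, cy)  # sum over components
  dimnames(sim) <- list(sel, colnames(model$Y))
  pmin(pmax(sim, -1), 1)
}

#' Integrate metabolite modules with pathway metagenes
#'
#' Fits one sparse PLS model per metabolite module: predictors are the
#' pathway metagene scores (component 1 per pathway by default), responses
#' are the module's metabolite abundance profiles. Samples are intersected
#' across the two blocks (logged when not identical). Modules with a
#' single metabolite are still fit (q = 1).
#'
#' @param metagenes a `metagene_table`.
#' @param modules named integer vector metabolite -> module (from
#'   [run_mmc()]'s `partition` or [read_modules()]), or an `mmc_result`.
#' @param metabolite_table a [feature_table()] of metabolites.
#' @param ncomp,keepX passed to [fit_spls()] (keepX clipped to the number
#'   of metagene predictors).
#' @param components metagene components used as predictors.
#' @return object of class `integration_result`: named list
#'   (`module_<k>`) of `list(model, heatmap)`.
#' @export
run_integration <- function(metagenes, modules, metabolite_table,
                            ncomp = 2, keepX = 10, components = 1L) {
  if (inherits(modules, "mmc_result")) modules <- modules$partition
  Xall <- metagene_matrix(metagenes, components = components)
  shared <- intersect(rownames(Xall), colnames(metabolite_table))
  if (length(shared) < 3L) stop("fewer than 3 shared samples")
  if (length(shared) < nrow(Xall) || length(shared) < ncol(metabolite_table))
    message("using ", length(shared), " shared sample(s)")
  Xall <- Xall[shared, , drop = FALSE]
  mets <- intersect(names(modules), rownames(metabolite_table))
  if (!length(mets)) stop("no module metabolite found in the table")
  ncomp_eff <- min(ncomp, ncol(Xall), length(shared) - 1L)
  keepX <- min(keepX, ncol(Xall))
  out <- list()
  for (k in sort(unique(modules[mets]))) {
    ids <- mets[modules[mets] == k]
    Y <- t(unclass(metabolite_table)[ids, shared, drop = FALSE])
    model <- fit_spls(Xall, Y, ncomp = ncomp_eff, keepX = keepX)
    out[[sprintf("module_%d", k)]] <-
      list(model = model, heatmap = spls_heatmap_data(model))
  }
  structure(out, class = "integration_result")
}

#' @export
print.integration_result <- function(x, ...) {
  cat(sprintf("integration_result: %d module model(s)\n", length(x)))
  invisible(x)
}

#' Write per-module integration output
#'
#' For each module writes `<prefix>module_<k>_heatmap.tsv` (similarity
#' matrix, pathways x metabolites) and `<prefix>module_<k>_loadings.tsv`
#' (X-loadings per component).
#'
#' @param integration an `integration_result`.
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @export
write_integration <- function(integration, dir, prefix = "") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(m) {
    out <- matrix(sprintf("%.8f", m), nrow(m), ncol(m))
    colnames(out) <- colnames(m)
    out
  }
  for (nm in names(integration)) {
    hm <- integration[[nm]]$heatmap
    out <- cbind(pathway = rownames(hm),
                 as.data.frame(fmt(hm), stringsAsFactors = FALSE))
    utils::write.table(out, file.path(dir, sprintf("%s%s_heatmap.tsv",
                                                   prefix, nm)),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
    ld <- integration[[nm]]$model$loadings_x
    out <- cbind(pathway = rownames(ld),
                 as.data.frame(fmt(ld), stringsAsFactors = FALSE))
    colnames(out) <- c("pathway", sprintf("comp%d", seq_len(ncol(ld))))
    utils::write.table(out, file.path(dir, sprintf("%s%s_loadings.tsv",
                                                   prefix, nm)),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  }
  invisible(dir)
}
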