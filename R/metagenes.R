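#' Extract a pathway's expression submatrix
#'
#' Restricts a gene feature table to the genes annotated to one KEGG
#' pathway, preserving the input row order.
#'
#' @param table a [feature_table()] of genes.
#' @param annotation an `annotation_table` with pathway membership.
#' @param pathway_id a KEGG pathway id.
#' @return a [feature_table()] (possibly with zero rows, with a warning).
#' @export
pathway_submatrix <- function(table, annotation, pathway_id) {
  psets <- pathway_sets(annotation)
  members <- names(psets)[vapply(psets, function(p) pathway_id %in% p,
                                 logical(1))]
  keep <- rownames(table) %in% members
  if (!any(keep))
    warning("no genes in the data annotated to pathway ", pathway_id)
  m <- unclass(table)[keep, , drop = FALSE]
  structure(m, class = c("feature_table", "matrix", "array"))
}

# Row-standardize with population (1/n) variance; constant rows dropped.
standardize_rows <- function(m, log_drop = TRUE) {
  mu <- rowMeans(m)
  sd_pop <- sqrt(rowMeans((m - mu)^2))
  const <- sd_pop == 0
  if (any(const) && log_drop)
    message("dropping ", sum(const), " constant gene(s): ",
            paste(rownames(m)[const], collapse = ", "))
  m <- m[!const, , drop = FALSE]
  (m - mu[!const]) / sd_pop[!const]
}

#' Compute pathway metagenes
#'
#' A metagene is a single per-sample score summarizing the coordinated
#' expression of one pathway's genes: the leading principal component(s)
#' of the standardized (zero mean, unit population variance per gene)
#' pathway submatrix. For each pathway with at least `min_genes` genes in
#' the data, the smallest number of components whose cumulative explained
#' variance reaches `var_target` is retained (always at least one).
#'
#' PCA signs are arbitrary, so each component is oriented to correlate
#' positively with the majority of the pathway's gene profiles (exact ties
#' fall back to making the loading of the lexicographically first gene id
#' positive — an id-based rather than row-based tie-break, so reruns on
#' permuted gene order give identical output).
#'
#' Defaults `min_genes = 3`, `var_target = 0.5`: metagenes are meant as
#' coarse pathway activity summaries, and in practice the first component
#' of a coherently-regulated pathway carries most of the usable signal, so
#' downstream integration uses component 1 by default with further
#' components optional.
#'
#' @param table a [feature_table()] of genes.
#' @param annotation an `annotation_table` with pathway membership.
#' @param min_genes minimum pathway size (after dropping constant genes).
#' @param var_target cumulative explained-variance target in `(0, 1]`.
#' @return object of class `metagene_table`: list with
#'   \describe{
#'     \item{scores}{matrix (pathway_id, component) x samples, rows named
#'       `"<pathway>_PC<k>"`, each row zero-mean across samples.}
#'     \item{info}{data.frame `pathway_id`, `component`,
#'       `variance_explained`, `n_genes`.}
#'     \item{loadings}{named list pathway_id -> genes x components matrix.}
#'   }
#' @export
compute_metagenes <- function(table, annotation, min_genes = 3,
                              var_target = 0.5) {
  if (ncol(table) < 3L) stop("need at least 3 samples")
  if (var_target <= 0 || var_target > 1) stop("var_target must be in (0, 1]")
  pids <- sort(unique(unlist(pathway_sets(annotation), use.names = FALSE)))
  scores <- NULL
  info <- list()
  loadings <- list()
  for (pid in pids) {
    sub <- suppressWarnings(pathway_submatrix(table, annotation, pid))
    if (!nrow(sub)) next
    z <- standardize_rows(unclass(sub))
    if (nrow(z) < min_genes) {
      message("skipping pathway ", pid, ": ", nrow(z), " gene(s) < min_genes")
      next
    }
    x <- t(z)  # samples x genes, columns centered
    sv <- svd(x)
    pos <- sv$d > max(sv$d) * 1e-12
    d <- sv$d[pos]
    ve <- d^2 / sum(d^2)
    ncomp <- which(cumsum(ve) >= var_target - 1e-12)[1L]
    if (is.na(ncomp)) ncomp <- length(ve)
    ncomp <- max(1L, ncomp)
    sc <- sv$u[, seq_len(ncomp), drop = FALSE] *
      rep(d[seq_len(ncomp)], each = nrow(x))
    ld <- sv$v[, seq_len(ncomp), drop = FALSE]
    first <- order(rownames(z), method = "radix")[1L]  # order-independent
    for (c in seq_len(ncomp)) {
      cors <- suppressWarnings(stats::cor(sc[, c], t(z)))
      npos <- sum(cors > 0, na.rm = TRUE)
      nneg <- sum(cors < 0, na.rm = TRUE)
      flip <- if (npos != nneg) npos < nneg else ld[first, c] < 0
      if (flip) { sc[, c] <- -sc[, c]; ld[, c] <- -ld[, c] }
    }
    rownames(sc) <- colnames(table)
    rownames(ld) <- rownames(z)
    colnames(sc) <- colnames(ld) <- sprintf("%s_PC%d", pid, seq_len(ncomp))
    scores <- rbind(scores, t(sc))
    info[[pid]] <- data.frame(pathway_id = pid, component = seq_len(ncomp),
                              variance_explained = ve[seq_len(ncomp)],
                              n_genes = nrow(z), stringsAsFactors = FALSE)
    loadings[[pid]] <- ld
  }
  if (is.null(scores)) stop("no pathway passed the min_genes threshold")
  info <- do.call(rbind, info)
  rownames(info) <- NULL
  structure(list(scores = scores, info = info, loadings = loadings),
            class = "metagene_table")
}

#' @export
print.metagene_table <- function(x, ...) {
  cat(sprintf("metagene_table: %d component(s) over %d pathway(s), %d samples\n",
              nrow(x$scores), length(unique(x$info$pathway_id)),
              ncol(x$scores)))
  invisible(x)
}

#' Metagene score matrix for integration
#'
#' Returns the samples x predictors matrix handed to the sparse PLS step:
#' one column per retained pathway component (by default component 1 only).
#'
#' @param metagenes a `metagene_table`.
#' @param components which components to keep per pathway.
#' @return numeric matrix samples x (pathway components).
#' @export
metagene_matrix <- function(metagenes, components = 1L) {
  keep <- metagenes$info$component %in% components
  t(metagenes$scores[keep, , drop = FALSE])
}

#' Write metagene scores and loadings
#'
#' Scores: TSV rows `pathwayID_PCk` x samples (plus varianceExplained and
#' nGenes columns); loadings: TSV rows gene x component per pathway.
#' @param metagenes a `metagene_table`.
#' @param path scores output path.
#' @param loadings_path optional loadings output path.
#' @export
write_metagenes <- function(metagenes, path, loadings_path = NULL) {
  sc <- metagenes$scores
  txt <- matrix(sprintf("%.10g", sc), nrow(sc), ncol(sc),
                dimnames = dimnames(sc))
  out <- cbind(metageneID = rownames(sc),
               as.data.frame(txt, stringsAsFactors = FALSE),
               varianceExplained = sprintf("%.6f",
                                           metagenes$info$variance_explained),
               nGenes = metagenes$info$n_genes)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  if (!is.null(loadings_path)) {
    rows <- character(0)
    for (pid in names(metagenes$loadings)) {
      ld <- metagenes$loadings[[pid]]
      for (g in rownames(ld))
        rows <- c(rows, paste(c(pid, g, sprintf("%.10g", ld[g, ])),
                              collapse = "\t"))
    }
    writeLines(c("pathwayID\tgene\tloadings", rows), loadings_path,
               useBytes = TRUE)
  }
  invisible(path)
}
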