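#' All-pairs gene-metabolite correlation
#'
#' Correlates every gene profile against every metabolite profile across
#' the shared samples (intersection by sample id, logged when the blocks
#' differ). This is the unbiased, knowledge-free counterpart to pathway
#' integration: no annotation is consulted, every measured pair is ranked.
#' Constant rows carry no signal and are excluded with a warning rather
#' than producing NaN columns.
#'
#' @param genes,metabolites [feature_table()] objects.
#' @param method `"pearson"` or `"spearman"`.
#' @return matrix genes x metabolites of correlations in `[-1, 1]`.
#' @export
all_pairs_correlation <- function(genes, metabolites,
                                  method = c("pearson", "spearman")) {
  method <- match.arg(method)
  shared <- intersect(colnames(genes), colnames(metabolites))
  if (length(shared) < 3L) stop("fewer than 3 shared samples")
  if (length(shared) < ncol(genes) || length(shared) < ncol(metabolites))
    message("correlating across ", length(shared), " shared sample(s)")
  g <- unclass(genes)[, shared, drop = FALSE]
  m <- unclass(metabolites)[, shared, drop = FALSE]
  dropc <- function(x, label) {
    rng <- apply(x, 1L, function(v) max(v) - min(v))
    if (any(rng == 0)) {
      warning("excluding constant ", label, "(s): ",
              paste(rownames(x)[rng == 0], collapse = ", "))
      x <- x[rng > 0, , drop = FALSE]
    }
    x
  }
  g <- dropc(g, "gene")
  m <- dropc(m, "metabolite")
  r <- stats::cor(t(g), t(m), method = method)
  pmin(pmax(r, -1), 1)
}

#' Top-K edges of a correlation matrix
#'
#' The `k` gene-metabolite pairs with the largest absolute correlation,
#' as a [bipartite_edges()] list sorted by `|r|` descending. Ties at any
#' rank (including the k-th) are broken by (gene, metabolite) bytewise
#' lexicographic order, never randomly, so the network is identical across
#' runs and input orderings. `k` larger than the number of pairs returns
#' all pairs.
#'
#' @param corr matrix genes x metabolites with dimnames.
#' @param k number of edges, `>= 1` (default 500).
#' @return a [bipartite_edges()] object.
#' @export
top_k_edges <- function(corr, k = 500) {
  if (k < 1) stop("k must be >= 1")
  gene <- rep(rownames(corr), times = ncol(corr))
  metab <- rep(colnames(corr), each = nrow(corr))
  r <- as.vector(corr)
  o <- order(-abs(r), gene, metab, method = "radix")
  o <- o[seq_len(min(k, length(o)))]
  bipartite_edges(gene[o], metab[o], r[o])
}

#' Metabolite hub summary
#'
#' Degree table of the bipartite network: for each metabolite the number
#' of incident genes, split by correlation sign, sorted by degree
#' descending (ties by metabolite id). High-degree metabolites ("hubs")
#' are the entry points for functional follow-up of the network.
#'
#' @param edges a [bipartite_edges()] object.
#' @return data.frame `metabolite`, `degree`, `n_pos`, `n_neg`.
#' @export
hub_summary <- function(edges) {
  stopifnot(inherits(edges, "bipartite_edges"))
  if (!nrow(edges))
    return(data.frame(metabolite = character(), degree = integer(),
                      n_pos = integer(), n_neg = integer(),
                      stringsAsFactors = FALSE))
  mets <- unique(edges$metabolite)
  out <- data.frame(
    metabolite = mets,
    degree = vapply(mets, function(m) sum(edges$metabolite == m), 0L),
    n_pos = vapply(mets, function(m)
      sum(edges$metabolite == m & edges$r >= 0), 0L),
    n_neg = vapply(mets, function(m)
      sum(edges$metabolite == m & edges$r < 0), 0L),
    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$metabolite, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
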