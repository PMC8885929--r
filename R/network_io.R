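#' Construct a bipartite edge list
#'
#' Edges of a gene-metabolite correlation network. The list is kept sorted
#' by `|r|` descending; ties are broken by (gene, metabolite) bytewise
#' lexicographic order so output files are identical across platforms and
#' locales.
#'
#' @param gene,metabolite character vectors of node identifiers.
#' @param r signed correlations in `[-1, 1]`.
#' @return data.frame of class `bipartite_edges` with columns `gene`,
#'   `metabolite`, `r`.
#' @export
bipartite_edges <- function(gene, metabolite, r) {
  gene <- as.character(gene)
  metabolite <- as.character(metabolite)
  r <- as.numeric(r)
  if (length(gene) != length(metabolite) || length(gene) != length(r))
    stop("gene, metabolite and r must have equal length")
  if (length(r) && max(abs(r)) > 1 + 1e-12)
    stop("|r| > 1 in edge list")
  r <- pmin(pmax(r, -1), 1)
  key <- paste(gene, metabolite, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (gene, metabolite) pair(s): ",
         paste(unique(gsub("\r", "/", key[duplicated(key)])), collapse = ", "))
  o <- order(-abs(r), gene, metabolite, method = "radix")
  out <- data.frame(gene = gene[o], metabolite = metabolite[o], r = r[o],
                    stringsAsFactors = FALSE)
  class(out) <- c("bipartite_edges", "data.frame")
  out
}

#' Write a bipartite network
#'
#' Exports a gene-metabolite edge list for network viewers. Three formats:
#' \describe{
#'   \item{sif}{Cytoscape simple-interaction lines
#'     `gene <TAB> pos|neg <TAB> metabolite`, relation chosen by the sign of
#'     r (`neg` iff r < 0).}
#'   \item{tsv}{columns `gene`, `metabolite`, `r` (8 decimals), `sign`.}
#'   \item{graphml}{bipartite graph with a `type` node attribute
#'     (gene/metabolite) and `weight` edge attribute, via igraph.}
#' }
#' Edges are written in `|r|`-descending order as stored.
#'
#' @param edges a [bipartite_edges()] object.
#' @param path output path.
#' @param format one of `"sif"`, `"tsv"`, `"graphml"`.
#' @export
write_network <- function(edges, path, format = c("tsv", "sif", "graphml")) {
  stopifnot(inherits(edges, "bipartite_edges"))
  format <- match.arg(format)
  if (format == "sif") {
    lines <- sprintf("%s\t%s\t%s", edges$gene,
                     ifelse(edges$r < 0, "neg", "pos"), edges$metabolite)
    writeLines(lines, path, useBytes = TRUE)
  } else if (format == "tsv") {
    lines <- c("gene\tmetabolite\tr\tsign",
               if (nrow(edges))
                 sprintf("%s\t%s\t%.8f\t%s", edges$gene, edges$metabolite,
                         edges$r, ifelse(edges$r < 0, "neg", "pos")))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    nodes <- data.frame(
      name = c(unique(edges$gene), unique(edges$metabolite)),
      type = rep(c("gene", "metabolite"),
                 c(length(unique(edges$gene)),
                   length(unique(edges$metabolite)))),
      stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(
      data.frame(from = edges$gene, to = edges$metabolite,
                 weight = edges$r, stringsAsFactors = FALSE),
      directed = FALSE, vertices = nodes)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a TSV network written by [write_network()]
#' @param path path to the TSV file.
#' @return a [bipartite_edges()] object.
#' @export
read_network_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "", check.names = FALSE,
                          stringsAsFactors = FALSE)
  bipartite_edges(df$gene, df$metabolite, df$r)
}
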