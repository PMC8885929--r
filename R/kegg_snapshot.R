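#' KEGG snapshot flat-file dialect
#'
#' A snapshot is a frozen local copy of the KEGG relations the annotation
#' step needs, so that annotation is deterministic and runs offline. A
#' snapshot directory contains four tab-delimited files, each starting with
#' the versioned header line `# gmlink-kegg-snapshot v1 <organism>`:
#' \describe{
#'   \item{compounds.tsv}{`compound_id <TAB> synonym`, one synonym per row;
#'     the first row of a compound gives its primary name.}
#'   \item{genes.tsv}{`gene_id <TAB> symbol`, one symbol/alias per row; the
#'     first row of a gene gives its primary symbol.}
#'   \item{pathways.tsv}{`pathway_id <TAB> pathway name`.}
#'   \item{pathway_members.tsv}{`pathway_id <TAB> member_id`; members
#'     matching `C\\d{5}` are compounds, all others are genes.}
#' }
#'
#' @param dir snapshot directory.
#' @return An object of class `kegg_snapshot`: a list with `organism`,
#'   `compounds` (named list compound_id -> synonyms), `genes` (named list
#'   gene_id -> symbols), `pathways` (named list pathway_id ->
#'   `list(name, genes, compounds)`).
#' @export
load_snapshot <- function(dir) {
  read2 <- function(file) {
    path <- file.path(dir, file)
    if (!file.exists(path)) stop("snapshot file missing: ", path)
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    if (!length(lines))
      return(data.frame(id = character(), value = character()))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(parts) != 2L))
      stop("malformed line(s) in ", path)
    data.frame(id = vapply(parts, `[[`, "", 1L),
               value = vapply(parts, `[[`, "", 2L),
               stringsAsFactors = FALSE)
  }
  header <- readLines(file.path(dir, "compounds.tsv"), n = 1L,
                      encoding = "UTF-8", warn = FALSE)
  organism <- if (startsWith(header, "# gmlink-kegg-snapshot"))
    utils::tail(strsplit(trimws(header), "[ ]+")[[1]], 1L) else NA_character_

  comp <- read2("compounds.tsv")
  gene <- read2("genes.tsv")
  pw <- read2("pathways.tsv")
  mem <- read2("pathway_members.tsv")

  compounds <- split(comp$value, factor(comp$id, levels = unique(comp$id)))
  genes <- split(gene$value, factor(gene$id, levels = unique(gene$id)))
  if (any(!lengths(compounds)) || any(!lengths(genes)))
    stop("empty synonym list in snapshot")

  is_comp <- grepl("^C[0-9]{5}$", mem$value)
  orphan <- c(setdiff(mem$value[is_comp], names(compounds)),
              setdiff(mem$value[!is_comp], names(genes)),
              setdiff(mem$id, pw$id))
  if (length(orphan))
    stop("dangling pathway member(s)/pathway(s) in snapshot: ",
         paste(unique(orphan), collapse = ", "))

  pathways <- lapply(seq_len(nrow(pw)), function(i) {
    rows <- mem$id == pw$id[i]
    list(name = pw$value[i],
         genes = mem$value[rows & !is_comp],
         compounds = mem$value[rows & is_comp])
  })
  names(pathways) <- pw$id

  structure(list(organism = organism, compounds = compounds, genes = genes,
                 pathways = pathways),
            class = "kegg_snapshot")
}

#' Write a snapshot to flat files
#'
#' @param snapshot a `kegg_snapshot`.
#' @param dir output directory (created if needed).
#' @export
write_snapshot <- function(snapshot, dir) {
  stopifnot(inherits(snapshot, "kegg_snapshot"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- sprintf("# gmlink-kegg-snapshot v1 %s", snapshot$organism)
  dump2 <- function(x, file) {
    lines <- c(hdr, unlist(lapply(names(x), function(id)
      sprintf("%s\t%s", id, x[[id]])), use.names = FALSE))
    writeLines(lines, file.path(dir, file), useBytes = TRUE)
  }
  dump2(snapshot$compounds, "compounds.tsv")
  dump2(snapshot$genes, "genes.tsv")
  dump2(lapply(snapshot$pathways, `[[`, "name"), "pathways.tsv")
  dump2(lapply(snapshot$pathways, function(p) c(p$genes, p$compounds)),
        "pathway_members.tsv")
  invisible(dir)
}

#' @export
print.kegg_snapshot <- function(x, ...) {
  cat(sprintf("kegg_snapshot (%s): %d compounds, %d genes, %d pathways\n",
              x$organism, length(x$compounds), length(x$genes),
              length(x$pathways)))
  invisible(x)
}

#' Fetch a KEGG snapshot over the REST API (optional, online)
#'
#' Downloads compound names, gene symbols and pathway membership for one
#' organism from the KEGG REST service and writes them in the snapshot
#' dialect, so a later [load_snapshot()] is fully offline and reproducible.
#' KEGG content drifts over time; the cached snapshot, not the live
#' service, is the authoritative input of every analysis. This function is
#' never needed for the bundled fixtures and requires network access.
#'
#' @param organism KEGG organism code (e.g. `"cel"`).
#' @param dir directory to write the snapshot into.
#' @param base_url KEGG REST endpoint.
#' @return the directory, invisibly.
#' @export
fetch_kegg_snapshot <- function(organism, dir,
                                base_url = "https://rest.kegg.jp") {
  get <- function(op) readLines(url(sprintf("%s/%s", base_url, op)),
                                warn = FALSE, encoding = "UTF-8")
  split2 <- function(lines) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    data.frame(id = vapply(parts, `[[`, "", 1L),
               value = vapply(parts, `[[`, "", 2L),
               stringsAsFactors = FALSE)
  }
  strip <- function(x) sub("^[a-z]+:", "", x)

  comp <- split2(get("list/compound"))
  compounds <- lapply(strsplit(comp$value, "; ", fixed = TRUE), trimws)
  names(compounds) <- strip(comp$id)

  gen <- split2(get(sprintf("list/%s", organism)))
  # KEGG gene entries: "symbol1, symbol2; description"
  syms <- sub(";.*$", "", gen$value)
  genes <- lapply(strsplit(syms, ", ", fixed = TRUE), trimws)
  names(genes) <- gen$id

  pw <- split2(get(sprintf("list/pathway/%s", organism)))
  pw$id <- strip(pw$id)
  link_g <- split2(get(sprintf("link/pathway/%s", organism)))
  link_c <- split2(get("link/pathway/compound"))
  pathways <- lapply(pw$id, function(pid) {
    gm <- link_g$id[strip(link_g$value) == pid]
    generic <- sub(sprintf("^%s", organism), "map", pid)
    cm <- strip(link_c$id[strip(link_c$value) %in% c(pid, generic)])
    list(name = pw$value[match(pid, pw$id)],
         genes = intersect(gm, names(genes)),
         compounds = intersect(cm, names(compounds)))
  })
  names(pathways) <- pw$id

  snap <- structure(list(organism = organism, compounds = compounds,
                         genes = genes, pathways = pathways),
                    class = "kegg_snapshot")
  write_snapshot(snap, dir)
}
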