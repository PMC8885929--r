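#' Normalize a metabolite name
#'
#' Free-text metabolite names are the main obstacle to KEGG mapping: the
#' same compound appears as "L-Valine", "l valine" or "Valine" depending on
#' the upstream annotation software. This canonical form makes those
#' variants collide. The transformation is deterministic and idempotent:
#' lowercase, trim, collapse internal whitespace, unify punctuation (en/em
#' dashes to "-", curly quotes to straight), strip one pair of enclosing
#' quotes, spell out Greek letters ("α" to "alpha"), and optionally
#' strip a leading stereo-descriptor ("L-", "D-", "DL-", "(S)-", "(R)-").
#'
#' Stereo stripping is on by default because stereo prefixes are the most
#' common mismatch between measured names and KEGG synonyms; the raw name
#' is always preserved alongside the match in annotation output.
#'
#' @param x character vector of raw names.
#' @param strip_stereo strip leading stereo-descriptors?
#' @param stereo_prefixes descriptors removed (matched after lowercasing,
#'   longest first, repeatedly, so "dl-l-x" reduces fully and the function
#'   stays idempotent).
#' @return character vector of normalized names (empty in, empty out).
#' @export
normalize_name <- function(x, strip_stereo = TRUE,
                           stereo_prefixes = c("l-", "d-", "dl-",
                                               "(s)-", "(r)-")) {
  greek <- c("α" = "alpha", "Α" = "alpha",
             "β" = "beta",  "Β" = "beta",
             "γ" = "gamma", "Γ" = "gamma",
             "δ" = "delta", "Δ" = "delta",
             "ε" = "epsilon", "Ε" = "epsilon",
             "ω" = "omega", "Ω" = "omega")
  x <- enc2utf8(as.character(x))
  for (g in names(greek)) x <- gsub(g, greek[[g]], x, fixed = TRUE)
  # punctuation variants: en/em dash, minus sign -> "-"; curly quotes
  x <- gsub("[–—−]", "-", x)
  x <- gsub("[‘’]", "'", x)
  x <- gsub("[“”]", "\"", x)
  x <- tolower(x)
  x <- gsub("[[:space:]]+", " ", x)
  x <- trimws(x)
  # strip one pair of enclosing straight quotes
  x <- sub("^\"(.*)\"$", "\\1", x)
  x <- sub("^'(.*)'$", "\\1", x)
  x <- trimws(x)
  if (strip_stereo && length(stereo_prefixes)) {
    pref <- stereo_prefixes[order(-nchar(stereo_prefixes))]
    repeat {
      hit <- rep(FALSE, length(x))
      for (p in pref) {
        m <- startsWith(x, p) & nchar(x) > nchar(p)
        x[m] <- substring(x[m], nchar(p) + 1L)
        hit <- hit | m
      }
      if (!any(hit)) break
    }
    x <- trimws(x)
  }
  x
}

name_tokens <- function(x) {
  toks <- strsplit(x, "[^a-z0-9]+")
  lapply(toks, function(t) unique(t[nzchar(t)]))
}

# Flat synonym index for a snapshot: one row per (compound, synonym).
synonym_index <- function(snapshot, strip_stereo = TRUE) {
  ids <- rep(names(snapshot$compounds), lengths(snapshot$compounds))
  syn <- unlist(snapshot$compounds, use.names = FALSE)
  data.frame(compound_id = ids, synonym = syn,
             norm = normalize_name(syn, strip_stereo = strip_stereo),
             stringsAsFactors = FALSE)
}

#' Match a metabolite name against a KEGG snapshot
#'
#' Three-stage cascade, stopping at the first stage that yields candidates:
#' \enumerate{
#'   \item exact match of the normalized name against a normalized synonym
#'     (score 1.0; only exact candidates are ever scored 1.0);
#'   \item token-subset match: every token of the query occurs in the
#'     synonym's token set or vice versa; scored by the Jaccard index of
#'     the token sets (capped just below 1 so fuzzy never outranks exact);
#'     this stage is gated by the subset condition itself, not by
#'     `min_score`, so reordered or partially qualified names still match;
#'   \item character similarity, 1 - levenshtein/max(nchar), kept only
#'     when at least `min_score`.
#' }
#' An empty candidate list means the name is unmatched (the caller flags
#' it, nothing is dropped silently). The default `min_score` 0.85 is
#' conservative: the exact and token stages resolve the common
#' case/stereo/spelling variants, and a high threshold on the
#' edit-distance stage avoids mapping unrelated short names.
#'
#' @param raw a single raw metabolite name.
#' @param snapshot a `kegg_snapshot` (or a prebuilt index from repeated
#'   calls, see [annotate_metabolites()]).
#' @param min_score minimum score for fuzzy candidates.
#' @param strip_stereo passed to [normalize_name()].
#' @return list of class `name_match`: `raw_name`, `normalized_name`,
#'   `candidates` (data.frame `compound_id`, `score`, `matched_synonym`,
#'   sorted by score descending, ties by compound id).
#' @export
match_metabolite <- function(raw, snapshot, min_score = 0.85,
                             strip_stereo = TRUE) {
  idx <- if (is.data.frame(snapshot)) snapshot
         else synonym_index(snapshot, strip_stereo = strip_stereo)
  q <- normalize_name(raw, strip_stereo = strip_stereo)
  cand <- NULL

  exact <- idx$norm == q & nzchar(q)
  if (any(exact)) {
    cand <- data.frame(compound_id = idx$compound_id[exact], score = 1,
                       matched_synonym = idx$synonym[exact],
                       stringsAsFactors = FALSE)
  } else if (nzchar(q)) {
    qt <- name_tokens(q)[[1]]
    st <- name_tokens(idx$norm)
    inter <- vapply(st, function(t) length(intersect(qt, t)), 0L)
    uni <- vapply(st, function(t) length(union(qt, t)), 0L)
    subset_ok <- inter == length(qt) | inter == lengths(st)
    jac <- ifelse(uni > 0, inter / uni, 0)
    score <- pmin(jac, 0.999)  # never ties with an exact match
    tok <- subset_ok & inter > 0
    if (any(tok)) {
      cand <- data.frame(compound_id = idx$compound_id[tok],
                         score = score[tok],
                         matched_synonym = idx$synonym[tok],
                         stringsAsFactors = FALSE)
    } else {
      d <- as.integer(utils::adist(q, idx$norm))
      sim <- 1 - d / pmax(nchar(q), nchar(idx$norm))
      sim <- pmin(sim, 0.999)
      fz <- sim >= min_score
      if (any(fz))
        cand <- data.frame(compound_id = idx$compound_id[fz],
                           score = sim[fz],
                           matched_synonym = idx$synonym[fz],
                           stringsAsFactors = FALSE)
    }
  }
  if (is.null(cand))
    cand <- data.frame(compound_id = character(), score = numeric(),
                       matched_synonym = character(),
                       stringsAsFactors = FALSE)
  # best synonym per compound, sorted by score then id for determinism
  cand <- cand[order(-cand$score, cand$compound_id, method = "radix"), ,
               drop = FALSE]
  cand <- cand[!duplicated(cand$compound_id), , drop = FALSE]
  rownames(cand) <- NULL
  structure(list(raw_name = raw, normalized_name = q, candidates = cand),
            class = "name_match")
}

#' @export
print.name_match <- function(x, ...) {
  cat(sprintf("'%s' -> '%s': %d candidate(s)\n", x$raw_name,
              x$normalized_name, nrow(x$candidates)))
  if (nrow(x$candidates)) print(utils::head(x$candidates, 5))
  invisible(x)
}

#' Assign metabolite classes
#'
#' Lipids measured at formula-level resolution (all sphingomyelins, all
#' phosphatidylcholines, ...) cannot be told apart by a single KEGG
#' compound; they are deliberately collapsed to one class with a
#' class-level KEGG identifier so they enter pathway integration as a
#' group. Rules are applied in order; the first matching rule wins and
#' overlaps are logged.
#'
#' @param raw_names character vector of metabolite names.
#' @param class_rules data.frame with columns `pattern`, `class_label`,
#'   `class_kegg_id` and optionally logical `regex` (default FALSE: the
#'   pattern is a literal, case-insensitive substring such as the lipid
#'   shorthand prefix "SM(").
#' @return data.frame `name`, `class_label`, `class_kegg_id` (NA where no
#'   rule matches), one row per input name.
#' @export
assign_metabolite_class <- function(raw_names, class_rules) {
  stopifnot(all(c("pattern", "class_label", "class_kegg_id") %in%
                  names(class_rules)))
  rx <- if ("regex" %in% names(class_rules)) class_rules$regex
        else rep(FALSE, nrow(class_rules))
  out <- data.frame(name = raw_names, class_label = NA_character_,
                    class_kegg_id = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_along(raw_names)) {
    hits <- which(vapply(seq_len(nrow(class_rules)), function(j) {
      if (rx[j]) grepl(class_rules$pattern[j], raw_names[i],
                       ignore.case = TRUE)
      else grepl(tolower(class_rules$pattern[j]), tolower(raw_names[i]),
                 fixed = TRUE)
    }, logical(1)))
    if (length(hits) > 1L)
      message("'", raw_names[i], "' matches ", length(hits),
              " class rules; keeping first ('",
              class_rules$class_label[hits[1]], "')")
    if (length(hits)) {
      out$class_label[i] <- class_rules$class_label[hits[1]]
      out$class_kegg_id[i] <- class_rules$class_kegg_id[hits[1]]
    }
  }
  out
}

#' Annotate metabolite names
#'
#' Runs the matching cascade over a vector of names and assembles the
#' annotation table used downstream. Every input name yields exactly one
#' row; unmatched names keep an empty `kegg_id`. Where class rules match, a
#' name's class label and class-level KEGG id override the per-compound
#' match (ambiguous lipids are meant to be analyzed as a class).
#'
#' @param raw_names character vector of metabolite names.
#' @param snapshot a `kegg_snapshot`.
#' @param min_score,strip_stereo see [match_metabolite()].
#' @param class_rules optional rules for [assign_metabolite_class()].
#' @return `annotation_table` data.frame: `feature_id`, `kegg_id`,
#'   `match_score`, `class_label`, `pathway_ids` (semicolon-joined),
#'   `ambiguous` (more than one candidate), `matched_synonym`.
#' @export
annotate_metabolites <- function(raw_names, snapshot, min_score = 0.85,
                                 strip_stereo = TRUE, class_rules = NULL) {
  idx <- synonym_index(snapshot, strip_stereo = strip_stereo)
  n <- length(raw_names)
  out <- data.frame(feature_id = raw_names,
                    kegg_id = character(n), match_score = rep(NA_real_, n),
                    class_label = NA_character_,
                    pathway_ids = character(n),
                    ambiguous = logical(n),
                    matched_synonym = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    m <- match_metabolite(raw_names[i], idx, min_score = min_score,
                          strip_stereo = strip_stereo)
    if (nrow(m$candidates)) {
      out$kegg_id[i] <- m$candidates$compound_id[1]
      out$match_score[i] <- m$candidates$score[1]
      out$matched_synonym[i] <- m$candidates$matched_synonym[1]
      out$ambiguous[i] <- nrow(m$candidates) > 1L
    }
  }
  if (!is.null(class_rules)) {
    cls <- assign_metabolite_class(raw_names, class_rules)
    hit <- !is.na(cls$class_label)
    out$class_label[hit] <- cls$class_label[hit]
    out$kegg_id[hit] <- cls$class_kegg_id[hit]
    out$match_score[hit] <- 1
  }
  class(out) <- c("annotation_table", "data.frame")
  annotate_pathways(out, snapshot)
}

#' Cross-reference gene symbols to KEGG genes
#'
#' Symbols are matched case-insensitively against each KEGG gene's primary
#' symbol first, then against its aliases. A symbol matching several KEGG
#' genes is reported once per gene and flagged ambiguous; unknown symbols
#' are retained with an empty `kegg_id` so nothing is dropped silently.
#'
#' @param symbols character vector of gene symbols.
#' @param snapshot a `kegg_snapshot`.
#' @return `annotation_table` data.frame as in [annotate_metabolites()]
#'   (without `matched_synonym`), pathways filled in.
#' @export
map_genes <- function(symbols, snapshot) {
  gids <- rep(names(snapshot$genes), lengths(snapshot$genes))
  als <- tolower(unlist(snapshot$genes, use.names = FALSE))
  primary <- tolower(vapply(snapshot$genes, `[[`, "", 1L))

  rows <- lapply(symbols, function(s) {
    sl <- tolower(s)
    hit <- names(snapshot$genes)[primary == sl]
    score <- 1
    if (!length(hit)) hit <- unique(gids[als == sl])
    if (!length(hit))
      return(data.frame(feature_id = s, kegg_id = "",
                        match_score = NA_real_, class_label = NA_character_,
                        pathway_ids = "", ambiguous = FALSE,
                        stringsAsFactors = FALSE))
    data.frame(feature_id = s, kegg_id = hit, match_score = score,
               class_label = NA_character_, pathway_ids = "",
               ambiguous = length(hit) > 1L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("annotation_table", "data.frame")
  annotate_pathways(out, snapshot)
}

#' Fill pathway membership into an annotation table
#'
#' Looks up each resolved KEGG id in the snapshot's pathway membership and
#' writes the semicolon-joined pathway ids. Features whose KEGG id belongs
#' to no pathway keep an empty list but stay in the table: downstream tools
#' that don't need pathways (module clustering, the correlation network)
#' still use them.
#'
#' @param annotation an `annotation_table`.
#' @param snapshot a `kegg_snapshot`.
#' @return the annotation with `pathway_ids` filled.
#' @export
annotate_pathways <- function(annotation, snapshot) {
  by_member <- list()
  for (pid in names(snapshot$pathways)) {
    p <- snapshot$pathways[[pid]]
    for (m in c(p$genes, p$compounds))
      by_member[[m]] <- c(by_member[[m]], pid)
  }
  annotation$pathway_ids <- vapply(annotation$kegg_id, function(k) {
    if (!nzchar(k) || is.na(k)) return("")
    paste(sort(unique(by_member[[k]])), collapse = ";")
  }, "", USE.NAMES = FALSE)
  annotation
}

#' Split the semicolon-joined pathway column
#' @param annotation an `annotation_table`.
#' @return named list feature_id -> character vector of pathway ids.
#' @export
pathway_sets <- function(annotation) {
  out <- strsplit(annotation$pathway_ids, ";", fixed = TRUE)
  out <- lapply(out, function(x) x[nzchar(x)])
  names(out) <- annotation$feature_id
  out
}

#' Write / read an annotation table
#'
#' TSV with columns featureID, keggID, score, class, pathwayIDs
#' (semicolon-joined), ambiguous.
#' @param annotation an `annotation_table`.
#' @param path file path.
#' @export
write_annotation <- function(annotation, path) {
  out <- data.frame(featureID = annotation$feature_id,
                    keggID = annotation$kegg_id,
                    score = ifelse(is.na(annotation$match_score), "",
                                   sprintf("%.6f", annotation$match_score)),
                    class = ifelse(is.na(annotation$class_label), "",
                                   annotation$class_label),
                    pathwayIDs = annotation$pathway_ids,
                    ambiguous = annotation$ambiguous,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "", check.names = FALSE,
                          colClasses = "character", fileEncoding = "UTF-8")
  out <- data.frame(feature_id = df$featureID, kegg_id = df$keggID,
                    match_score = suppressWarnings(as.numeric(df$score)),
                    class_label = ifelse(nzchar(df$class), df$class,
                                         NA_character_),
                    pathway_ids = df$pathwayIDs,
                    ambiguous = df$ambiguous == "TRUE",
                    stringsAsFactors = FALSE)
  class(out) <- c("annotation_table", "data.frame")
  out
}
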