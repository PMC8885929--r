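#' Construct a feature table
#'
#' A feature table is the basic container of the package: a numeric matrix of
#' abundances or expression values with features (genes or metabolites) in
#' rows and samples in columns, carrying unique feature and sample
#' identifiers. Values may be on any consistent scale (the package never
#' normalizes them); all downstream statistics are second-moment methods
#' operating across samples.
#'
#' @param values numeric matrix, features x samples.
#' @param feature_ids character vector of unique feature identifiers; taken
#'   from `rownames(values)` when missing.
#' @param sample_ids character vector of unique sample identifiers; taken
#'   from `colnames(values)` when missing.
#' @return An object of class `feature_table`: the numeric matrix with
#'   `dimnames` set to the identifiers.
#' @examples
#' ft <- feature_table(matrix(rnorm(6), 3, 2,
#'   dimnames = list(c("m1", "m2", "m3"), c("s1", "s2"))))
#' dim(ft)
#' @export
feature_table <- function(values, feature_ids = rownames(values),
                          sample_ids = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("feature table values must be numeric")
  if (is.null(feature_ids)) stop("feature_ids missing and values has no rownames")
  if (is.null(sample_ids)) stop("sample_ids missing and values has no colnames")
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (length(feature_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop("identifier lengths do not match matrix dimensions")
  dup <- unique(feature_ids[duplicated(feature_ids)])
  if (length(dup))
    stop("duplicated feature IDs: ", paste(dup, collapse = ", "))
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup))
    stop("duplicated sample IDs: ", paste(dup, collapse = ", "))
  if (any(!is.finite(values)))
    stop("feature table contains non-finite values; apply a missing-value ",
         "policy first (see read_wide_dataset)")
  dimnames(values) <- list(feature_ids, sample_ids)
  structure(values, class = c("feature_table", "matrix", "array"))
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d features x %d samples\n", nrow(x), ncol(x)))
  utils::str(unclass(x))
  invisible(x)
}

#' Read a wide-format dataset
#'
#' Reads a tab-delimited features-x-samples table with a header row. One
#' column (`id_column`) carries the unique feature identifier; every other
#' column is treated as a sample. Values are parsed with "." as the decimal
#' separator only, with no thousands separators, so files round-trip
#' bit-exactly across locales.
#'
#' @param path path to a tab-delimited UTF-8 text file.
#' @param id_column name of the unique-identifier column.
#' @param missing policy for cells that are empty, "NA" or non-numeric:
#'   `"drop"` removes any feature with a missing value (logged via
#'   `message()`), `"error"` aborts. Correlation and PCA downstream require
#'   complete rows, so dropping is the default.
#' @return A [feature_table()].
#' @export
read_wide_dataset <- function(path, id_column, missing = c("drop", "error")) {
  missing <- match.arg(missing)
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "", check.names = FALSE,
                          colClasses = "character", fileEncoding = "UTF-8")
  if (!id_column %in% names(df))
    stop("id column '", id_column, "' not found in ", path)
  ids <- df[[id_column]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicated feature IDs in ", path, ": ", paste(dup, collapse = ", "))
  sample_cols <- setdiff(names(df), id_column)
  if (!length(sample_cols)) stop("no sample columns in ", path)
  vals <- suppressWarnings(
    vapply(df[sample_cols], as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1L) vals <- matrix(vals, nrow = 1L,
                                     dimnames = list(NULL, sample_cols))
  bad <- !is.finite(vals)
  if (any(bad)) {
    bad_feat <- ids[rowSums(bad) > 0]
    if (missing == "error")
      stop("missing or non-numeric values for features: ",
           paste(bad_feat, collapse = ", "))
    message("dropping ", length(bad_feat),
            " feature(s) with missing values: ",
            paste(utils::head(bad_feat, 10), collapse = ", "),
            if (length(bad_feat) > 10) ", ...")
    keep <- rowSums(bad) == 0
    vals <- vals[keep, , drop = FALSE]
    ids <- ids[keep]
  }
  feature_table(vals, feature_ids = ids, sample_ids = sample_cols)
}

#' Write a wide-format dataset
#'
#' Inverse of [read_wide_dataset()]. Values are written with 17 significant
#' digits so a write-then-read round trip reproduces every double bit for
#' bit.
#'
#' @param table a [feature_table()].
#' @param path output path.
#' @param id_column header used for the identifier column.
#' @export
write_wide_dataset <- function(table, path, id_column = "uniqID") {
  stopifnot(inherits(table, "feature_table"))
  m <- unclass(table)
  txt <- apply(m, 2L, function(col) sprintf("%.17g", col))
  if (nrow(m) == 1L) txt <- matrix(txt, nrow = 1L)
  out <- cbind(rownames(m), txt)
  colnames(out) <- c(id_column, colnames(m))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a design table
#'
#' A design table maps each sample to an experimental group. Groups are kept
#' as character labels; no contrasts or statistics are derived from them
#' here (differential testing happens upstream of this package).
#'
#' @param path tab-delimited file with a header.
#' @param sample_column,group_column column names for samples and groups.
#' @return data.frame of class `design_table` with columns `sample_id`,
#'   `group`.
#' @export
read_design <- function(path, sample_column = "sampleID",
                        group_column = "group") {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "", check.names = FALSE,
                          colClasses = "character", fileEncoding = "UTF-8")
  for (col in c(sample_column, group_column))
    if (!col %in% names(df)) stop("column '", col, "' not found in ", path)
  out <- data.frame(sample_id = df[[sample_column]],
                    group = df[[group_column]],
                    stringsAsFactors = FALSE)
  dup <- unique(out$sample_id[duplicated(out$sample_id)])
  if (length(dup))
    stop("duplicated sample(s) in design: ", paste(dup, collapse = ", "))
  class(out) <- c("design_table", "data.frame")
  out
}

#' Write a design table
#' @param design a `design_table` (or data.frame with `sample_id`, `group`).
#' @param path output path.
#' @export
write_design <- function(design, path) {
  out <- data.frame(sampleID = design$sample_id, group = design$group)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Check a design against a feature table
#'
#' Every sample of the feature table must appear exactly once in the design.
#' Design rows for samples absent from the table are allowed (a design may
#' cover a superset, e.g. samples dropped during QC) and are ignored with a
#' logged message.
#'
#' @param table a [feature_table()].
#' @param design a `design_table`.
#' @return the design restricted to the table's samples, in table order.
#' @export
align_design <- function(table, design) {
  miss <- setdiff(colnames(table), design$sample_id)
  if (length(miss))
    stop("samples missing from design: ", paste(miss, collapse = ", "))
  extra <- setdiff(design$sample_id, colnames(table))
  if (length(extra))
    message("ignoring ", length(extra), " design sample(s) not in the data: ",
            paste(extra, collapse = ", "))
  out <- design[match(colnames(table), design$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drop constant features
#'
#' Features with zero variance across samples carry no correlation signal
#' and would produce undefined correlations; they are removed with a logged
#' message before any correlation or PCA step.
#'
#' @param table a [feature_table()].
#' @return the table without constant features.
#' @export
drop_constant_features <- function(table) {
  v <- apply(unclass(table), 1L, function(x) max(x) - min(x))
  const <- v == 0
  if (any(const)) {
    message("dropping ", sum(const), " constant feature(s): ",
            paste(utils::head(rownames(table)[const], 10), collapse = ", "))
    table <- feature_table(unclass(table)[!const, , drop = FALSE])
  }
  table
}
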