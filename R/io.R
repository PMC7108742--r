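## Readers/writers for the two input tables and the analysis-organized output
## tree. Delimiter is chosen by extension (.csv -> comma, anything else ->
## tab); missing-value tokens "", "NA", "NaN", "nan" cover both R and Python
## exports.

.missing_tokens <- c("", "NA", "NaN", "nan")

.delim_for <- function(path) {
  if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
}

#' Read an expression/abundance matrix from TSV/CSV
#'
#' Expects variable IDs in the first column and a header row of sample IDs.
#' Empty cells and the tokens `NA`, `NaN`, `nan` are parsed as missing.
#'
#' @param path file path; `.csv` is comma-separated, anything else
#'   tab-separated.
#' @param datatype data-type tag, see [expr_matrix()].
#' @param transpose set to `TRUE` when the file is samples x variables.
#' @return an [expr_matrix()].
#' @export
read_expression_matrix <- function(path, datatype = c("array", "seq", "ms", "other"),
                                   transpose = FALSE) {
  datatype <- match.arg(datatype)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = .delim_for(path),
                          na.strings = .missing_tokens, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "")
  if (ncol(df) < 2) stop("matrix file needs an ID column plus >= 1 sample column")
  ids <- df[[1L]]
  body <- df[, -1L, drop = FALSE]
  vals <- matrix(NA_real_, nrow(body), ncol(body),
                 dimnames = list(ids, colnames(body)))
  for (j in seq_len(ncol(body))) {
    cell <- body[[j]]
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(num) & !is.na(cell))
    if (length(bad))
      stop(sprintf("non-numeric value %s at row '%s', column '%s'",
                   dQuote(cell[bad[1L]]), ids[bad[1L]], colnames(body)[j]))
    vals[, j] <- num
  }
  if (transpose) vals <- t(vals)
  if (datatype == "seq") {
    ok <- !is.na(vals)
    bad <- which(ok & (vals < 0 | vals != floor(vals)), arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("datatype 'seq' forbids value %g at row '%s', column '%s'",
                   vals[bad[1L, 1L], bad[1L, 2L]],
                   rownames(vals)[bad[1L, 1L]], colnames(vals)[bad[1L, 2L]]))
  }
  expr_matrix(vals, datatype)
}

#' Write an expression matrix as TSV
#'
#' Values are written with full `%.17g`-style precision so a write/read
#' round-trip reproduces finite entries bit-identically.
#'
#' @param x an [expr_matrix()] (or plain named matrix).
#' @param path output path; delimiter by extension as in
#'   [read_expression_matrix()].
#' @export
write_expression_matrix <- function(x, path) {
  body <- apply(unclass(x), 2, function(col)
    ifelse(is.na(col), "NA", sprintf("%.17g", col)))
  if (is.null(dim(body))) body <- matrix(body, nrow = nrow(x), dimnames = dimnames(x))
  df <- cbind(data.frame(id = rownames(x), stringsAsFactors = FALSE),
              as.data.frame(body, stringsAsFactors = FALSE, check.names = FALSE))
  utils::write.table(df, path, sep = .delim_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read per-sample metadata
#'
#' The metadata table must contain a sample-ID column and a group column.
#' Survival columns are auto-detected by the exact names `age`,
#' `outcome.time` and `outcome`; the survival triplet must be all present or
#' all absent, `outcome` must lie in \{0, 1\} and `outcome.time` must be
#' positive.
#'
#' @param path file path (delimiter by extension).
#' @param id_col name of the sample-ID column.
#' @param group_col name of the group column.
#' @return a `data.frame` of class `sample_metadata`, one row per sample, with
#'   attributes `id_col` and `group_col`.
#' @export
read_metadata <- function(path, id_col = "id", group_col = "group") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = .delim_for(path),
                          na.strings = .missing_tokens, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  as_sample_metadata(df, id_col = id_col, group_col = group_col)
}

#' @rdname read_metadata
#' @param df a data frame already in memory.
#' @export
as_sample_metadata <- function(df, id_col = "id", group_col = "group") {
  for (col in c(id_col, group_col))
    if (!col %in% names(df)) stop("metadata lacks column '", col, "'")
  ids <- as.character(df[[id_col]])
  if (anyDuplicated(ids))
    stop("duplicate sample IDs in metadata: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if ("outcome" %in% names(df)) {
    oc <- df$outcome[!is.na(df$outcome)]
    if (!all(oc %in% c(0, 1)))
      stop("`outcome` must be a 0/1 event indicator; saw: ",
           paste(unique(oc[!oc %in% c(0, 1)]), collapse = ", "))
  }
  surv_cols <- c("age", "outcome.time", "outcome")
  present <- surv_cols %in% names(df)
  if (any(present) && !all(present[2:3] == present[2]))
    stop("survival columns `outcome.time` and `outcome` must be supplied together")
  if ("outcome.time" %in% names(df)) {
    tt <- df[["outcome.time"]]
    if (any(!is.na(tt) & tt <= 0)) stop("`outcome.time` must be positive")
  }
  if ("age" %in% names(df) && any(!is.na(df$age) & df$age < 0))
    stop("`age` must be non-negative")
  rownames(df) <- ids
  structure(df, id_col = id_col, group_col = group_col,
            class = c("sample_metadata", "data.frame"))
}

#' Check that metadata and matrix describe the same samples
#'
#' @param x an [expr_matrix()].
#' @param meta a [read_metadata()] result.
#' @return `meta`, reordered to the matrix column order, invisibly errors on
#'   any mismatch (the symmetric difference is listed).
#' @export
check_samples <- function(x, meta) {
  ids_x <- colnames(x)
  ids_m <- as.character(meta[[attr(meta, "id_col")]])
  only_x <- setdiff(ids_x, ids_m)
  only_m <- setdiff(ids_m, ids_x)
  if (length(only_x) || length(only_m))
    stop("sample-ID mismatch; matrix-only: {",
         paste(only_x, collapse = ", "), "}, metadata-only: {",
         paste(only_m, collapse = ", "), "}")
  meta[match(ids_x, ids_m), , drop = FALSE]
}

#' Sample groups as a factor
#' @param meta a `sample_metadata`.
#' @return factor of group labels in metadata row order.
#' @export
sample_groups <- function(meta) factor(meta[[attr(meta, "group_col")]])

#' Write an analysis-organized output tree
#'
#' Results are laid out one subfolder per executed analysis
#' (`preprocess/`, `distcheck/`, `cluster/`, `dea/`, `select/`, `coexpr/`,
#' `survival/`, `network/`), each table as TSV, plus a `manifest.tsv` listing
#' every file written.
#'
#' @param results named list; each element is itself a named list of data
#'   frames (or matrices) for one analysis folder.
#' @param outdir output directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return character vector of relative paths written (the manifest),
#'   invisibly.
#' @export
write_output_tree <- function(results, outdir, overwrite = FALSE) {
  if (dir.exists(outdir) && length(dir(outdir, all.files = FALSE)) > 0 && !overwrite)
    stop("output directory ", outdir, " is not empty; use overwrite = TRUE")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- character(0)
  for (analysis in names(results)) {
    sub <- file.path(outdir, analysis)
    dir.create(sub, showWarnings = FALSE)
    tables <- results[[analysis]]
    for (nm in names(tables)) {
      tab <- tables[[nm]]
      rel <- file.path(analysis, paste0(nm, ".tsv"))
      if (is.matrix(tab))
        tab <- data.frame(id = rownames(tab) %||% seq_len(nrow(tab)), tab,
                          check.names = FALSE, stringsAsFactors = FALSE)
      utils::write.table(tab, file.path(outdir, rel), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      manifest <- c(manifest, rel)
    }
  }
  utils::write.table(data.frame(file = manifest), file.path(outdir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
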