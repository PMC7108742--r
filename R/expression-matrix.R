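#' Expression/abundance matrix container
#'
#' An `expr_matrix` wraps a numeric variables x samples matrix together with a
#' data-type tag that downstream stages use to pick the appropriate
#' normalization path. Row names are variable IDs, column names sample IDs;
#' both must be unique. `NA` entries are allowed before imputation. For the
#' `"seq"` data type all non-missing values must be non-negative integers
#' (raw counts).
#'
#' @param values numeric matrix, variables in rows, samples in columns, with
#'   unique row and column names.
#' @param datatype one of `"array"`, `"seq"`, `"ms"`, `"other"`.
#' @return an object of class `expr_matrix`: the value matrix with a
#'   `datatype` attribute.
#' @export
expr_matrix <- function(values, datatype = c("array", "seq", "ms", "other")) {
  datatype <- match.arg(datatype)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry variable IDs as rownames and sample IDs as colnames")
  dup_r <- rownames(values)[duplicated(rownames(values))]
  if (length(dup_r))
    stop("duplicate variable IDs: ", paste(unique(dup_r), collapse = ", "))
  dup_c <- colnames(values)[duplicated(colnames(values))]
  if (length(dup_c))
    stop("duplicate sample IDs: ", paste(unique(dup_c), collapse = ", "))
  if (datatype == "seq") {
    v <- values[!is.na(values)]
    if (any(v < 0) || any(v != floor(v)))
      stop("datatype 'seq' requires non-negative integer counts")
  }
  structure(values, datatype = datatype, class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix [%s]: %d variables x %d samples (%d missing cells)\n",
              attr(x, "datatype"), nrow(x), ncol(x), sum(is.na(x))))
  invisible(x)
}

#' @rdname expr_matrix
#' @param x object to test or coerce.
#' @export
is_expr_matrix <- function(x) inherits(x, "expr_matrix")

datatype_of <- function(x) attr(x, "datatype") %||% "other"

`%||%` <- function(a, b) if (is.null(a)) b else a

## keep class + datatype when subsetting
#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out))
    out <- structure(out, datatype = attr(x, "datatype"),
                     class = c("expr_matrix", "matrix", "array"))
  out
}

## replace the values but keep IDs/datatype
em_replace <- function(x, values) {
  dimnames(values) <- dimnames(x)
  structure(values, datatype = attr(x, "datatype"),
            class = c("expr_matrix", "matrix", "array"))
}
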