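# Observation tables: reading, validation, normalization (pipeline step 1).

#' Read a numeric observation table
#'
#' Reads a delimited text file of m observations on d continuous variables
#' into a tibble of doubles. The first line is treated as a header if and
#' only if at least one of its cells does not parse as a number; otherwise
#' columns are named `X1..Xd`.
#'
#' @param path Path to a CSV/TSV file (UTF-8, `.` decimal separator).
#' @param delimiter Field delimiter, default `","`.
#'
#' @return A tibble with m rows and d double columns.
#' @export
#'
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("a,b", "1,2", "3,4"), f)
#' read_dataset(f)
read_dataset <- function(path, delimiter = ",") {
  if (!file.exists(path)) {
    abort(paste0("input file does not exist: ", path), class = "rlcausal_io_error")
  }
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) {
    abort("input file is empty", class = "rlcausal_dimension_error")
  }
  cells <- strsplit(first, delimiter, fixed = TRUE)[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(cells)))
  df <- utils::read.table(
    path, sep = delimiter, header = has_header,
    colClasses = NA, stringsAsFactors = FALSE,
    check.names = FALSE, comment.char = ""
  )
  if (!has_header) names(df) <- paste0("X", seq_along(df))
  if (nrow(df) == 0L) {
    abort("no data rows after the header", class = "rlcausal_dimension_error")
  }
  for (j in seq_along(df)) {
    col <- df[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(col)))))[1]
      abort(
        sprintf("non-numeric cell at row %d, column '%s'", bad, names(df)[j]),
        class = "rlcausal_parse_error"
      )
    }
    df[[j]] <- as.numeric(col)
  }
  out <- tibble::as_tibble(df)
  validate_dataset(out)
  out
}

# Validate an observation table and return it as a plain double matrix.
# Enforces: all finite, m >= 2, d >= 2, unique column names.
as_dataset_matrix <- function(data) {
  if (is.matrix(data)) {
    x <- data
    if (is.null(colnames(x))) colnames(x) <- paste0("X", seq_len(ncol(x)))
  } else {
    x <- as.matrix(as.data.frame(data))
  }
  storage.mode(x) <- "double"
  if (nrow(x) < 2L || ncol(x) < 2L) {
    abort(
      sprintf("need at least 2 rows and 2 columns, got %d x %d", nrow(x), ncol(x)),
      class = "rlcausal_dimension_error"
    )
  }
  if (anyDuplicated(colnames(x))) {
    abort("column names must be unique", class = "rlcausal_dimension_error")
  }
  if (!all(is.finite(x))) {
    abort("all entries must be finite numbers", class = "rlcausal_parse_error")
  }
  x
}

validate_dataset <- function(data) {
  invisible(as_dataset_matrix(data))
}

#' Normalize each column of an observation table
#'
#' Per-column rescaling applied independently to every variable. The default,
#' min-max, maps each column onto \[0, 1\] (minimum to 0, maximum to 1) so that
#' the downstream spacing entropy estimates share a common bounded support and
#' the inverse-entropy strengths are comparable across variables; `"zscore"`
#' (mean 0, sd 1) is offered as an alternative. Min-max normalization is
#' idempotent and invariant to positive affine transforms of a column.
#'
#' @param data A data frame or matrix of finite numeric observations.
#' @param method `"minmax"` (default) or `"zscore"`.
#'
#' @return A tibble of the same shape.
#' @export
#'
#' @examples
#' normalize_dataset(data.frame(a = c(0, 5, 10), b = c(1, 2, 4)))
normalize_dataset <- function(data, method = c("minmax", "zscore")) {
  method <- match.arg(method)
  x <- as_dataset_matrix(data)
  rng <- apply(x, 2, function(v) diff(range(v)))
  if (any(rng == 0)) {
    abort(
      paste0(
        "constant column(s): ",
        paste(colnames(x)[rng == 0], collapse = ", "),
        " (normalization and entropy estimation are undefined)"
      ),
      class = "rlcausal_constant_column_error"
    )
  }
  y <- switch(method,
    minmax = apply(x, 2, function(v) (v - min(v)) / (max(v) - min(v))),
    zscore = scale(x)[, , drop = FALSE]
  )
  out <- tibble::as_tibble(as.data.frame(y))
  names(out) <- colnames(x)
  out
}
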