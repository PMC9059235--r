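#' ASV abundance tables
#'
#' An abundance table is a plain integer matrix of read counts with ASVs as
#' rows and samples as columns; `rownames()` carry the ASV identifiers and
#' `colnames()` the sample identifiers. All package functions accept and
#' return this representation (the convention of community-ecology packages
#' such as vegan, transposed: taxa in rows as in typical ASV-table exports).
#'
#' @name asv-table
NULL

#' Validate an ASV abundance table
#'
#' Checks the structural invariants every downstream stage relies on:
#' a numeric matrix of finite, non-negative, integral counts with unique,
#' non-empty ASV (row) and sample (column) identifiers.
#'
#' @param x matrix to validate.
#' @return the validated matrix with integer storage mode, invisibly.
#' @export
validate_asv_table <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("abundance table must be a numeric matrix (ASV rows x sample columns)")
  }
  if (is.null(rownames(x)) || anyNA(rownames(x)) || any(rownames(x) == "")) {
    stop("abundance table must have non-empty ASV row names")
  }
  if (is.null(colnames(x)) || anyNA(colnames(x)) || any(colnames(x) == "")) {
    stop("abundance table must have non-empty sample column names")
  }
  if (anyDuplicated(rownames(x))) {
    stop("duplicate ASV id: ", rownames(x)[duplicated(rownames(x))][1L])
  }
  if (anyDuplicated(colnames(x))) {
    stop("duplicate sample id: ", colnames(x)[duplicated(colnames(x))][1L])
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop("abundance table contains missing or non-finite counts")
  }
  if (any(x < 0)) {
    bad <- which(x < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative count at ASV '%s', sample '%s'",
                 rownames(x)[bad[1L]], colnames(x)[bad[2L]]))
  }
  if (any(x != round(x))) {
    bad <- which(x != round(x), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-integer count at ASV '%s', sample '%s'",
                 rownames(x)[bad[1L]], colnames(x)[bad[2L]]))
  }
  storage.mode(x) <- "integer"
  invisible(x)
}

#' Read an ASV abundance table from TSV
#'
#' Expects the common ASV-table export dialect: tab-separated, UTF-8, first
#' row a header, first column the ASV identifier, remaining columns one per
#' sample with non-negative integer cells. Input ordering of rows and
#' columns is preserved.
#'
#' @param path path to a TSV file.
#' @return validated abundance matrix (see [validate_asv_table()]).
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' m <- matrix(c(3L, 1L, 0L, 7L), 2, 2,
#'             dimnames = list(c("ASV1", "ASV2"), c("s1", "s2")))
#' write_abundance_table(m, tf)
#' identical(read_abundance_table(tf), m)
read_abundance_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L) {
    stop("malformed header in ", path,
         ": expected an ASV id column plus at least one sample column")
  }
  sample_ids <- header[-1L]
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample column in ", path, ": ",
         sample_ids[duplicated(sample_ids)][1L])
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          colClasses = c("character",
                                         rep("numeric", length(sample_ids))))
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  colnames(m) <- sample_ids
  validate_asv_table(m)
  storage.mode(m) <- "integer"
  m
}

#' Write an ASV abundance table to TSV
#'
#' Inverse of [read_abundance_table()]; `read(write(x))` is the identity.
#'
#' @param x abundance matrix.
#' @param path output path.
#' @param id_column header name of the ASV id column.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(x, path, id_column = "asv_id") {
  validate_asv_table(x)
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(id_column, colnames(x))
  write_tsv(df, path)
}
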