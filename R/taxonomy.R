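#' Taxonomy tables
#'
#' Taxonomy is a data frame with the column `asv_id` plus one column per
#' rank, ordered domain -> genus (species optional). Unannotated ranks hold
#' the literal token `"unclassified"`. ASVs referenced by an abundance
#' table but absent from the taxonomy are treated as unannotated and
#' reported by [validate_taxonomy()].
#'
#' @name taxonomy-table
NULL

.tax_ranks <- c("domain", "phylum", "class", "order", "family", "genus",
                "species")

#' Validate a taxonomy table
#'
#' @param tax taxonomy data frame (`asv_id` + rank columns).
#' @param table optional abundance matrix; when supplied, ASVs without a
#'   taxonomy entry are returned in the `unannotated` attribute and noted
#'   via `message()`.
#' @return the validated data frame, invisibly.
#' @export
validate_taxonomy <- function(tax, table = NULL) {
  if (!is.data.frame(tax)) stop("taxonomy must be a data frame")
  if (!"asv_id" %in% colnames(tax)) stop("taxonomy lacks asv_id column")
  ranks <- intersect(.tax_ranks, colnames(tax))
  if (!length(ranks)) {
    stop("taxonomy has no recognised rank column (",
         paste(.tax_ranks, collapse = ", "), ")")
  }
  if (anyDuplicated(tax$asv_id)) {
    stop("duplicate asv_id in taxonomy: ",
         tax$asv_id[duplicated(tax$asv_id)][1L])
  }
  unannotated <- character(0)
  if (!is.null(table)) {
    unannotated <- setdiff(rownames(table), tax$asv_id)
    if (length(unannotated)) {
      message(length(unannotated), " ASV(s) lack taxonomy annotation")
    }
  }
  attr(tax, "unannotated") <- unannotated
  invisible(tax)
}

#' Read a taxonomy table from TSV
#'
#' @param path TSV with `asv_id` plus one column per rank.
#' @return validated taxonomy data frame.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tax <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "", na.strings = "",
                           colClasses = "character")
  validate_taxonomy(tax)
  tax
}

#' Write a taxonomy table to TSV
#'
#' @param tax taxonomy data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(tax, path) {
  validate_taxonomy(tax)
  write_tsv(tax, path)
}

#' Genus lookup for a set of ASVs
#'
#' @param asv_ids character vector.
#' @param tax taxonomy data frame.
#' @return character vector of genera, `NA` where no annotation exists.
#' @keywords internal
genus_of <- function(asv_ids, tax) {
  if (!"genus" %in% colnames(tax)) {
    return(rep(NA_character_, length(asv_ids)))
  }
  tax$genus[match(asv_ids, tax$asv_id)]
}
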