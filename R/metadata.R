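#' Sample metadata for the nested replicate design
#'
#' Metadata is a data frame with one row per sequenced data set and the
#' columns `sample_id`, `material` (milk/water/mock/ntc), `protocol`
#' (P1..P6), `prototype` (the four SCC/cfu milk conditions),
#' `extraction_rep`, `sequencing_rep`, `primer_run` (V1V2/V3V4) and `phase`
#' (pretrial/main). Fields that do not apply to a material (e.g. prototype
#' for water controls) are `NA`. Design coordinates live only here; sample
#' ids are opaque strings and are never parsed.
#'
#' @name sample-metadata
NULL

.materials  <- c("milk", "water", "mock", "ntc")
.protocols  <- paste0("P", 1:6)
.prototypes <- c("SCC-cfu-", "SCC+cfu-", "SCC+cfu+", "SCC-cfu+")
.runs       <- c("V1V2", "V3V4")
.phases     <- c("pretrial", "main")

.meta_cols <- c("sample_id", "material", "protocol", "prototype",
                "extraction_rep", "sequencing_rep", "primer_run", "phase")

#' Validate sample metadata
#'
#' Enforces the controlled vocabularies and the per-material field rules:
#' milk rows carry protocol, prototype and extraction replicate; water rows
#' carry protocol and extraction replicate but no prototype; mock/ntc rows
#' carry neither. The design coordinates
#' (material, protocol, prototype, extraction_rep, sequencing_rep,
#' primer_run, phase) must be jointly unique, as must sample ids.
#'
#' @param meta metadata data frame.
#' @return the validated data frame, invisibly.
#' @export
validate_metadata <- function(meta) {
  if (!is.data.frame(meta)) stop("metadata must be a data frame")
  missing_cols <- setdiff(.meta_cols, colnames(meta))
  if (length(missing_cols)) {
    stop("metadata lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyNA(meta$sample_id) || any(meta$sample_id == "")) {
    stop("metadata has empty sample_id")
  }
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicate sample_id in metadata: ",
         meta$sample_id[duplicated(meta$sample_id)][1L])
  }
  check_vocab <- function(col, vocab, allow_na) {
    v <- meta[[col]]
    bad <- !(v %in% vocab) & !(allow_na & is.na(v))
    if (any(bad)) {
      stop(sprintf("unknown %s token '%s' (sample '%s')",
                   col, v[bad][1L], meta$sample_id[bad][1L]))
    }
  }
  check_vocab("material", .materials, allow_na = FALSE)
  check_vocab("protocol", .protocols, allow_na = TRUE)
  check_vocab("prototype", .prototypes, allow_na = TRUE)
  check_vocab("primer_run", .runs, allow_na = FALSE)
  check_vocab("phase", .phases, allow_na = FALSE)
  for (col in c("extraction_rep", "sequencing_rep")) {
    v <- meta[[col]]
    if (!is.numeric(v) || any(!is.na(v) & (v < 1 | v != round(v)))) {
      stop(col, " must be integer >= 1 (or absent)")
    }
  }
  if (anyNA(meta$sequencing_rep)) stop("sequencing_rep is required for all rows")

  requires <- function(rows, col, must_have, what) {
    v <- meta[[col]][rows]
    bad <- if (must_have) is.na(v) else !is.na(v)
    if (any(bad)) {
      stop(sprintf("%s record '%s' %s %s",
                   what, meta$sample_id[rows][bad][1L],
                   if (must_have) "lacks" else "must not carry", col))
    }
  }
  milk <- meta$material == "milk"
  water <- meta$material == "water"
  ctrl <- meta$material %in% c("mock", "ntc")
  requires(milk, "protocol", TRUE, "milk")
  requires(milk, "prototype", TRUE, "milk")
  requires(milk, "extraction_rep", TRUE, "milk")
  requires(water, "protocol", TRUE, "water")
  requires(water, "extraction_rep", TRUE, "water")
  requires(water, "prototype", FALSE, "water")
  requires(ctrl, "protocol", FALSE, "control")
  requires(ctrl, "prototype", FALSE, "control")
  requires(ctrl, "extraction_rep", FALSE, "control")

  key <- do.call(paste, c(meta[c("material", "protocol", "prototype",
                                 "extraction_rep", "sequencing_rep",
                                 "primer_run", "phase")], sep = "\r"))
  if (anyDuplicated(key)) {
    stop("duplicate design coordinates (sample '",
         meta$sample_id[duplicated(key)][1L], "')")
  }
  invisible(meta)
}

#' Read sample metadata from TSV
#'
#' Columns may appear in any order; extra columns are preserved. Empty
#' string cells map to `NA` ("absent").
#'
#' @param path path to a TSV file with the columns listed under
#'   [sample-metadata].
#' @return validated metadata data frame.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  meta <- utils::read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE,
                            quote = "", na.strings = "",
                            colClasses = "character")
  missing_cols <- setdiff(.meta_cols, colnames(meta))
  if (length(missing_cols)) {
    stop("metadata file lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in c("extraction_rep", "sequencing_rep")) {
    v <- suppressWarnings(as.numeric(meta[[col]]))
    if (any(is.na(v) & !is.na(meta[[col]]))) {
      stop(col, " must be integer")
    }
    meta[[col]] <- as.integer(v)
  }
  meta <- meta[, c(.meta_cols, setdiff(colnames(meta), .meta_cols)),
               drop = FALSE]
  validate_metadata(meta)
  meta
}

#' Write sample metadata to TSV
#'
#' @param meta metadata data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  validate_metadata(meta)
  write_tsv(meta, path)
}

#' Summarize the replicate design
#'
#' Counts, per primer run of the requested phase: data sets by material,
#' extraction data sets (milk + water), and per protocol the number of
#' distinct milk extracts and sequencing replicates per extract. Reports
#' only; never mutates.
#'
#' @param meta validated metadata.
#' @param phase `"pretrial"` or `"main"`.
#' @return a list keyed by primer run; each element has `n_milk`, `n_water`,
#'   `n_mock`, `n_ntc`, `n_extraction_data_sets`, `n_total` (all materials)
#'   and a `protocols` data frame (`protocol`, `n_extracts`,
#'   `seq_reps_per_extract`, `n_milk_data_sets`).
#' @export
summarize_design <- function(meta, phase) {
  validate_metadata(meta)
  phase <- match.arg(phase, .phases)
  meta <- meta[meta$phase == phase, , drop = FALSE]
  out <- list()
  for (run in .runs) {
    m <- meta[meta$primer_run == run, , drop = FALSE]
    milk <- m[m$material == "milk", , drop = FALSE]
    protos <- sort(unique(milk$protocol))
    ptab <- data.frame(protocol = protos,
                       n_extracts = rep(NA_integer_, length(protos)),
                       seq_reps_per_extract = rep(NA_integer_,
                                                  length(protos)),
                       n_milk_data_sets = rep(NA_integer_, length(protos)),
                       stringsAsFactors = FALSE)
    for (i in seq_along(protos)) {
      mp <- milk[milk$protocol == protos[i], , drop = FALSE]
      ptab$n_extracts[i] <- length(unique(mp$extraction_rep))
      ptab$seq_reps_per_extract[i] <- length(unique(mp$sequencing_rep))
      ptab$n_milk_data_sets[i] <- nrow(mp)
    }
    n_milk <- sum(m$material == "milk")
    n_water <- sum(m$material == "water")
    out[[run]] <- list(
      n_milk = n_milk,
      n_water = n_water,
      n_mock = sum(m$material == "mock"),
      n_ntc = sum(m$material == "ntc"),
      n_extraction_data_sets = n_milk + n_water,
      n_total = nrow(m),
      protocols = ptab
    )
  }
  out
}
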