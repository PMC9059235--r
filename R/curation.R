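#' Curation thresholds
#'
#' Bundles every threshold used by the curation rules. Defaults follow the
#' study conventions for low-biomass milk amplicon data: samples under 500
#' clean reads are dropped, taxa under 0.01% pooled relative abundance are
#' dropped, an ASV seen in more than two water (blank) replicates with at
#' least one count above 100 reads is flagged as a recurrent blank
#' contaminant, and protocols qualify for resequencing only above a median
#' of 1000 clean reads. All "less/more than" rules are strict inequalities.
#'
#' @param tau_depth minimum per-sample clean reads (samples with fewer are
#'   removed; default 500).
#' @param tau_rel minimum pooled relative abundance in percent (ASVs below
#'   are removed; default 0.01).
#' @param tau_flag_count per-replicate read threshold for blank flagging
#'   (rule is "> tau_flag_count"; default 100).
#' @param tau_flag_reps blank replicate-count threshold (rule is
#'   "> tau_flag_reps" replicates; default 2).
#' @param tau_median protocol-selection median clean-read threshold
#'   (rule is "> tau_median"; default 1000).
#' @param foreign_taxa character vector of genera considered implausible in
#'   the milk matrix (index-swap candidates from co-sequenced specimens).
#' @return an object of class `curation_params`.
#' @export
curation_params <- function(tau_depth = 500, tau_rel = 0.01,
                            tau_flag_count = 100, tau_flag_reps = 2,
                            tau_median = 1000,
                            foreign_taxa = character(0)) {
  p <- list(tau_depth = tau_depth, tau_rel = tau_rel,
            tau_flag_count = tau_flag_count, tau_flag_reps = tau_flag_reps,
            tau_median = tau_median,
            foreign_taxa = as.character(foreign_taxa))
  num <- c("tau_depth", "tau_rel", "tau_flag_count", "tau_flag_reps",
           "tau_median")
  for (f in num) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      stop(f, " must be a single non-negative number")
    }
  }
  if (p$tau_rel > 100) stop("tau_rel is a percentage and must be <= 100")
  structure(p, class = "curation_params")
}

#' Per-sample clean-read totals
#'
#' Clean reads are the column sums of the (post-denoising) ASV table.
#'
#' @param table abundance matrix.
#' @return named integer-valued numeric vector, one total per sample.
#' @export
clean_read_totals <- function(table) {
  validate_asv_table(table)
  colSums(table)
}

#' Remove low-depth samples
#'
#' Drops every sample whose clean-read total is strictly below
#' `params$tau_depth`; retained samples are untouched.
#'
#' @param table abundance matrix.
#' @param params [curation_params()].
#' @return list with `table` (filtered matrix) and `samples` (data frame
#'   `sample_id`, `disposition` in kept / removed:low_depth, `clean_reads`).
#' @export
apply_depth_filter <- function(table, params = curation_params()) {
  totals <- clean_read_totals(table)
  keep <- totals >= params$tau_depth
  if (!any(keep)) {
    warning("depth filter removed every sample (tau_depth = ",
            params$tau_depth, ")")
  }
  list(
    table = table[, keep, drop = FALSE],
    samples = data.frame(
      sample_id = colnames(table),
      disposition = ifelse(keep, "kept", "removed:low_depth"),
      clean_reads = as.integer(totals),
      stringsAsFactors = FALSE
    )
  )
}

#' Remove rare taxa by pooled relative abundance
#'
#' An ASV is removed iff its pooled count over all samples, as a percentage
#' of the grand total, is strictly below `params$tau_rel`.
#'
#' @inheritParams apply_depth_filter
#' @return list with `table` and `asvs` (data frame `asv_id`, `disposition`
#'   in kept / removed:rare, `pooled_pct`).
#' @export
apply_rare_taxon_filter <- function(table, params = curation_params()) {
  validate_asv_table(table)
  grand <- sum(table)
  if (grand == 0) stop("rare-taxon filter: grand total is zero")
  pooled_pct <- 100 * rowSums(table) / grand
  keep <- pooled_pct >= params$tau_rel
  list(
    table = table[keep, , drop = FALSE],
    asvs = data.frame(
      asv_id = rownames(table),
      disposition = ifelse(keep, "kept", "removed:rare"),
      pooled_pct = pooled_pct,
      stringsAsFactors = FALSE,
      row.names = NULL
    )
  )
}

.material_cols <- function(table, meta, material) {
  validate_metadata(meta)
  ids <- meta$sample_id[meta$material == material]
  intersect(colnames(table), ids)
}

#' Remove ASVs present only in water controls
#'
#' An ASV is removed iff it has zero reads across all milk samples and a
#' positive total across the water extraction controls. Milk clean-read
#' totals are never altered by this rule.
#'
#' @param table abundance matrix.
#' @param meta validated metadata identifying milk and water samples.
#' @return list with `table` and `asvs` (data frame `asv_id`, `disposition`
#'   in kept / removed:water_only, `milk_reads`, `water_reads`).
#' @export
remove_water_only_asvs <- function(table, meta) {
  validate_asv_table(table)
  milk_cols <- .material_cols(table, meta, "milk")
  water_cols <- .material_cols(table, meta, "water")
  if (!length(water_cols)) {
    message("no water samples present; water-only removal is a no-op")
  }
  milk_tot <- rowSums(table[, milk_cols, drop = FALSE])
  water_tot <- rowSums(table[, water_cols, drop = FALSE])
  drop <- milk_tot == 0 & water_tot > 0
  list(
    table = table[!drop, , drop = FALSE],
    asvs = data.frame(
      asv_id = rownames(table),
      disposition = ifelse(drop, "removed:water_only", "kept"),
      milk_reads = as.integer(milk_tot),
      water_reads = as.integer(water_tot),
      stringsAsFactors = FALSE,
      row.names = NULL
    )
  )
}

#' Remove single-hit ASVs
#'
#' A single hit is an ASV with non-zero counts in exactly one sample
#' (any material), regardless of how many reads it carries there.
#'
#' @param table abundance matrix.
#' @return list with `table` and `asvs` (data frame `asv_id`, `disposition`
#'   in kept / removed:single_hit, `n_samples_present`).
#' @export
remove_single_hit_asvs <- function(table) {
  validate_asv_table(table)
  occupancy <- rowSums(table > 0)
  drop <- occupancy == 1
  list(
    table = table[!drop, , drop = FALSE],
    asvs = data.frame(
      asv_id = rownames(table),
      disposition = ifelse(drop, "removed:single_hit", "kept"),
      n_samples_present = as.integer(occupancy),
      stringsAsFactors = FALSE,
      row.names = NULL
    )
  )
}

#' Flag recurrent water-control ASVs
#'
#' An ASV is flagged (retained, never removed) iff it appears in strictly
#' more than `tau_flag_reps` water replicates and at least one water count
#' exceeds `tau_flag_count` reads.
#'
#' @inheritParams remove_water_only_asvs
#' @param params [curation_params()].
#' @return data frame `asv_id`, `flagged` (logical), `n_water_present`,
#'   `max_water_count`.
#' @export
flag_recurrent_water_asvs <- function(table, meta,
                                      params = curation_params()) {
  validate_asv_table(table)
  water_cols <- .material_cols(table, meta, "water")
  w <- table[, water_cols, drop = FALSE]
  n_present <- rowSums(w > 0)
  max_count <- if (length(water_cols)) apply(w, 1L, max) else
    rep(0L, nrow(table))
  data.frame(
    asv_id = rownames(table),
    flagged = n_present > params$tau_flag_reps &
      max_count > params$tau_flag_count,
    n_water_present = as.integer(n_present),
    max_water_count = as.integer(max_count),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Flag foreign (index-swap candidate) ASVs
#'
#' Flags every ASV whose genus annotation is in `params$foreign_taxa` —
#' taxa judged implausible for the milk matrix and more likely carried in
#' by index swapping from co-sequenced libraries. Flagged ASVs stay in the
#' table; removal is a separate policy decision. ASVs without a genus
#' annotation are never flagged (and are noted via `message()`).
#'
#' The flagged read fraction is the percentage of milk reads carried by
#' flagged ASVs, computed per primer run when metadata is supplied (the
#' scale on which run-level swap rates are quoted), else over all milk
#' samples pooled.
#'
#' @param table abundance matrix.
#' @param taxonomy taxonomy data frame.
#' @param meta optional metadata (for milk columns and primer runs).
#' @param params [curation_params()].
#' @return list with `flags` (data frame `asv_id`, `flagged`, `genus`) and
#'   `flagged_read_fraction` (named numeric, percent per primer run, or a
#'   single `"all"` entry without metadata).
#' @export
flag_foreign_asvs <- function(table, taxonomy, meta = NULL,
                              params = curation_params()) {
  validate_asv_table(table)
  genus <- genus_of(rownames(table), taxonomy)
  flagged <- !is.na(genus) & genus %in% params$foreign_taxa
  if (length(params$foreign_taxa) && anyNA(genus)) {
    message(sum(is.na(genus)),
            " ASV(s) lack genus annotation and were not flagged")
  }
  frac <- function(cols) {
    tot <- sum(table[, cols, drop = FALSE])
    if (tot == 0) return(0)
    100 * sum(table[flagged, cols, drop = FALSE]) / tot
  }
  if (is.null(meta)) {
    fractions <- c(all = frac(colnames(table)))
  } else {
    validate_metadata(meta)
    runs <- intersect(.runs, unique(meta$primer_run))
    fractions <- vapply(runs, function(r) {
      ids <- meta$sample_id[meta$material == "milk" & meta$primer_run == r]
      frac(intersect(colnames(table), ids))
    }, numeric(1))
  }
  list(
    flags = data.frame(asv_id = rownames(table), flagged = flagged,
                       genus = genus, stringsAsFactors = FALSE,
                       row.names = NULL),
    flagged_read_fraction = fractions
  )
}

#' Total sum scaling
#'
#' Divides each sample's counts by its clean-read total, yielding per-sample
#' proportions (columns sum to one). Zero-total samples are an error; run
#' the depth filter first.
#'
#' @param table abundance matrix.
#' @return numeric matrix of relative abundances with the same dimnames.
#' @export
tss_normalize <- function(table) {
  validate_asv_table(table)
  totals <- colSums(table)
  if (any(totals == 0)) {
    stop("tss_normalize: zero-total sample(s): ",
         paste(colnames(table)[totals == 0], collapse = ", "),
         " (apply the depth filter first)")
  }
  sweep(table, 2L, totals, "/")
}

#' Run the full curation pipeline
#'
#' Applies, in fixed order: water-only removal, single-hit removal, sample
#' depth filter, pooled rarity filter; then computes the recurrent-blank
#' and foreign-taxon flags on the surviving ASV set. Blank-derived flags are
#' evaluated against the water controls as they stood before the depth
#' filter, since blanks are typically shallow yet still informative.
#' Flags never remove ASVs unless `drop_flagged = TRUE`.
#'
#' @param table abundance matrix.
#' @param meta validated metadata.
#' @param taxonomy taxonomy data frame (may be `NULL` when
#'   `params$foreign_taxa` is empty).
#' @param params [curation_params()].
#' @param drop_flagged if `TRUE`, flagged ASVs are dropped from the curated
#'   table (their ledger disposition stays `kept` with the flag recorded).
#' @return list of class `curation_report` with elements `table` (curated
#'   matrix), `asvs` (ledger: `asv_id`, `disposition`, `flag_recurrent_water`,
#'   `flag_foreign`), `samples` (ledger: `sample_id`, `disposition`,
#'   `clean_reads`), `flagged_read_fraction` (percent per primer run) and
#'   `params`.
#' @export
run_curation <- function(table, meta, taxonomy = NULL,
                         params = curation_params(),
                         drop_flagged = FALSE) {
  validate_asv_table(table)
  validate_metadata(meta)
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop("curation stage '", what, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }
  disposition <- setNames(rep("kept", nrow(table)), rownames(table))

  s1 <- stage("remove_water_only", remove_water_only_asvs(table, meta))
  removed <- s1$asvs$disposition != "kept"
  disposition[s1$asvs$asv_id[removed]] <- s1$asvs$disposition[removed]

  s2 <- stage("remove_single_hit", remove_single_hit_asvs(s1$table))
  removed <- s2$asvs$disposition != "kept"
  disposition[s2$asvs$asv_id[removed]] <- s2$asvs$disposition[removed]

  s3 <- stage("apply_depth_filter", apply_depth_filter(s2$table, params))

  s4 <- stage("apply_rare_taxon_filter",
              apply_rare_taxon_filter(s3$table, params))
  removed <- s4$asvs$disposition != "kept"
  disposition[s4$asvs$asv_id[removed]] <- s4$asvs$disposition[removed]

  curated <- s4$table

  # blank flags use pre-depth-filter water columns, restricted to kept ASVs
  fw <- stage("flag_recurrent_water",
              flag_recurrent_water_asvs(
                s2$table[rownames(curated), , drop = FALSE], meta, params))
  flag_water <- setNames(fw$flagged, fw$asv_id)

  if (is.null(taxonomy) && length(params$foreign_taxa)) {
    stop("curation stage 'flag_foreign': foreign_taxa supplied without taxonomy")
  }
  if (!is.null(taxonomy)) {
    ff <- stage("flag_foreign",
                flag_foreign_asvs(curated, taxonomy, meta, params))
    flag_foreign <- setNames(ff$flags$flagged, ff$flags$asv_id)
    fractions <- ff$flagged_read_fraction
  } else {
    flag_foreign <- setNames(rep(FALSE, nrow(curated)), rownames(curated))
    fractions <- setNames(numeric(0), character(0))
  }

  asv_ledger <- data.frame(
    asv_id = rownames(table),
    disposition = unname(disposition),
    flag_recurrent_water = unname(flag_water[rownames(table)] %in% TRUE),
    flag_foreign = unname(flag_foreign[rownames(table)] %in% TRUE),
    stringsAsFactors = FALSE
  )
  if (drop_flagged) {
    keep <- !(flag_water[rownames(curated)] %in% TRUE |
                flag_foreign[rownames(curated)] %in% TRUE)
    curated <- curated[keep, , drop = FALSE]
  }
  structure(list(
    table = curated,
    asvs = asv_ledger,
    samples = s3$samples,
    flagged_read_fraction = fractions,
    params = params
  ), class = "curation_report")
}

#' @export
print.curation_report <- function(x, ...) {
  cat("Curation report\n")
  cat("  ASVs:   ", nrow(x$asvs), "in ->", nrow(x$table), "kept\n")
  print(table(x$asvs$disposition))
  cat("  flagged recurrent water:", sum(x$asvs$flag_recurrent_water),
      "| flagged foreign:", sum(x$asvs$flag_foreign), "\n")
  cat("  samples:", nrow(x$samples), "in ->", ncol(x$table), "kept\n")
  if (length(x$flagged_read_fraction)) {
    cat("  foreign-flagged milk read fraction (%):\n")
    print(round(x$flagged_read_fraction, 3))
  }
  invisible(x)
}

#' Serialize a curation report
#'
#' Writes the per-ASV ledger, the per-sample ledger and a structured
#' summary (counts per disposition, flagged read fractions) as TSV files.
#'
#' @param report a `curation_report`.
#' @param dir output directory (created if needed).
#' @return character vector of the files written, invisibly.
#' @export
write_curation_report <- function(report, dir) {
  stopifnot(inherits(report, "curation_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- file.path(dir, c("curation_asvs.tsv", "curation_samples.tsv",
                            "curation_summary.tsv"))
  write_tsv(report$asvs, files[1L])
  write_tsv(report$samples, files[2L])
  disp <- as.data.frame(table(report$asvs$disposition),
                        stringsAsFactors = FALSE)
  colnames(disp) <- c("key", "value")
  extra <- data.frame(
    key = c("samples_removed_low_depth",
            "flagged_recurrent_water", "flagged_foreign",
            if (length(report$flagged_read_fraction))
              paste0("flagged_read_fraction_",
                     names(report$flagged_read_fraction))),
    value = c(sum(report$samples$disposition != "kept"),
              sum(report$asvs$flag_recurrent_water),
              sum(report$asvs$flag_foreign),
              unname(report$flagged_read_fraction)),
    stringsAsFactors = FALSE
  )
  write_tsv(rbind(disp, extra), files[3L])
  invisible(files)
}
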