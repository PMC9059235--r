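#' Top-taxa summary at genus level
#'
#' Aggregates a TSS-normalized table to genus (ASVs without annotation and
#' the literal `"unclassified"` token are pooled), ranks named genera by
#' overall mean relative abundance, and reports per-group means for the top
#' `top_n` plus a `remaining/unknown` remainder so each group's column sums
#' to one.
#'
#' @param normalized TSS-normalized matrix (columns sum to 1).
#' @param taxonomy taxonomy data frame.
#' @param groups grouping labels named by sample id (or aligned with the
#'   columns of `normalized`).
#' @param top_n number of named genera to report (default 20).
#' @return data frame with column `genus` (top genera plus
#'   `"remaining/unknown"`) and one mean-relative-abundance column per
#'   group; groups without samples are absent.
#' @export
summarize_top_taxa <- function(normalized, taxonomy, groups, top_n = 20L) {
  if (top_n < 1) stop("top_n must be >= 1")
  tot <- colSums(normalized)
  if (any(abs(tot - 1) > 1e-6)) {
    stop("summarize_top_taxa expects a TSS-normalized table")
  }
  genus <- genus_of(rownames(normalized), taxonomy)
  genus[is.na(genus)] <- "unclassified"
  by_genus <- rowsum(normalized, group = genus)
  named <- setdiff(rownames(by_genus), "unclassified")
  ranking <- named[order(rowMeans(by_genus[named, , drop = FALSE]),
                         decreasing = TRUE)]
  top <- utils::head(ranking, top_n)

  if (!is.null(names(groups))) groups <- groups[colnames(normalized)]
  groups <- as.character(groups)
  out <- data.frame(genus = c(top, "remaining/unknown"),
                    stringsAsFactors = FALSE)
  for (g in unique(groups[!is.na(groups)])) {
    cols <- which(groups == g)
    gm <- rowMeans(by_genus[, cols, drop = FALSE])
    named_means <- gm[top]
    out[[g]] <- c(unname(named_means), 1 - sum(named_means))
  }
  out
}

#' Pipeline run configuration
#'
#' Exactly one of `input` (paths to abundance/metadata/taxonomy TSVs) or
#' `simulate` (a [simulation_config()]) must be given. All randomness flows
#' from `seed`: the simulation uses `seed` and rarefaction uses a derived
#' substream seed.
#'
#' @param input `NULL` or list with `abundance`, `metadata`, `taxonomy`
#'   paths (`taxonomy` optional).
#' @param simulate `NULL` or a [simulation_config()].
#' @param params [curation_params()].
#' @param rarefaction `NULL` (min-retained policy) or a
#'   [rarefaction_spec()].
#' @param out_dir output directory for the report bundle.
#' @param seed top-level integer seed.
#' @param drop_flagged drop flagged ASVs from the curated table.
#' @param top_n genera in the top-taxa summary.
#' @return an object of class `run_config`.
#' @export
run_config <- function(input = NULL, simulate = NULL,
                       params = curation_params(), rarefaction = NULL,
                       out_dir = tempfile("milkmb_run_"), seed = 1L,
                       drop_flagged = FALSE, top_n = 20L) {
  if (is.null(input) == is.null(simulate)) {
    stop("exactly one of 'input' and 'simulate' must be supplied")
  }
  if (top_n < 1) stop("top_n must be >= 1")
  structure(list(input = input, simulate = simulate, params = params,
                 rarefaction = rarefaction, out_dir = out_dir,
                 seed = as.integer(seed), drop_flagged = drop_flagged,
                 top_n = as.integer(top_n)),
            class = "run_config")
}

.load_inputs <- function(config) {
  if (!is.null(config$simulate)) {
    sim <- simulate_study(config$simulate)
    list(table = sim$table, meta = sim$meta, taxonomy = sim$taxonomy,
         truth = sim$truth)
  } else {
    list(
      table = read_abundance_table(config$input$abundance),
      meta = read_metadata(config$input$metadata),
      taxonomy = if (!is.null(config$input$taxonomy)) {
        read_taxonomy(config$input$taxonomy)
      },
      truth = NULL
    )
  }
}

#' Run the full analysis pipeline
#'
#' Orchestrates io -> curation -> diversity -> reproducibility -> report:
#' curates the table, TSS-normalizes, computes protocol-specific rarefied
#' alpha diversity with per-protocol ANOVA across prototype samples,
#' Bray-Curtis distances and PCoA per primer run, replicate dispersion,
#' the clean-read variability decomposition (when the design has
#' resequencing replicates), per-protocol medians with the selection rule,
#' and the top-taxa summary. Every table is written as TSV under
#' `config$out_dir` together with a run log recording all thresholds and
#' seeds; every reported number is traceable to an exported table.
#'
#' @param config a [run_config()].
#' @return list of class `run_bundle` with all computed tables (`curation`,
#'   `clean_reads`, `medians`, `selected`, `diversity`, `anova`,
#'   `distance` and `ordination` per run, `dispersion`, `variability`,
#'   `top_taxa`, plus `truth` for simulated inputs), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(
    paste0("milkmb run, seed=", config$seed),
    paste0("params: tau_depth=", config$params$tau_depth,
           " tau_rel=", config$params$tau_rel,
           " tau_flag_count=", config$params$tau_flag_count,
           " tau_flag_reps=", config$params$tau_flag_reps,
           " tau_median=", config$params$tau_median),
    paste0("foreign_taxa: ",
           paste(config$params$foreign_taxa, collapse = ",")),
    paste0("drop_flagged: ", config$drop_flagged)
  )
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", what, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }

  inputs <- stage("io", .load_inputs(config))
  table <- inputs$table
  meta <- inputs$meta

  cur <- stage("curation",
               run_curation(table, meta, inputs$taxonomy, config$params,
                            drop_flagged = config$drop_flagged))
  write_curation_report(cur, config$out_dir)
  curated <- cur$table
  meta_kept <- meta[meta$sample_id %in% colnames(curated), , drop = FALSE]

  clean <- clean_read_totals(table)  # pre-curation clean reads
  write_tsv(data.frame(sample_id = names(clean),
                       clean_reads = as.integer(clean),
                       stringsAsFactors = FALSE),
            file.path(config$out_dir, "clean_reads.tsv"))

  medians <- stage("selection", protocol_median_clean_reads(clean, meta))
  selected <- select_protocols(medians, config$params)
  write_tsv(medians, file.path(config$out_dir, "protocol_medians.tsv"))
  write_tsv(data.frame(protocol = selected, stringsAsFactors = FALSE),
            file.path(config$out_dir, "selected_protocols.tsv"))

  rspec <- config$rarefaction %||%
    rarefaction_spec(seed = config$seed + 1000L)
  log_lines <- c(log_lines,
                 paste0("rarefaction: policy=", rspec$policy,
                        " seed=", rspec$seed))
  div <- stage("diversity", alpha_diversity_table(curated, meta_kept, rspec))
  write_tsv(div, file.path(config$out_dir, "diversity.tsv"))

  anova_rows <- list()
  for (run in unique(div$primer_run)) {
    for (p in unique(div$protocol[div$primer_run == run])) {
      sub <- div[div$primer_run == run & div$protocol == p, , drop = FALSE]
      for (index in c("H", "R", "E")) {
        res <- tryCatch(anova_alpha(sub[[index]], sub$prototype),
                        error = function(e) NULL)
        if (is.null(res)) next
        anova_rows[[length(anova_rows) + 1L]] <-
          cbind(data.frame(primer_run = run, protocol = p, index = index,
                           stringsAsFactors = FALSE), res)
      }
    }
  }
  anova_tab <- if (length(anova_rows)) do.call(rbind, anova_rows) else NULL
  if (!is.null(anova_tab)) {
    write_tsv(anova_tab, file.path(config$out_dir, "anova.tsv"))
  }

  norm <- stage("normalization", tss_normalize(curated))

  distances <- list()
  ordinations <- list()
  dispersion_rows <- list()
  top_taxa <- list()
  for (run in intersect(.runs, unique(meta_kept$primer_run))) {
    milk_ids <- meta_kept$sample_id[meta_kept$material == "milk" &
                                      meta_kept$primer_run == run]
    milk_ids <- intersect(colnames(norm), milk_ids)
    if (length(milk_ids) < 3) next
    sub <- norm[, milk_ids, drop = FALSE]
    D <- stage("betadiv", bray_curtis_matrix(sub, use_relative = FALSE))
    distances[[run]] <- D
    write_tsv(data.frame(sample_id = rownames(D), D, check.names = FALSE),
              file.path(config$out_dir, paste0("distance_", run, ".tsv")))
    ord <- stage("ordination", pcoa(D, n_axes = 2L))
    ordinations[[run]] <- ord
    write_tsv(data.frame(sample_id = rownames(ord$coordinates),
                         ord$coordinates, check.names = FALSE),
              file.path(config$out_dir, paste0("ordination_", run, ".tsv")))

    mm <- meta_kept[match(milk_ids, meta_kept$sample_id), , drop = FALSE]
    disp <- group_dispersion(
      D, stats::setNames(paste(mm$protocol, mm$prototype, sep = "|"),
                         mm$sample_id))
    dispersion_rows[[run]] <- data.frame(
      primer_run = run,
      protocol = sub("\\|.*", "", names(disp)),
      prototype = sub(".*\\|", "", names(disp)),
      mean_within_dissimilarity = unname(disp),
      stringsAsFactors = FALSE)

    if (!is.null(inputs$taxonomy)) {
      top_taxa[[run]] <- summarize_top_taxa(
        sub, inputs$taxonomy,
        stats::setNames(mm$prototype, mm$sample_id), config$top_n)
      write_tsv(top_taxa[[run]],
                file.path(config$out_dir, paste0("top_taxa_", run, ".tsv")))
    }
  }
  dispersion <- if (length(dispersion_rows)) {
    do.call(rbind, dispersion_rows)
  } else {
    NULL
  }
  if (!is.null(dispersion)) {
    rownames(dispersion) <- NULL
    write_tsv(dispersion, file.path(config$out_dir, "dispersion.tsv"))
  }

  variability <- NULL
  milk_kept <- meta[meta$material == "milk", , drop = FALSE]
  has_reseq <- length(unique(milk_kept$sequencing_rep)) >= 2
  if (has_reseq) {
    variability <- stage("variability",
                         decompose_read_variability(clean, meta))
    write_tsv(variability, file.path(config$out_dir, "variability.tsv"))
  } else {
    log_lines <- c(log_lines,
                   "variability: skipped (no resequencing replicates)")
  }

  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  invisible(structure(list(
    curation = cur, clean_reads = clean, medians = medians,
    selected = selected, diversity = div, anova = anova_tab,
    distance = distances, ordination = ordinations,
    dispersion = dispersion, variability = variability,
    top_taxa = top_taxa, truth = inputs$truth, out_dir = config$out_dir
  ), class = "run_bundle"))
}
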