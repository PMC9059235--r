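#' Mock community profile
#'
#' Equal-proportion composition over the eight bacterial members of the
#' commercial mock standard used as positive sequencing control (the two
#' yeast members do not amplify with 16S primers and are excluded).
#'
#' @return named numeric vector of 8 genera, each 0.125.
#' @export
mock_profile <- function() {
  genera <- c("Bacillus", "Escherichia", "Enterococcus", "Listeria",
              "Lactobacillus", "Pseudomonas", "Salmonella", "Staphylococcus")
  stats::setNames(rep(1 / 8, 8L), genera)
}

.default_depth_medians <- function(phase) {
  # per-protocol median clean reads; pretrial values follow the published
  # run medians where printed, P1 is an order-of-magnitude stand-in
  if (phase == "pretrial") {
    m <- rbind(P1 = c(400, 1200), P2 = c(268, 983), P3 = c(1616, 3482),
               P4 = c(1002, 2527), P5 = c(257, 308), P6 = c(6175, 11564))
  } else {
    m <- rbind(P3 = c(1779, 3341), P4 = c(2263, 8860), P6 = c(22810, 17643))
  }
  colnames(m) <- c("V1V2", "V3V4")
  m
}

.default_design <- function(phase) {
  if (phase == "pretrial") {
    list(extracts = c(P1 = 3L, P2 = 3L, P3 = 3L, P4 = 2L, P5 = 2L, P6 = 3L),
         seq_reps = 1L)
  } else {
    list(extracts = c(P3 = 3L, P4 = 2L, P6 = 3L), seq_reps = 3L)
  }
}

.milk_genera <- c("Staphylococcus", "Streptococcus", "Corynebacterium",
                  "Lactobacillus", "Lactococcus", "Bacteroides", "Bacillus",
                  "Acinetobacter", "Pseudomonas", "Aerococcus",
                  "Jeotgalicoccus", "Sphingomonas", "Brevibacterium",
                  "Enterococcus", "Micrococcus", "Kocuria")
.foreign_genera <- c("Aquabacterium", "Pelomonas", "Acidocella",
                     "Cutibacterium", "Prevotella", "Porphyromonas",
                     "Halomonas", "Synechococcus")
.contaminant_genera <- c("Bradyrhizobium", "Ralstonia", "Caulobacter",
                         "Methylobacterium", "Sphingobium", "Burkholderia")

#' Simulation configuration
#'
#' Parameters of the synthetic study generator. Defaults state the world
#' the generator emulates: four prototype milk samples in a 2x2 SCC/cfu
#' design; six protocols extracted in duplicate/triplicate with one water
#' control per protocol and extraction replicate (pretrial), or three
#' protocols resequenced in triplicate (main); per-protocol clean-read
#' medians matching the published run medians; kit-specific contaminants
#' confined to blanks; and index swapping at the run-level rates observed
#' in the flagged-read analysis (1.64% V1V2, 1.1% V3V4).
#'
#' @param phase `"pretrial"` or `"main"`; fixes the replicate design and
#'   depth medians unless overridden.
#' @param G number of milk-community ASVs.
#' @param base_alpha Dirichlet concentration for the prototype base
#'   compositions (smaller = sparser, more realistic amplicon profiles).
#' @param protocol_bias_sigma SD of the per-ASV log-normal extraction bias,
#'   drawn once per protocol (kit chemistry favouring some taxa).
#' @param sigma_ext SD of the per-extract log-normal perturbation; applied
#'   to the extract's composition *and* as a multiplier on its expected
#'   sequencing depth (extraction yield drives read numbers).
#' @param depth_sigma SD (log scale) of the per-sequencing-replicate
#'   clean-read depth around the extract's expected depth.
#' @param depth_medians matrix protocol x run of median clean reads
#'   (default: published run medians for the phase).
#' @param epsilon named per-run index-swap read fractions in [0, 1].
#' @param n_foreign number of ASVs in the co-sequenced foreign pool.
#' @param n_contaminants_per_protocol kit contaminant ASVs per protocol.
#' @param contaminant_mean mean blank read counts, recycled over a
#'   protocol's contaminant ASVs.
#' @param contaminant_presence probability that a contaminant ASV is carried
#'   by a given extraction replicate's kit aliquot (per-blank dropout).
#' @param unclassified_frac fraction of milk ASVs whose genus annotation is
#'   the literal token `"unclassified"`.
#' @param design list with `extracts` (named integer vector protocol ->
#'   number of extraction replicates) and `seq_reps`; default from `phase`.
#' @param mock_depth,ntc_lambda expected depths of the mock and no-template
#'   control data sets.
#' @param water_swap_base nominal read pool against which blank swap counts
#'   are drawn.
#' @param seed integer seed; the generator is bit-reproducible given it.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(phase = c("main", "pretrial"),
                              G = 150L,
                              base_alpha = 0.3,
                              protocol_bias_sigma = 0.5,
                              sigma_ext = 0.3,
                              depth_sigma = 0.7,
                              depth_medians = NULL,
                              epsilon = c(V1V2 = 0.0164, V3V4 = 0.011),
                              n_foreign = 25L,
                              n_contaminants_per_protocol = 3L,
                              contaminant_mean = c(150, 60, 25),
                              contaminant_presence = 0.7,
                              unclassified_frac = 0.15,
                              design = NULL,
                              mock_depth = 25000L,
                              ntc_lambda = 20,
                              water_swap_base = 300,
                              seed = 1L) {
  phase <- match.arg(phase)
  cfg <- list(
    phase = phase, G = as.integer(G), base_alpha = base_alpha,
    protocol_bias_sigma = protocol_bias_sigma, sigma_ext = sigma_ext,
    depth_sigma = depth_sigma,
    depth_medians = depth_medians %||% .default_depth_medians(phase),
    epsilon = epsilon, n_foreign = as.integer(n_foreign),
    n_contaminants_per_protocol = as.integer(n_contaminants_per_protocol),
    contaminant_mean = contaminant_mean,
    contaminant_presence = contaminant_presence,
    unclassified_frac = unclassified_frac,
    design = design %||% .default_design(phase),
    mock_depth = as.integer(mock_depth), ntc_lambda = ntc_lambda,
    water_swap_base = water_swap_base,
    seed = as.integer(seed)
  )
  if (any(cfg$epsilon < 0 | cfg$epsilon > 1)) {
    stop("epsilon must be in [0, 1]")
  }
  if (is.null(names(cfg$epsilon)) || !all(.runs %in% names(cfg$epsilon))) {
    stop("epsilon must be named with runs ", paste(.runs, collapse = ", "))
  }
  for (f in c("protocol_bias_sigma", "sigma_ext", "depth_sigma")) {
    if (cfg[[f]] < 0) stop(f, " must be >= 0")
  }
  if (!all(names(cfg$design$extracts) %in% rownames(cfg$depth_medians))) {
    stop("design/phase mismatch: depth_medians lacks protocol(s) ",
         paste(setdiff(names(cfg$design$extracts),
                       rownames(cfg$depth_medians)), collapse = ", "))
  }
  structure(cfg, class = "simulation_config")
}

.rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(x) == 0) x[which.max(alpha)] <- 1
  x / sum(x)
}

#' Simulate one sequencing data set from an extract
#'
#' Draws `depth` reads from the extract's composition, then replaces a
#' `Binomial(depth, epsilon)` number of reads with draws from the foreign
#' pool (index swapping). The output total is exactly `depth` and the
#' swapped-read count is recorded.
#'
#' @param composition normalized composition over the extract's own ASVs.
#' @param depth non-negative integer read depth.
#' @param epsilon index-swap read fraction in [0, 1].
#' @param foreign_profile normalized composition over the foreign pool.
#' @param seed optional seed (RNG state restored).
#' @return list with `own` (counts over `composition`), `foreign` (counts
#'   over `foreign_profile`) and `n_swapped`.
#' @export
sequence_extract <- function(composition, depth, epsilon, foreign_profile,
                             seed = NULL) {
  if (epsilon < 0 || epsilon > 1) stop("epsilon must be in [0, 1]")
  if (depth < 0) stop("depth must be >= 0")
  with_seed(seed, {
    n_swap <- stats::rbinom(1L, depth, epsilon)
    own <- if (depth - n_swap > 0) {
      as.integer(stats::rmultinom(1L, depth - n_swap, composition))
    } else {
      integer(length(composition))
    }
    foreign <- if (n_swap > 0) {
      as.integer(stats::rmultinom(1L, n_swap, foreign_profile))
    } else {
      integer(length(foreign_profile))
    }
    list(own = stats::setNames(own, names(composition)),
         foreign = stats::setNames(foreign, names(foreign_profile)),
         n_swapped = n_swap)
  })
}

#' Simulate the full study
#'
#' Generates the abundance table, metadata, taxonomy and ground-truth
#' ledger for one phase of the nested design. Per prototype sample a base
#' composition is drawn from a Dirichlet; each protocol applies a fixed
#' per-ASV multiplicative extraction bias; each extraction replicate
#' perturbs the composition log-normally (and its expected depth by the
#' same `sigma_ext`); each sequencing replicate draws a log-normal depth
#' and multinomial reads, with an `epsilon` fraction replaced by foreign
#' reads (index swapping). Water controls carry only kit contaminants
#' (Poisson counts with per-extract presence dropout) plus swapped reads;
#' the mock is a fixed 8-taxon profile; the no-template control is
#' near-empty (a few artifact/swap reads).
#'
#' @param config a [simulation_config()].
#' @return list with `table` (abundance matrix), `meta` (metadata data
#'   frame), `taxonomy` (taxonomy data frame) and `truth` (list:
#'   `asv_labels` — milk / contaminant:<protocol> / foreign / mock;
#'   `datasets` — per data set `sample_id`, `planted_depth`,
#'   `swapped_reads`, `contaminant_reads`; `config`).
#' @export
simulate_study <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, .simulate_study_impl(config))
}

.simulate_study_impl <- function(cfg) {
  protos <- names(cfg$design$extracts)
  runs <- .runs
  G <- cfg$G

  milk_ids <- sprintf("ASV%04d", seq_len(G))
  foreign_ids <- sprintf("FOR%03d", seq_len(cfg$n_foreign))
  cont_ids <- list()
  for (p in protos) {
    cont_ids[[p]] <- sprintf("CONT_%s_%d", p,
                             seq_len(cfg$n_contaminants_per_protocol))
  }
  mock_genera <- names(mock_profile())
  mock_ids <- sprintf("MOCK%d", seq_along(mock_genera))
  all_ids <- c(milk_ids, unlist(cont_ids, use.names = FALSE), foreign_ids,
               mock_ids)

  # taxonomy: genus labels with an unclassified fraction among milk ASVs
  milk_genus <- sample(.milk_genera, G, replace = TRUE)
  n_uncl <- round(cfg$unclassified_frac * G)
  if (n_uncl > 0) {
    milk_genus[sample.int(G, n_uncl)] <- "unclassified"
  }
  cont_genus <- sample(.contaminant_genera,
                       length(protos) * cfg$n_contaminants_per_protocol,
                       replace = TRUE)
  foreign_genus <- sample(.foreign_genera, cfg$n_foreign, replace = TRUE)
  taxonomy <- data.frame(
    asv_id = all_ids,
    domain = "Bacteria",
    genus = c(milk_genus, cont_genus, foreign_genus, mock_genera),
    stringsAsFactors = FALSE
  )

  labels <- stats::setNames(
    c(rep("milk", G),
      rep(paste0("contaminant:", protos),
          each = cfg$n_contaminants_per_protocol),
      rep("foreign", cfg$n_foreign),
      rep("mock", length(mock_ids))),
    all_ids)

  base <- lapply(.prototypes, function(s) {
    stats::setNames(.rdirichlet1(rep(cfg$base_alpha, G)), milk_ids)
  })
  names(base) <- .prototypes

  bias <- lapply(protos, function(p) {
    exp(stats::rnorm(G, 0, cfg$protocol_bias_sigma))
  })
  names(bias) <- protos

  foreign_profile <- stats::setNames(
    .rdirichlet1(rep(0.5, cfg$n_foreign)), foreign_ids)

  # per-extract state, shared across primer runs (one physical extract)
  ext_comp <- list()   # [[p]][[s]][[e]] composition over milk ASVs
  ext_dmul <- list()   # depth multiplier
  cont_present <- list()  # [[p]][[e]] presence of each contaminant ASV
  for (p in protos) {
    ext_comp[[p]] <- list()
    ext_dmul[[p]] <- list()
    for (s in .prototypes) {
      ext_comp[[p]][[s]] <- list()
      ext_dmul[[p]][[s]] <- numeric(cfg$design$extracts[[p]])
      for (e in seq_len(cfg$design$extracts[[p]])) {
        v <- base[[s]] * bias[[p]] *
          exp(stats::rnorm(G, 0, cfg$sigma_ext))
        ext_comp[[p]][[s]][[e]] <- v / sum(v)
        ext_dmul[[p]][[s]][e] <- exp(stats::rnorm(1, 0, cfg$sigma_ext))
      }
    }
    cont_present[[p]] <- lapply(seq_len(cfg$design$extracts[[p]]),
                                function(e) {
      stats::rbinom(cfg$n_contaminants_per_protocol, 1L,
                    cfg$contaminant_presence) == 1L
    })
  }

  cols <- list()
  meta_rows <- list()
  truth_rows <- list()
  add <- function(id, counts_named, material, protocol, prototype, e, s,
                  run, depth, swapped, cont_reads) {
    col <- stats::setNames(integer(length(all_ids)), all_ids)
    col[names(counts_named)] <- counts_named
    cols[[id]] <<- col
    meta_rows[[id]] <<- data.frame(
      sample_id = id, material = material,
      protocol = protocol %||% NA_character_,
      prototype = prototype %||% NA_character_,
      extraction_rep = e %||% NA_integer_,
      sequencing_rep = s,
      primer_run = run, phase = cfg$phase, stringsAsFactors = FALSE)
    truth_rows[[id]] <<- data.frame(
      sample_id = id, planted_depth = depth, swapped_reads = swapped,
      contaminant_reads = cont_reads, stringsAsFactors = FALSE)
  }

  cont_mean <- rep_len(cfg$contaminant_mean, cfg$n_contaminants_per_protocol)

  for (run in runs) {
    eps <- cfg$epsilon[[run]]
    for (p in protos) {
      for (s_idx in seq_along(.prototypes)) {
        s <- .prototypes[s_idx]
        for (e in seq_len(cfg$design$extracts[[p]])) {
          for (sr in seq_len(cfg$design$seq_reps)) {
            mu <- log(cfg$depth_medians[p, run]) +
              log(ext_dmul[[p]][[s]][e])
            depth <- max(1L, as.integer(round(
              stats::rlnorm(1, mu, cfg$depth_sigma))))
            sq <- sequence_extract(ext_comp[[p]][[s]][[e]], depth, eps,
                                   foreign_profile)
            id <- sprintf("%s_%s_%s_%s_e%d_s%d", cfg$phase, run, p, s, e, sr)
            add(id, c(sq$own, sq$foreign), "milk", p, s, e, sr, run,
                depth, sq$n_swapped, 0L)
          }
        }
        NULL
      }
      # one water control per extraction replicate
      for (e in seq_len(cfg$design$extracts[[p]])) {
        for (sr in seq_len(cfg$design$seq_reps)) {
          cc <- integer(cfg$n_contaminants_per_protocol)
          pres <- cont_present[[p]][[e]]
          if (any(pres)) {
            cc[pres] <- stats::rpois(sum(pres), cont_mean[pres])
          }
          names(cc) <- cont_ids[[p]]
          n_swap <- stats::rpois(1L, eps * cfg$water_swap_base)
          fw <- if (n_swap > 0) {
            stats::setNames(as.integer(
              stats::rmultinom(1L, n_swap, foreign_profile)), foreign_ids)
          } else {
            stats::setNames(integer(cfg$n_foreign), foreign_ids)
          }
          id <- sprintf("%s_%s_%s_water_e%d_s%d", cfg$phase, run, p, e, sr)
          add(id, c(cc, fw), "water", p, NULL, e, sr, run,
              sum(cc) + n_swap, n_swap, sum(cc))
        }
      }
    }
    # sequencing controls, once per run
    mock_comp <- stats::setNames(unname(mock_profile()), mock_ids)
    sq <- sequence_extract(mock_comp, cfg$mock_depth, eps, foreign_profile)
    add(sprintf("%s_%s_mock_s1", cfg$phase, run), c(sq$own, sq$foreign),
        "mock", NULL, NULL, NULL, 1L, run, cfg$mock_depth, sq$n_swapped, 0L)
    ntc_depth <- stats::rpois(1L, cfg$ntc_lambda)
    fw <- if (ntc_depth > 0) {
      stats::setNames(as.integer(
        stats::rmultinom(1L, ntc_depth, foreign_profile)), foreign_ids)
    } else {
      stats::setNames(integer(cfg$n_foreign), foreign_ids)
    }
    add(sprintf("%s_%s_ntc_s1", cfg$phase, run), fw,
        "ntc", NULL, NULL, NULL, 1L, run, ntc_depth, ntc_depth, 0L)
  }

  table <- do.call(cbind, cols)
  rownames(table) <- all_ids
  storage.mode(table) <- "integer"
  meta <- do.call(rbind, meta_rows)
  rownames(meta) <- NULL
  truth_ds <- do.call(rbind, truth_rows)
  rownames(truth_ds) <- NULL
  validate_asv_table(table)
  validate_metadata(meta)

  list(table = table, meta = meta, taxonomy = taxonomy,
       truth = list(asv_labels = labels, datasets = truth_ds,
                    config = cfg))
}

#' Write a simulated study to disk
#'
#' Exports the three input tables plus the ground-truth ledger as TSV.
#'
#' @param sim result of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return character vector of the files written, invisibly.
#' @export
write_simulated_study <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- file.path(dir, c("abundance.tsv", "metadata.tsv", "taxonomy.tsv",
                            "truth_asvs.tsv", "truth_datasets.tsv"))
  write_abundance_table(sim$table, files[1L])
  write_metadata(sim$meta, files[2L])
  write_taxonomy(sim$taxonomy, files[3L])
  write_tsv(data.frame(asv_id = names(sim$truth$asv_labels),
                       label = unname(sim$truth$asv_labels),
                       stringsAsFactors = FALSE), files[4L])
  write_tsv(sim$truth$datasets, files[5L])
  invisible(files)
}
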