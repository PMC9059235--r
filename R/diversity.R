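#' Rarefy a count vector to a fixed depth
#'
#' Subsamples reads without replacement so that the output totals exactly
#' `d`. Samples shallower than `d` must be excluded by the caller — they
#' are never padded.
#'
#' @param counts non-negative integer vector of per-ASV counts.
#' @param d target depth, `1 <= d <= sum(counts)`.
#' @param seed optional seed for the draw (RNG state is restored).
#' @return integer vector of the same length and names, elementwise `<=`
#'   `counts`, summing to `d`.
#' @export
rarefy_counts <- function(counts, d, seed = NULL) {
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  total <- sum(counts)
  if (d < 1 || d != round(d)) stop("depth d must be a positive integer")
  if (d > total) {
    stop("depth d = ", d, " exceeds sample total ", total,
         " (exclude the sample instead of padding)")
  }
  if (d == total) return(stats::setNames(as.integer(counts), names(counts)))
  with_seed(seed, {
    reads <- rep.int(seq_along(counts), counts)
    drawn <- sample(reads, d)
    stats::setNames(tabulate(drawn, nbins = length(counts)), names(counts))
  })
}

#' Expected richness under rarefaction
#'
#' Analytic expectation of the number of ASVs observed when `d` reads are
#' drawn without replacement (multivariate hypergeometric):
#' `sum_i (1 - choose(N - n_i, d) / choose(N, d))`. Computed in log space
#' via `lchoose`, so it stays finite for totals up to at least 1e6.
#'
#' @param counts non-negative integer vector.
#' @param d depth, `d <= sum(counts)`.
#' @return expected richness (real number).
#' @export
expected_rarefied_richness <- function(counts, d) {
  N <- sum(counts)
  if (d > N) stop("d exceeds total")
  lc <- lchoose(N - counts, d) - lchoose(N, d)
  sum(1 - exp(lc))
}

#' Alpha diversity at a rarefaction depth
#'
#' Rarefies once (seeded) and computes richness `R` (number of non-zero
#' ASVs), Shannon index `H = -sum p log p` in nats over the non-zero
#' rarefied proportions, and Pielou evenness `E = H / log(R)`. `E` is
#' undefined (`NA`) when `R <= 1`. When `d` equals the sample total the
#' counts are used as-is.
#'
#' @param counts non-negative integer vector.
#' @param d rarefaction depth (default: full depth).
#' @param seed optional seed for the rarefaction draw.
#' @param n_rep number of independent rarefaction draws to average the
#'   indices over (default 1, a single draw).
#' @return data frame with one row: `d`, `R`, `H`, `E`.
#' @export
alpha_diversity <- function(counts, d = sum(counts), seed = NULL,
                            n_rep = 1L) {
  one <- function(x) {
    x <- x[x > 0]
    R <- length(x)
    p <- x / sum(x)
    H <- -sum(p * log(p))
    E <- if (R >= 2) H / log(R) else NA_real_
    c(R = R, H = H, E = E)
  }
  draws <- with_seed(seed, {
    vapply(seq_len(n_rep), function(i) one(rarefy_counts(counts, d)),
           numeric(3))
  })
  m <- rowMeans(draws)
  data.frame(d = d, R = m[["R"]], H = m[["H"]], E = m[["E"]])
}

#' Rarefaction policy
#'
#' Depths are chosen per protocol (and primer run), never across protocols:
#' rarefying everything to the weakest protocol's depth would mask the very
#' differences under study. The default policy takes the minimum retained
#' clean-read total among a protocol's milk samples; explicit depths (one
#' per protocol, optionally per run) override the policy verbatim.
#'
#' @param policy `"min_retained"` or `"explicit"`.
#' @param depths for `"explicit"`: named numeric vector `protocol -> depth`,
#'   or a data frame with columns `protocol`, `primer_run`, `depth`.
#' @param seed seed used for the per-sample rarefaction draws.
#' @return an object of class `rarefaction_spec`.
#' @export
rarefaction_spec <- function(policy = c("min_retained", "explicit"),
                             depths = NULL, seed = 1L) {
  policy <- match.arg(policy)
  if (policy == "explicit") {
    if (is.null(depths)) stop("explicit policy requires depths")
    dd <- if (is.data.frame(depths)) depths$depth else depths
    if (any(dd < 1)) stop("explicit depths must be >= 1")
  }
  structure(list(policy = policy, depths = depths, seed = seed),
            class = "rarefaction_spec")
}

#' Protocol-specific rarefaction depths
#'
#' @param table depth-filtered abundance matrix.
#' @param meta validated metadata.
#' @param spec a [rarefaction_spec()].
#' @return data frame `protocol`, `primer_run`, `depth`.
#' @export
protocol_rarefaction_depth <- function(table, meta,
                                       spec = rarefaction_spec()) {
  validate_asv_table(table)
  validate_metadata(meta)
  milk <- meta[meta$material == "milk" &
                 meta$sample_id %in% colnames(table), , drop = FALSE]
  keys <- unique(milk[, c("protocol", "primer_run")])
  keys <- keys[order(keys$protocol, keys$primer_run), , drop = FALSE]
  rownames(keys) <- NULL
  totals <- clean_read_totals(table)
  if (spec$policy == "explicit") {
    if (is.data.frame(spec$depths)) {
      m <- merge(keys, spec$depths, by = c("protocol", "primer_run"),
                 all.x = TRUE)
      if (anyNA(m$depth)) {
        stop("explicit depths missing for: ",
             paste(m$protocol[is.na(m$depth)], m$primer_run[is.na(m$depth)],
                   collapse = ", "))
      }
      return(m[order(m$protocol, m$primer_run), , drop = FALSE])
    }
    keys$depth <- unname(spec$depths[keys$protocol])
    if (anyNA(keys$depth)) {
      stop("explicit depths missing for protocol(s): ",
           paste(unique(keys$protocol[is.na(keys$depth)]), collapse = ", "))
    }
    return(keys)
  }
  keys$depth <- NA_real_
  for (i in seq_len(nrow(keys))) {
    ids <- milk$sample_id[milk$protocol == keys$protocol[i] &
                            milk$primer_run == keys$primer_run[i]]
    if (!length(ids)) {
      stop("no retained samples for protocol ", keys$protocol[i], " / ",
           keys$primer_run[i])
    }
    keys$depth[i] <- min(totals[ids])
  }
  keys
}

#' Alpha diversity for every retained milk sample
#'
#' Looks up each milk sample's protocol-specific depth, excludes samples
#' shallower than their depth, and computes [alpha_diversity()] once per
#' sample with a per-sample seed derived from `spec$seed`.
#'
#' @param table curated abundance matrix.
#' @param meta validated metadata.
#' @param spec a [rarefaction_spec()].
#' @param n_rep rarefaction draws averaged per sample (default 1).
#' @return data frame `sample_id`, `protocol`, `primer_run`, `prototype`,
#'   `d`, `R`, `H`, `E` (one row per retained milk sample).
#' @export
alpha_diversity_table <- function(table, meta, spec = rarefaction_spec(),
                                  n_rep = 1L) {
  depths <- protocol_rarefaction_depth(table, meta, spec)
  milk <- meta[meta$material == "milk" &
                 meta$sample_id %in% colnames(table), , drop = FALSE]
  totals <- clean_read_totals(table)
  rows <- vector("list", nrow(milk))
  for (i in seq_len(nrow(milk))) {
    id <- milk$sample_id[i]
    d <- depths$depth[depths$protocol == milk$protocol[i] &
                        depths$primer_run == milk$primer_run[i]]
    if (totals[id] < d) next  # below protocol depth: excluded, not padded
    div <- alpha_diversity(table[, id], d = d,
                           seed = spec$seed + i, n_rep = n_rep)
    rows[[i]] <- cbind(
      data.frame(sample_id = id, protocol = milk$protocol[i],
                 primer_run = milk$primer_run[i],
                 prototype = milk$prototype[i], stringsAsFactors = FALSE),
      div
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' One-way fixed-effects ANOVA
#'
#' Classical decomposition: `F = MS_between / MS_within` with the p-value
#' from the F distribution. Pairs with `NA` in either vector are dropped.
#' Zero within-group variance with unequal means yields `F = Inf`, `p = 0`
#' with a warning (degenerate limit).
#'
#' @param values numeric vector (one diversity index per data set).
#' @param groups grouping labels (e.g. prototype sample), same length.
#' @return data frame `F`, `p`, `df_between`, `df_within`.
#' @export
anova_alpha <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- factor(groups[ok])
  k <- nlevels(groups)
  n <- length(values)
  if (k < 2) stop("ANOVA needs at least 2 groups")
  if (n - k < 2) stop("ANOVA needs at least 2 residual degrees of freedom")
  gm <- tapply(values, groups, mean)
  gn <- tapply(values, groups, length)
  grand <- mean(values)
  ss_between <- sum(gn * (gm - grand)^2)
  ss_within <- sum((values - gm[groups])^2)
  df_b <- k - 1L
  df_w <- n - k
  if (ss_within == 0) {
    if (ss_between == 0) {
      return(data.frame(F = 0, p = 1, df_between = df_b, df_within = df_w))
    }
    warning("zero within-group variance with unequal means: F is infinite")
    return(data.frame(F = Inf, p = 0, df_between = df_b, df_within = df_w))
  }
  f <- (ss_between / df_b) / (ss_within / df_w)
  data.frame(F = f, p = stats::pf(f, df_b, df_w, lower.tail = FALSE),
             df_between = df_b, df_within = df_w)
}
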