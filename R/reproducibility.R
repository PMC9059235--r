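#' Bray-Curtis dissimilarity matrix
#'
#' `BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i)` over an aligned ASV index.
#' By default abundances are total-sum-scaled first, since samples differ in
#' sequencing depth; set `use_relative = FALSE` to work on raw counts.
#'
#' @param table abundance matrix (ASV rows x sample columns), non-negative,
#'   no zero-total sample.
#' @param use_relative normalize columns to proportions first (default).
#' @return symmetric numeric matrix with zero diagonal, entries in [0, 1],
#'   sample ids as dimnames.
#' @export
bray_curtis_matrix <- function(table, use_relative = TRUE) {
  if (any(table < 0)) stop("abundances must be non-negative")
  totals <- colSums(table)
  if (any(totals == 0)) {
    stop("zero-total sample(s): ",
         paste(colnames(table)[totals == 0], collapse = ", "))
  }
  m <- if (use_relative) sweep(table, 2L, totals, "/") else table
  D <- as.matrix(vegan::vegdist(t(m), method = "bray"))
  diag(D) <- 0
  D
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centers the squared dissimilarities
#' (`B = -1/2 J D^2 J`), eigendecomposes, and scales eigenvectors by the
#' square root of their (positive) eigenvalues. Axes are ordered by
#' descending eigenvalue. Negative eigenvalues — which a semimetric like
#' Bray-Curtis can produce — are reported but excluded from the
#' coordinates; no Lingoes/Cailliez correction is applied.
#'
#' @param D symmetric dissimilarity matrix (or `dist`).
#' @param n_axes number of coordinate axes to return (capped at the number
#'   of positive eigenvalues).
#' @return list of class `pcoa_result`: `coordinates` (samples x axes),
#'   `eigenvalues` (all, descending), `proportion_explained` (share of the
#'   positive-eigenvalue total per retained axis).
#' @export
pcoa <- function(D, n_axes = 2L) {
  D <- as.matrix(stats::as.dist(D))
  n <- nrow(D)
  if (n < 2) stop("PCoA needs at least 2 samples")
  fit <- suppressWarnings(
    stats::cmdscale(stats::as.dist(D), k = n - 1L, eig = TRUE)
  )
  eig <- fit$eig
  n_pos <- sum(eig > sqrt(.Machine$double.eps) * max(abs(eig)))
  if (n_pos == 0) stop("degenerate PCoA: no positive eigenvalues")
  k <- min(n_axes, n_pos)
  coords <- fit$points[, seq_len(k), drop = FALSE]
  colnames(coords) <- paste0("Axis", seq_len(k))
  rownames(coords) <- rownames(D)
  structure(list(
    coordinates = coords,
    eigenvalues = eig,
    proportion_explained = eig[seq_len(k)] / sum(eig[eig > 0])
  ), class = "pcoa_result")
}

#' Mean within-group dissimilarity
#'
#' Replicate dispersion: the average dissimilarity over all unordered
#' within-group pairs. Singleton groups yield `NA` with a notice.
#'
#' @param D symmetric dissimilarity matrix with sample ids as dimnames.
#' @param groups grouping labels, named by sample id or aligned with the
#'   rows of `D`.
#' @return named numeric vector, one mean per group.
#' @export
group_dispersion <- function(D, groups) {
  D <- as.matrix(D)
  if (!is.null(names(groups))) groups <- groups[rownames(D)]
  groups <- as.character(groups)
  out <- c()
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 2) {
      message("group '", g, "' has a single member; dispersion is NA")
      out[g] <- NA_real_
      next
    }
    sub <- D[idx, idx, drop = FALSE]
    out[g] <- mean(sub[lower.tri(sub)])
  }
  out
}

#' Decompose clean-read variability into sequencing and total components
#'
#' For every key (protocol, primer run, prototype sample):
#' * `max_seq_var` — within each extract, the range (max - min) of its
#'   sequencing replicates' clean reads; the maximum of those ranges over
#'   the key's extracts. Pure resequencing variability.
#' * `total_var` — the largest absolute clean-read difference over all pairs
#'   of data sets belonging to *different* extracts. Extraction plus
#'   sequencing variability.
#' * `ratio_pct = 100 * max_seq_var / total_var` — may legitimately exceed
#'   100% when one extract's resequencing spread beats every cross-extract
#'   difference.
#' * `extraction_contribution_pp = 100 * (total_var - max_seq_var) /
#'   max_seq_var` — percentage points of extra variability attributable to
#'   extraction when sequencing variability is set to 100%.
#'
#' @param clean_reads named numeric vector of clean-read totals (names are
#'   sample ids), e.g. from [clean_read_totals()].
#' @param meta validated metadata; only milk data sets are used. Every
#'   extract must have at least 2 sequencing replicates and every key at
#'   least 2 extracts.
#' @return data frame `protocol`, `primer_run`, `prototype`, `max_seq_var`,
#'   `total_var`, `ratio_pct`, `extraction_contribution_pp`. Ratios are `NA`
#'   (with a notice) when `total_var` is zero.
#' @export
decompose_read_variability <- function(clean_reads, meta) {
  validate_metadata(meta)
  milk <- meta[meta$material == "milk" &
                 meta$sample_id %in% names(clean_reads), , drop = FALSE]
  keys <- unique(milk[, c("protocol", "primer_run", "prototype")])
  keys <- keys[order(keys$protocol, keys$primer_run, keys$prototype), ,
               drop = FALSE]
  rownames(keys) <- NULL
  out <- keys
  out$max_seq_var <- NA_real_
  out$total_var <- NA_real_
  out$ratio_pct <- NA_real_
  out$extraction_contribution_pp <- NA_real_
  for (i in seq_len(nrow(keys))) {
    mk <- milk[milk$protocol == keys$protocol[i] &
                 milk$primer_run == keys$primer_run[i] &
                 milk$prototype == keys$prototype[i], , drop = FALSE]
    extracts <- split(clean_reads[mk$sample_id], mk$extraction_rep)
    if (length(extracts) < 2) {
      stop("key ", paste(unlist(keys[i, ]), collapse = "/"),
           " has fewer than 2 extracts")
    }
    if (any(lengths(extracts) < 2)) {
      stop("key ", paste(unlist(keys[i, ]), collapse = "/"),
           " has an extract with fewer than 2 sequencing replicates")
    }
    seq_var <- max(vapply(extracts, function(x) diff(range(x)), numeric(1)))
    total_var <- 0
    ne <- length(extracts)
    for (a in seq_len(ne - 1L)) {
      for (b in seq(a + 1L, ne)) {
        total_var <- max(total_var,
                         max(abs(outer(extracts[[a]], extracts[[b]], "-"))))
      }
    }
    out$max_seq_var[i] <- seq_var
    out$total_var[i] <- total_var
    if (total_var == 0) {
      message("key ", paste(unlist(keys[i, ]), collapse = "/"),
              ": total variability is zero; ratio undefined")
    } else {
      out$ratio_pct[i] <- 100 * seq_var / total_var
    }
    if (seq_var > 0) {
      out$extraction_contribution_pp[i] <-
        100 * (total_var - seq_var) / seq_var
    }
  }
  out
}

#' Per-protocol median clean reads
#'
#' Medians over milk data sets, per protocol and primer run (even counts
#' use the arithmetic mean of the central pair).
#'
#' @param clean_reads named numeric vector of clean-read totals.
#' @param meta validated metadata.
#' @return data frame `protocol`, `primer_run`, `median_clean_reads`, `n`.
#' @export
protocol_median_clean_reads <- function(clean_reads, meta) {
  validate_metadata(meta)
  milk <- meta[meta$material == "milk" &
                 meta$sample_id %in% names(clean_reads), , drop = FALSE]
  keys <- unique(milk[, c("protocol", "primer_run")])
  keys <- keys[order(keys$protocol, keys$primer_run), , drop = FALSE]
  rownames(keys) <- NULL
  keys$median_clean_reads <- NA_real_
  keys$n <- NA_integer_
  for (i in seq_len(nrow(keys))) {
    x <- clean_reads[milk$sample_id[milk$protocol == keys$protocol[i] &
                                      milk$primer_run == keys$primer_run[i]]]
    keys$median_clean_reads[i] <- stats::median(x)
    keys$n[i] <- length(x)
  }
  keys
}

#' Select protocols by median clean reads
#'
#' A protocol qualifies iff its median clean reads are strictly above
#' `tau_median` in *both* primer runs; a missing or `NA` run fails the
#' protocol.
#'
#' @param medians data frame `protocol`, `primer_run`,
#'   `median_clean_reads` (as from [protocol_median_clean_reads()]).
#' @param params [curation_params()] (only `tau_median` is used).
#' @return sorted character vector of selected protocols (possibly empty).
#' @export
select_protocols <- function(medians, params = curation_params()) {
  if (!nrow(medians)) return(character(0))
  sel <- character(0)
  for (p in sort(unique(medians$protocol))) {
    ok <- vapply(.runs, function(r) {
      v <- medians$median_clean_reads[medians$protocol == p &
                                        medians$primer_run == r]
      length(v) == 1L && !is.na(v) && v > params$tau_median
    }, logical(1))
    if (all(ok)) sel <- c(sel, p)
  }
  sel
}
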