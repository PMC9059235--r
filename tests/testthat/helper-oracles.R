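# Brute-force oracles and tiny fixture builders. Oracles are deliberately
# naive re-derivations, independent of the implementation paths they check.

oracle_shannon <- function(x) {
  p <- x[x > 0] / sum(x)
  -sum(p * log(p))
}

oracle_bray_curtis <- function(x, y) {
  sum(abs(x - y)) / sum(x + y)
}

# exhaustive pair enumeration of the variability decomposition for one key
oracle_variability <- function(reads, extract_id) {
  seq_var <- max(vapply(split(reads, extract_id),
                        function(x) max(x) - min(x), numeric(1)))
  total_var <- 0
  n <- length(reads)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (extract_id[i] != extract_id[j]) {
        total_var <- max(total_var, abs(reads[i] - reads[j]))
      }
    }
  }
  c(max_seq_var = seq_var, total_var = total_var,
    ratio_pct = if (total_var > 0) 100 * seq_var / total_var else NA_real_)
}

# classical scaling from first principles: double-centered eigendecomposition
oracle_pcoa_coords <- function(D, k) {
  D <- as.matrix(D)
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  e <- eigen(B, symmetric = TRUE)
  e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(e$values[seq_len(k)]), k)
}

# metadata row builder with milk defaults; NA fields where material demands
meta_rows <- function(sample_id, material = "milk", protocol = "P3",
                      prototype = "SCC-cfu-", extraction_rep = 1L,
                      sequencing_rep = 1L, primer_run = "V1V2",
                      phase = "main") {
  data.frame(sample_id = sample_id, material = material,
             protocol = protocol, prototype = prototype,
             extraction_rep = as.integer(extraction_rep),
             sequencing_rep = as.integer(sequencing_rep),
             primer_run = primer_run, phase = phase,
             stringsAsFactors = FALSE)
}

# random sparse count table with unique ids
random_table <- function(n_asv, n_sample, lambda = 3, p_zero = 0.6) {
  m <- matrix(stats::rpois(n_asv * n_sample, lambda) *
                stats::rbinom(n_asv * n_sample, 1, 1 - p_zero),
              nrow = n_asv,
              dimnames = list(sprintf("ASV%03d", seq_len(n_asv)),
                              sprintf("S%02d", seq_len(n_sample))))
  storage.mode(m) <- "integer"
  m
}

all_foreign_genera <- c("Aquabacterium", "Pelomonas", "Acidocella",
                        "Cutibacterium", "Prevotella", "Porphyromonas",
                        "Halomonas", "Synechococcus")
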