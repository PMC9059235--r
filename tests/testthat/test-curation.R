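test_that("clean_read_totals are column sums", {
  m <- matrix(c(3L, 0L, 7L, 0L, 0L, 0L), 3, 2,
              dimnames = list(paste0("A", 1:3), c("s1", "s2")))
  expect_equal(clean_read_totals(m), c(s1 = 10, s2 = 0))
})

test_that("depth filter keeps samples at exactly the threshold", {
  m <- matrix(c(499L, 500L, 501L), 1, 3,
              dimnames = list("A1", c("a", "b", "c")))
  res <- apply_depth_filter(m, curation_params())
  expect_identical(colnames(res$table), c("b", "c"))
  expect_equal(res$samples$disposition,
               c("removed:low_depth", "kept", "kept"))

  # all deep -> identity; all shallow -> warning
  deep <- matrix(600L, 2, 2, dimnames = list(c("A1", "A2"), c("a", "b")))
  expect_identical(apply_depth_filter(deep)$table, deep)
  shallow <- matrix(1L, 1, 2, dimnames = list("A1", c("a", "b")))
  expect_warning(apply_depth_filter(shallow), "every sample")
})

test_that("rare-taxon filter uses pooled percent with a strict boundary", {
  # grand total 100000: 10 reads = 0.01% kept, 9 reads removed
  m <- matrix(c(10L, 9L, 99981L), 3, 1,
              dimnames = list(c("at", "below", "bulk"), "s1"))
  res <- apply_rare_taxon_filter(m, curation_params())
  expect_identical(rownames(res$table), c("at", "bulk"))
  expect_equal(res$asvs$disposition[res$asvs$asv_id == "below"],
               "removed:rare")

  single <- matrix(5L, 1, 1, dimnames = list("only", "s1"))
  expect_identical(apply_rare_taxon_filter(single)$table, single)
  zero <- matrix(0L, 1, 1, dimnames = list("A", "s1"))
  expect_error(apply_rare_taxon_filter(zero), "grand total")
})

test_that("rare-taxon filter matches brute-force enumeration", {
  set.seed(42)
  m <- random_table(100, 8, lambda = 2, p_zero = 0.7)
  m[1, 1] <- 5000L  # make others rare relative to the grand total
  params <- curation_params(tau_rel = 0.5)
  res <- apply_rare_taxon_filter(m, params)
  expected_removed <- rownames(m)[vapply(seq_len(nrow(m)), function(i) {
    100 * sum(m[i, ]) / sum(m) < params$tau_rel
  }, logical(1))]
  expect_setequal(res$asvs$asv_id[res$asvs$disposition == "removed:rare"],
                  expected_removed)
})

test_that("water-only removal drops blank-only ASVs and preserves milk totals", {
  meta <- rbind(meta_rows(c("m1", "m2"), sequencing_rep = 1:2),
                meta_rows("w1", material = "water", prototype = NA))
  m <- matrix(c(0L, 5L, 2L,   0L, 3L, 0L,   50L, 1L, 0L), 3, 3,
              dimnames = list(c("blankonly", "both", "milkonly"),
                              c("m1", "m2", "w1")))
  res <- remove_water_only_asvs(m, meta)
  expect_identical(rownames(res$table), c("both", "milkonly"))
  expect_equal(res$asvs$disposition,
               c("removed:water_only", "kept", "kept"))
  expect_equal(colSums(res$table)[c("m1", "m2")], colSums(m)[c("m1", "m2")])

  no_water <- meta_rows(c("m1", "m2"), sequencing_rep = 1:2)
  expect_message(res2 <- remove_water_only_asvs(m[, 1:2], no_water),
                 "no-op")
  expect_identical(res2$table, m[, 1:2])
})

test_that("single-hit removal matches brute-force occupancy", {
  m <- matrix(0L, 4, 10,
              dimnames = list(paste0("A", 1:4), paste0("s", 1:10)))
  m[1, 3] <- 999L          # single hit despite high count
  m[2, c(1, 2)] <- 1L      # two samples -> kept
  m[3, ] <- 2L             # everywhere
  res <- remove_single_hit_asvs(m)
  expect_identical(rownames(res$table), c("A2", "A3", "A4"))

  set.seed(7)
  r <- random_table(80, 12, lambda = 1, p_zero = 0.8)
  res <- remove_single_hit_asvs(r)
  expect_setequal(
    res$asvs$asv_id[res$asvs$disposition == "removed:single_hit"],
    rownames(r)[rowSums(r > 0) == 1])
})

test_that("recurrent-water flag follows the >2 replicates and >100 reads rule", {
  meta <- rbind(meta_rows("m1"),
                meta_rows(paste0("w", 1:3), material = "water",
                          prototype = NA, extraction_rep = 1:3))
  mk <- function(water) {
    m <- cbind(m1 = 1L, rbind(water))
    rownames(m) <- "A1"
    colnames(m) <- c("m1", paste0("w", seq_along(water)))
    storage.mode(m) <- "integer"
    m
  }
  expect_true(flag_recurrent_water_asvs(mk(c(150L, 3L, 2L)), meta)$flagged)
  # only two water replicates present: not "more than two"
  meta2 <- meta[1:3, ]
  expect_false(flag_recurrent_water_asvs(mk(c(200L, 150L)), meta2)$flagged)
  # never above 100 reads
  expect_false(flag_recurrent_water_asvs(mk(c(90L, 80L, 70L)), meta)$flagged)
})

test_that("foreign flags report per-run milk read fractions", {
  tax <- data.frame(asv_id = c("A1", "A2", "A3"),
                    genus = c("Aquabacterium", "Staphylococcus", NA),
                    stringsAsFactors = FALSE)
  meta <- rbind(meta_rows("m1", primer_run = "V1V2"),
                meta_rows("m2", primer_run = "V3V4"))
  m <- matrix(c(3L, 197L, 0L, 10L, 90L, 0L), 3, 2,
              dimnames = list(c("A1", "A2", "A3"), c("m1", "m2")))
  params <- curation_params(foreign_taxa = "Aquabacterium")
  res <- suppressMessages(flag_foreign_asvs(m, tax, meta, params))
  expect_equal(res$flags$flagged, c(TRUE, FALSE, FALSE))
  expect_equal(res$flagged_read_fraction[["V1V2"]], 100 * 3 / 200)
  expect_equal(res$flagged_read_fraction[["V3V4"]], 100 * 10 / 100)

  none <- flag_foreign_asvs(m, tax, meta, curation_params())
  expect_false(any(none$flags$flagged))
  expect_equal(unname(none$flagged_read_fraction), c(0, 0))
})

test_that("tss_normalize yields unit-sum columns and errors on zero totals", {
  m <- matrix(c(3L, 1L), 2, 1, dimnames = list(c("A1", "A2"), "s1"))
  expect_equal(as.vector(tss_normalize(m)), c(0.75, 0.25))

  set.seed(3)
  r <- random_table(30, 6, p_zero = 0.3)
  r <- r[, colSums(r) > 0, drop = FALSE]
  n <- tss_normalize(r)
  expect_equal(unname(colSums(n)), rep(1, ncol(n)), tolerance = 1e-9)
  expect_equal(n, sweep(r, 2, colSums(r), "/"), ignore_attr = FALSE)

  z <- matrix(0L, 1, 1, dimnames = list("A", "s1"))
  expect_error(tss_normalize(z), "zero-total")
})

test_that("curation filters are idempotent", {
  set.seed(9)
  m <- random_table(60, 10, lambda = 5, p_zero = 0.5)
  m[1, ] <- 700L  # keep at least one sample above depth threshold
  meta <- meta_rows(colnames(m), extraction_rep = 1L,
                    sequencing_rep = seq_len(ncol(m)))
  params <- curation_params(tau_depth = 10, tau_rel = 0.2)

  f1 <- apply_depth_filter(m, params)$table
  expect_identical(apply_depth_filter(f1, params)$table, f1)
  f2 <- apply_rare_taxon_filter(m, params)$table
  expect_identical(apply_rare_taxon_filter(f2, params)$table, f2)
  f3 <- remove_single_hit_asvs(m)$table
  expect_identical(remove_single_hit_asvs(f3)$table, f3)
  f4 <- suppressMessages(remove_water_only_asvs(m, meta)$table)
  expect_identical(suppressMessages(remove_water_only_asvs(f4, meta)$table),
                   f4)
})

test_that("run_curation partitions ASVs and samples exactly once", {
  sim <- simulate_study(simulation_config(phase = "main", G = 60, seed = 21))
  rep <- run_curation(sim$table, sim$meta, sim$taxonomy,
                      curation_params(foreign_taxa = all_foreign_genera))
  expect_setequal(rep$asvs$asv_id, rownames(sim$table))
  expect_false(anyDuplicated(rep$asvs$asv_id) > 0)
  expect_setequal(rep$samples$sample_id, colnames(sim$table))
  # kept dispositions coincide with membership in the curated table
  expect_setequal(rep$asvs$asv_id[rep$asvs$disposition == "kept"],
                  rownames(rep$table))
  expect_setequal(rep$samples$sample_id[rep$samples$disposition == "kept"],
                  colnames(rep$table))
})

test_that("run_curation on an already-clean deep table is the identity", {
  meta <- rbind(meta_rows(c("m1", "m2"), sequencing_rep = 1:2),
                meta_rows("w1", material = "water", prototype = NA))
  m <- matrix(c(600L, 400L, 580L, 420L, 5L, 3L), 3, 2, byrow = TRUE,
              dimnames = list(c("A1", "A2", "A3"), NULL))
  m <- cbind(m, c(2L, 1L, 0L))
  colnames(m) <- c("m1", "m2", "w1")
  m["A3", "w1"] <- 3L  # present in water AND milk -> kept
  rep <- run_curation(m, meta, params = curation_params(tau_depth = 5))
  expect_identical(rep$table, m)
  expect_true(all(rep$asvs$disposition == "kept"))
})

test_that("curation report serializes to a TSV ledger", {
  sim <- simulate_study(simulation_config(phase = "main", G = 40, seed = 3))
  rep <- run_curation(sim$table, sim$meta, sim$taxonomy,
                      curation_params(foreign_taxa = all_foreign_genera))
  dir <- withr::local_tempdir()
  files <- write_curation_report(rep, dir)
  expect_true(all(file.exists(files)))
  ledger <- read.delim(files[1L], stringsAsFactors = FALSE)
  expect_setequal(ledger$asv_id, rownames(sim$table))
})

test_that("planted contaminants and singletons are recovered exactly", {
  sim <- simulate_study(simulation_config(phase = "main", G = 80, seed = 17))
  truth <- sim$truth$asv_labels
  meta <- sim$meta
  tab <- sim$table

  milk_cols <- meta$sample_id[meta$material == "milk"]
  water_cols <- meta$sample_id[meta$material == "water"]
  # ground truth, derived from planted labels and presence
  water_only_true <- names(truth)[startsWith(truth, "contaminant") &
                                    rowSums(tab[, water_cols]) > 0]
  expect_true(all(rowSums(tab[water_only_true, milk_cols, drop = FALSE]) == 0))

  res <- remove_water_only_asvs(tab, meta)
  called <- res$asvs$asv_id[res$asvs$disposition == "removed:water_only"]
  # contaminants are confined to blanks, so sensitivity and specificity
  # against the planted set must both be exactly 1 (mock/ntc columns are
  # neither milk nor water and carry mock/foreign ASVs, not contaminants)
  expect_setequal(
    setdiff(called, names(truth)[truth == "foreign" | truth == "mock"]),
    water_only_true)
  expect_true(all(truth[called] != "milk"))

  singles <- remove_single_hit_asvs(tab)
  expect_setequal(
    singles$asvs$asv_id[singles$asvs$disposition == "removed:single_hit"],
    rownames(tab)[rowSums(tab > 0) == 1])
})
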