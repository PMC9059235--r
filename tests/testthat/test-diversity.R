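test_that("rarefy_counts honors the subsampling contract", {
  x <- c(a = 5L, b = 0L, c = 12L)
  expect_identical(rarefy_counts(x, sum(x)), x)  # full depth is identity

  one <- rarefy_counts(x, 1, seed = 4)
  expect_equal(sum(one), 1)
  expect_equal(sum(one > 0), 1)

  set.seed(8)
  for (i in 1:25) {
    d <- sample(1:17, 1)
    r <- rarefy_counts(x, d)
    expect_equal(sum(r), d)
    expect_true(all(r <= x))
  }
  expect_error(rarefy_counts(x, 18), "exceeds sample total")
  expect_error(rarefy_counts(x, 0), "positive integer")

  # seeded draws are reproducible and do not disturb the global stream
  set.seed(123); before <- runif(1)
  set.seed(123)
  a <- rarefy_counts(c(10L, 10L), 5, seed = 99)
  expect_identical(a, rarefy_counts(c(10L, 10L), 5, seed = 99))
  expect_equal(runif(1), before)
})

test_that("expected_rarefied_richness matches direct combinatorics", {
  # counts (5,5), d=2: 2 * (1 - choose(5,2)/choose(10,2)) = 14/9
  expect_equal(expected_rarefied_richness(c(5, 5), 2), 14 / 9)
  # d = N recovers observed richness; d = 1 gives exactly 1
  expect_equal(expected_rarefied_richness(c(3, 7, 2), 12), 3)
  expect_equal(expected_rarefied_richness(c(3, 7, 2), 1), 1)
  # brute-force hypergeometric for a random vector
  set.seed(5)
  n <- c(4, 9, 1, 6)
  d <- 7
  N <- sum(n)
  expect_equal(expected_rarefied_richness(n, d),
               sum(1 - choose(N - n, d) / choose(N, d)))
  # log-space evaluation stays finite at large totals
  expect_true(is.finite(expected_rarefied_richness(c(999000, 1000), 5000)))
})

test_that("mean simulated richness converges to the hypergeometric expectation", {
  draws <- with(list(), {
    set.seed(31)
    replicate(20000, sum(rarefy_counts(c(5L, 5L), 2) > 0))
  })
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 14 / 9), 3 * se)
})

test_that("alpha diversity reproduces direct formula evaluation", {
  # uniform over 4 ASVs: H = ln 4, E = 1
  res <- alpha_diversity(c(5L, 5L, 5L, 5L), d = 20)
  expect_equal(res$H, log(4))
  expect_equal(res$E, 1)
  expect_equal(res$R, 4)

  # single ASV: H = 0, R = 1, E undefined
  res <- alpha_diversity(c(9L, 0L), d = 9)
  expect_equal(res$H, 0)
  expect_equal(res$R, 1)
  expect_true(is.na(res$E))

  # counts (3,1) at full depth
  res <- alpha_diversity(c(3L, 1L), d = 4)
  expect_equal(res$H, -(0.75 * log(0.75) + 0.25 * log(0.25)))
  expect_equal(res$E, res$H / log(2))
  expect_equal(round(res$H, 4), 0.5623)
  expect_equal(round(res$E, 4), 0.8113)
})

test_that("Shannon is permutation-invariant, maximal at uniformity; E in [0,1]", {
  set.seed(77)
  for (i in 1:20) {
    x <- rpois(8, 20) + 1L
    H <- alpha_diversity(x, d = sum(x))$H
    expect_equal(H, oracle_shannon(x), tolerance = 1e-12)
    expect_equal(alpha_diversity(sample(x), d = sum(x))$H, H)
    expect_lte(H, log(length(x)) + 1e-12)
    E <- alpha_diversity(x, d = sum(x))$E
    expect_gte(E, 0); expect_lte(E, 1)
  }
})

test_that("protocol rarefaction depths follow policy or explicit spec", {
  meta <- rbind(
    meta_rows(c("a", "b", "c"), protocol = "P3", sequencing_rep = 1:3),
    meta_rows(c("d", "e"), protocol = "P4", sequencing_rep = 1:2)
  )
  m <- rbind(A1 = c(302L, 900L, 5000L, 468L, 700L))
  m <- rbind(m, A2 = 0L)
  colnames(m) <- c("a", "b", "c", "d", "e")
  dep <- protocol_rarefaction_depth(m, meta)
  expect_equal(dep$depth[dep$protocol == "P3"], 302)
  expect_equal(dep$depth[dep$protocol == "P4"], 468)

  spec <- rarefaction_spec("explicit",
                           depths = c(P3 = 302, P4 = 468, P6 = 1302))
  dep <- protocol_rarefaction_depth(m, meta, spec)
  expect_equal(dep$depth, c(302, 468))

  # all totals equal -> that value
  eq <- matrix(10L, 1, 3, dimnames = list("A1", c("a", "b", "c")))
  dep <- protocol_rarefaction_depth(eq, meta[1:3, ])
  expect_equal(dep$depth, 10)
})

test_that("alpha_diversity_table rarefies per protocol and excludes shallow samples", {
  sim <- simulate_study(simulation_config(phase = "main", G = 40, seed = 13))
  rep <- run_curation(sim$table, sim$meta)
  meta_kept <- sim$meta[sim$meta$sample_id %in% colnames(rep$table), ]
  div <- alpha_diversity_table(rep$table, meta_kept,
                               rarefaction_spec(seed = 5))
  expect_true(all(div$d >= 1))
  # every sample's depth equals its protocol/run depth
  dep <- protocol_rarefaction_depth(rep$table, meta_kept,
                                    rarefaction_spec(seed = 5))
  key <- paste(div$protocol, div$primer_run)
  expect_equal(div$d, dep$depth[match(key, paste(dep$protocol,
                                                 dep$primer_run))])
  # deterministic under the same spec
  div2 <- alpha_diversity_table(rep$table, meta_kept,
                                rarefaction_spec(seed = 5))
  expect_identical(div, div2)
})

test_that("one-way ANOVA matches stats::aov and handles degenerate input", {
  # identical group means -> F = 0, p = 1
  res <- anova_alpha(c(1, 2, 3, 1, 2, 3), rep(c("g1", "g2"), each = 3))
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)

  # zero within-group variance with unequal means -> degenerate limit
  expect_warning(res <- anova_alpha(c(1, 1, 2, 2), c("a", "a", "b", "b")),
                 "infinite")
  expect_identical(res$F, Inf)
  expect_equal(res$p, 0)

  expect_error(anova_alpha(c(1, 2), c("a", "b")), "degrees of freedom")

  # textbook 3-group case against stats::aov
  set.seed(14)
  values <- c(rnorm(5, 0), rnorm(6, 1), rnorm(4, 3))
  groups <- rep(c("x", "y", "z"), c(5, 6, 4))
  res <- anova_alpha(values, groups)
  ref <- summary(stats::aov(values ~ factor(groups)))[[1]]
  expect_equal(res$F, ref[["F value"]][1], tolerance = 1e-10)
  expect_equal(res$p, ref[["Pr(>F)"]][1], tolerance = 1e-10)

  # F invariant under affine rescaling of the response
  res2 <- anova_alpha(3.7 * values - 11, groups)
  expect_equal(res2$F, res$F, tolerance = 1e-10)
})
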