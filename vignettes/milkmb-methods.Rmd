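---
title: "Methods: replicate-level evaluation of milk DNA extraction protocols"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: replicate-level evaluation of milk DNA extraction protocols}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(milkmb)
```

## The model of the study

The package operates on the output of a nested benchmarking design for
low-biomass milk microbiome sequencing. Four prototype quarter-milk
samples span a 2×2 grid of somatic cell count (SCC, host inflammation
marker) and colony-forming units (cfu, culturable bacterial load):
`SCC-cfu-`, `SCC+cfu-`, `SCC+cfu+`, `SCC-cfu+`. In a pretrial, six DNA
extraction protocols (P1–P6) each process every prototype in duplicate
(P4, P5) or triplicate (P1, P2, P3, P6), with one nuclease-free-water
control per protocol and extraction replicate, and everything is
sequenced with two 16S primer pairs (V1V2, V3V4): 64 milk + 16 water =
80 extraction data sets per run, plus a mock community and a no-template
control. Protocols whose median clean reads exceed 1000 in **both** runs
advance to a main trial in which the original extracts are resequenced
in triplicate: 4 samples × (3+2+3) extracts × 3 sequencing replicates =
96 milk data sets, 120 with the water controls.

All analysis starts from the ASV (amplicon sequence variant) count
table; read denoising and taxonomic classification are upstream inputs,
not part of this package.

## Curation rules and their parameters

All thresholds live in `curation_params()` and are logged verbatim by
the pipeline. The "less/more than" wording is implemented strictly:

| parameter | default | unit | rule |
|---|---|---|---|
| `tau_depth` | 500 | reads | sample removed iff total < 500 |
| `tau_rel` | 0.01 | % of grand total | ASV removed iff pooled share < 0.01 % |
| `tau_flag_reps` | 2 | blank replicates | flag needs presence in > 2 |
| `tau_flag_count` | 100 | reads | flag needs one blank count > 100 |
| `tau_median` | 1000 | reads | protocol selected iff median > 1000 in both runs |

`run_curation()` applies, in fixed order: water-only removal (ASVs with
zero milk reads but positive blank reads), single-hit removal (non-zero
in exactly one sample, any count), the sample depth filter, the pooled
rarity filter; then the two flag computations. Design choices a
maintainer should know:

* **Pooled, not per-sample, rarity.** "Relative abundance across all
  samples" is read as pooled count over the grand total. A per-sample
  variant would keep locally-abundant singletons the single-hit rule
  targets anyway.
* **Flags never remove.** Recurrent-blank and foreign-taxon flags are
  annotations; `drop_flagged = TRUE` is a separate policy switch. This
  mirrors curation practice where flagged taxa are reviewed, not
  auto-deleted — borderline cases (a genus in two-of-three blanks, a
  plausible-but-suspicious skin commensal) are judgment calls the
  package deliberately does not automate.
* **Blank flags see pre-depth-filter blanks.** Water controls usually
  fall below 500 reads, yet they carry the contamination evidence; the
  recurrent-blank flag is therefore evaluated against the blank columns
  as they stood before sample filtering.
* **Foreign flagging is genus-level.** Index-swap plausibility operates
  on the genus annotation (the rank a naïve Bayes classifier supplies
  reliably); ASVs without a genus are never flagged, only counted in a
  notice. The flagged milk-read share is reported per primer run, the
  scale on which swap rates are quoted (≈1.6 % V1V2, ≈1.1 % V3V4).

Every ASV ends in exactly one removal disposition (`kept`,
`removed:water_only`, `removed:single_hit`, `removed:rare`), flags may
coexist with `kept`, and each filter is idempotent — all three
properties are under test.

## Diversity

Samples are rarefied **within protocols** (per primer run), never
across: rarefying everything to the weakest protocol's depth would
punish the better protocols for their own strength, which is the
quantity under study. The default depth policy is the minimum retained
clean-read total among the protocol's milk samples; explicit depths are
accepted as configuration because published depths need not be
derivable from any single policy. Rarefaction is a seeded draw without
replacement totalling exactly `d`; shallower samples are excluded, never
up-sampled. One draw per sample is the default (`n_rep` allows
averaging); the seed is recorded in the run log.

Indices: richness `R` (non-zero ASVs after rarefaction), Shannon
`H = -sum(p log p)` in **nats** (matching reported magnitudes of ~2–3.5),
Pielou evenness `E = H / log(R)`, undefined at `R <= 1`. The analytic
check for the rarefaction engine is the multivariate hypergeometric
expectation `E[R] = sum_i (1 - C(N - n_i, d) / C(N, d))`, evaluated in
log space so it remains finite at totals of 10^6.

One-way fixed-effects ANOVA compares an index across the four prototype
samples within one protocol × run (replicates are the observations);
swapping roles gives the protocol comparison. No mixed-effects
modelling of the nested design is attempted — plain ANOVA is what the
workflow being reproduced used. The degenerate zero-within-variance
case returns the `F = Inf`, `p = 0` limit with a warning.

## Reproducibility

β-diversity uses Bray–Curtis on TSS proportions by default (depth
differences would otherwise dominate); PCoA is classical metric scaling
(double-centering, eigendecomposition, coordinates scaled by the square
root of positive eigenvalues). Bray–Curtis is a semimetric, so negative
eigenvalues can occur; they are reported, excluded from coordinates,
and no Lingoes/Cailliez correction is applied. Replicate dispersion is
the mean dissimilarity over unordered within-group pairs.

The clean-read variability decomposition defines, per (protocol, run,
prototype): the **sequencing** component as the largest within-extract
range of resequencing replicates, and the **total** component as the
largest absolute difference between data sets from *different*
extracts. `ratio_pct` may exceed 100 %: a single extract's resequencing
spread can beat every cross-extract difference. "Maximum difference" is
one consistent reading of an under-specified quantity; the
pair-enumeration definition is frozen here because it is the one that
admits ratios above 100 %, which the real data exhibit.

## The synthetic world

`simulate_study()` states the world once; its defaults are not tuned to
test outcomes:

* Base composition per prototype ~ Dirichlet(0.3) over `G = 150` ASVs
  (sparse, amplicon-like).
* Per-protocol extraction bias: per-ASV log-normal factor, SD 0.5 —
  protocols see systematically shifted communities, which is what makes
  protocol separation in a PCoA non-trivial.
* Per-extract perturbation `sigma_ext = 0.3` applied to the composition
  **and** as a multiplier on the extract's expected depth. The second
  application is a deliberate extension of the composition-only reading:
  extraction yield drives read numbers, and without it the variability
  ratio would be independent of extraction noise, contradicting the very
  property the decomposition is meant to expose.
* Sequencing depth per replicate ~ log-normal around the protocol × run
  median with `depth_sigma = 0.7`; medians default to the published run
  medians (pretrial P2 268/983 … P6 6175/11564; main P3 1779/3341,
  P4 2263/8860, P6 22810/17643; P1 is an order-of-magnitude stand-in of
  400/1200 since no value is printed). These are order-of-magnitude
  matches, not fits — the real per-protocol depth distributions are only
  summarized by their medians.
* Index swapping: each read is foreign with probability `epsilon`
  (run defaults 0.0164 / 0.011), drawn from a labelled foreign pool; the
  swapped count per data set is recorded exactly, and column totals
  always equal the planted depth.
* Blanks contain only kit contaminants (per-protocol ASV sets, Poisson
  counts, presence dropout 0.7 per extraction replicate — contamination
  tracks the kit, not the handling) plus swapped reads. Mock = equal
  1/8 mix of the 8 bacterial mock genera (the vendor's exact
  distribution is not public here; equality avoids inventing numbers);
  NTC is near-empty foreign/artifact reads.

What the generator does **not** emulate: PCR/chimera artifacts,
taxonomic misclassification, compositional correlations between taxa,
run-to-run batch effects beyond depth and epsilon. A green
synthetic-recovery test therefore establishes that the *rules* are
implemented as defined — not that the rules are sufficient for real
milk data.

## A criterion left red, on purpose

One stated acceptance property — "with `sigma_ext = 0` the median
variability ratio is ≥ 100 %" — is incompatible with the frozen
pair-enumeration definition of `total_var`. With independent
per-replicate depths, whenever the global maximum and minimum fall in
different extracts (probability `1 - (m-1)/(n-1) > 1/2` for every
extract count here), the cross-extract maximum equals the global range
and strictly bounds every within-extract range, forcing the ratio below
100 %. Simulation confirms a median near 92–93 %. The assertion is kept
as stated and fails honestly rather than being weakened; the companion
properties (oracle equivalence of the decomposition; ratio decreasing
in `sigma_ext`) hold and pass.

## Numerical conventions

TSS columns sum to 1 within 1e−9; Bray–Curtis oracle agreement is
asserted at 1e−9 and PCoA embedding recovery at 1e−8; medians of even
counts are the mean of the central pair; all "less/more than" thresholds
are strict; every random draw flows from one top-level seed through
named substreams (simulation, per-sample rarefaction), and RNG state is
restored after seeded operations so library calls never perturb user
code.
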