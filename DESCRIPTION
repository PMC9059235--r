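Package: milkmb
Title: Replicate-Level Evaluation of DNA Extraction Protocols for Milk
    Microbiome Amplicon Data
Version: 0.1.0
Authors@R:
    person("milkmb", "maintainers", email = "maintainers@milkmb.example.org",
           role = c("aut", "cre"))
Description: Tools for evaluating 16S rRNA amplicon sequencing of bovine
    milk at the level of extraction and sequencing replicates. Implements
    rule-based curation of ASV count tables against water extraction
    controls (blank-only removal, single-hit removal, depth and pooled
    rarity filters, recurrent-blank and index-swap plausibility flags),
    total sum scaling, protocol-specific rarefaction with Shannon,
    richness and Pielou evenness plus one-way ANOVA, Bray-Curtis
    dissimilarity and principal coordinates analysis, a decomposition of
    clean-read variability into sequencing and total (extraction plus
    sequencing) components, and a median clean-read protocol-selection
    rule. A synthetic-data generator reproduces the nested study design
    (prototype milk samples in a 2x2 somatic-cell-count by
    colony-forming-unit layout, multiple protocols, replicate extraction
    and resequencing, kit-specific blank contaminants, index swapping) so
    that every pipeline stage can be exercised offline against planted
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
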