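Package: combsig
Title: Combinatorial SNP-Genotype Disease Signatures and Expanded
    Genotypes Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines case-control genotype data for combinatorial disease
    signatures: sets of exact SNP-genotype states (0/1/2 minor-allele
    counts) that co-occur in cases far more often than expected.
    Signatures are discovered in layers of increasing combinatorial
    order, filtered on case prevalence, Fisher exact p-value and odds
    ratio relative to the cohort mean odds, and validated by a
    permutation-calibrated Benjamini-Hochberg false-discovery procedure
    in which the full search is re-run on label-permuted data. Validated
    signatures are merged into a disease-architecture network, critical
    SNPs are scored by cross-validated Random Forest prediction and a
    permutation test, and mapped to genes by a cascade (coding-region
    containment, then a strand-aware 2kb-upstream/0.5kb-downstream
    window). Expanded Genotypes Analysis (EGA) disentangles a critical
    SNP's effect from its interacting partners by enumerating all 3^k
    genotype assignments, computing per-block EGA odds ratios with Woolf
    confidence intervals, and classifying the causality pattern into
    seven categories. Includes quartile-based symptom-change cohort
    construction, ancestry-confounder screening, phenotype enrichment,
    seeded (hypothesis-driven) mining, and a synthetic-data generator
    with Hardy-Weinberg genotypes, Balding-Nichols population structure
    and planted epistatic signatures so every stage is testable
    end-to-end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph,
    randomForest,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
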