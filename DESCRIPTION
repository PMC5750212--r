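Package: hsmscan
Title: Haplotype-Specific DNA Methylation Scanning in GWAS LD Blocks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects haplotype-specific DNA methylation (HSM) within GWAS
    linkage-disequilibrium blocks from MeDIP-seq window scores. Builds
    recombination-bounded LD blocks from a genetic map, tiles 500 bp sliding
    windows, normalizes window scores (RPM and rank-based inverse-normal),
    tests each window for association with GWAS-SNP allelic count using
    covariate-adjusted linear models and family-structured linear mixed
    models compared by likelihood-ratio test, applies a Bonferroni threshold
    with tri-cohort directional consensus, merges surviving windows into HSM
    peaks, annotates peaks by overlapping variant classes (CNV, indel, STR,
    eSTR) and SNPs that create or abolish CpG dinucleotides, computes
    dual-background overlap enrichment (Fisher's exact test, odds ratios,
    tissue-panel fold enrichment), and provides a methylation-array
    per-probe mixed-model analysis with SNP-proximity probe pruning and
    genotype-permutation empirical nulls. A synthetic three-cohort generator
    with planted effects makes the full pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    lme4
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
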