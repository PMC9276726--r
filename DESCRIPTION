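Package: sweepscan
Title: Selective-Sweep Scans from Multi-Population SNP Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects selective-sweep candidate regions from a multi-population
    VCF of biallelic SNPs: GATK-style hard filtering and cohort QC, per-population
    allele frequencies, sliding-window Weir-Cockerham Fst and nucleotide-diversity
    (theta-pi) ratio scans with top-quantile outlier intersection and
    bedtools-style region merging, a per-SNP delta-allele-frequency screen for
    population-specific near-fixed alleles, ANNOVAR-style functional annotation
    of SNPs against gene models with coding-effect calls, population-structure
    summaries (genotype PCA, allele-sharing distances, neighbor-joining tree,
    LD decay), and hypergeometric gene-set enrichment. Includes a
    Balding-Nichols cohort simulator with designated sweep intervals so the
    whole pipeline is testable end to end with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    vcfR,
    ape,
    Biostrings,
    IRanges,
    S4Vectors,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
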