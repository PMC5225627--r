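Package: poolDiv
Title: Microsatellite and Pool-Seq Estimators of Genetic Diversity and
    Differentiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimators of population genetic diversity and differentiation
    for two marker systems and the statistics needed to compare them.
    Implements pooled-sequencing (Pool-Seq) estimators from per-site read
    counts in PoPoolation2 "sync" format (biallelic SNP calling with
    coverage and minor-allele-count filters, SNP expected heterozygosity,
    detection-weighted Watterson's theta per gene, pooled Tajima's D,
    pooled pairwise FST), microsatellite estimators from GenePop genotype
    tables (expected heterozygosity, allelic richness, permutation G_IS,
    EM null-allele frequencies, Weir-Cockerham pairwise FST), a comparison
    battery (correlations, paired t-tests, pairwise Wilcoxon signed-rank
    tests, Mantel tests, Tajima's-D-versus-zero tests), and a SNP
    down-sampling procedure that determines how many random SNPs are needed
    for accurate genome-wide heterozygosity estimates. A synthetic-data
    generator with known ground truth (Balding-Nichols allele frequencies,
    binomial pool and read sampling, sequencing error) makes every stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    data.table,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
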