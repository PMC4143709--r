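Package: dualclust
Title: Dual-Clustering Association Screening for Rare Variants and
    Longitudinal Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene-based association screening between whole-genome
    sequencing genotypes and longitudinal phenotypes. Subjects are
    partitioned twice: once by an inverse-probability-weighted genotype
    similarity that up-weights sharing of rare alleles, and once by
    hierarchical clustering of covariate-adjusted trait trajectories.
    Association between the two partitions is scored per gene by the
    partition-retention I statistic and one-way ANOVA, with permutation
    p-values, multiplicity control, a linear weighted-kernel score test
    as comparator, and an ROC/AUC simulation harness for method
    evaluation. Includes a synthetic-data generator producing
    Hardy-Weinberg genotypes with a rare-variant-rich allele-frequency
    spectrum and longitudinal traits with covariate and gene-level
    genetic effects.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
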