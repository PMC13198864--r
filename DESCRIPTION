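Package: crossphase
Title: Across-Chromosome Phasing via Windowed Haplotype Similarity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Matches the within-chromosome phased haplotypes of different
    chromosomes by parent of origin, producing two genome-wide parental
    haplotype sets per focal individual without requiring genotyped
    relatives. Chromosomes are divided into windows bounded by strong
    recombination hotspots; within each window a haploid SNP-similarity
    score (a minor-allele-frequency-weighted longest identical run over
    the focal individual's heterozygous sites) is computed against every
    other cohort member, and the signed combination of Pearson
    correlations between windows' similarity profiles drives a greedy
    merge of window haplotypes into two parental sets. Includes
    trio-based evaluation of across-chromosome phasing accuracy (ACPA),
    the standard variant QC filters, and a seeded pedigree simulator
    (founders, Mendelian transmission with map-based crossovers,
    configurable distant relatives, switch-error injection) so the whole
    pipeline is testable on synthetic data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    vcfR,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
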