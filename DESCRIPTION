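Package: paleoimpute
Title: Simulation and Evaluation of Low-Coverage Ancient-Genome Imputation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying genotype imputation of low-coverage ancient
    genomes against a phased modern reference panel. Simulates multi-ancestry
    phased haplotype panels, diploid test genomes of in-panel or diverged
    ancestry, and ancient sequencing reads with residual CpG deamination after
    UDG treatment; computes genotype likelihoods, gold-standard validation
    calls, deamination masks, and pseudohaploid calls; imputes genotype
    likelihoods with a chunked diploid haplotype-copying hidden Markov model
    emitting genotype posteriors, dosages, and INFO scores; and evaluates
    results with genotype concordance, recovery, error rate, non-reference
    discordance, MAF-stratified tables, sliding-window outlier scans, runs of
    homozygosity, and least-squares PCA projection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    withr,
    readr,
    Rcpp,
    stats,
    utils,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
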