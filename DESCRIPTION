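Package: evosteer
Title: Stochastic Models and Inference for Evolutionary Steering of
    Barcoded Tumour Cell Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing and analysing lineage-tracing experiments
    in which drug sequences steer the clonal evolution of barcoded cancer
    cell populations. Provides exact and Monte Carlo simulators of
    experimental evolution (Gillespie birth-death outgrowth of barcoded
    lineages, replicate splitting with an analytic occupancy oracle,
    re-plating waiting times for resistant mutants), a barcode-sequencing
    pipeline (quality filtering, flank-anchored extraction, Hamming
    error-merging onto weak/strong-patterned representatives, growth-rate
    estimation and resistance-phenotype assignment), post-variant-calling
    genomic statistics (VAF enrichment, BAF/LRR, segment heterozygosity
    testing, ASCAT-style ploidy grid search, depth-ratio calls), drug-screen
    analytics (percent inhibition, top-six hit calling, log-logistic
    dose-response fitting), and a synthetic-data generator that emulates the
    full experimental design for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    Biostrings,
    minpack.lm,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
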