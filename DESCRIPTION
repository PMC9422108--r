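Package: vicimpute
Title: Vicinity-Based Li-Stephens Hidden Markov Model Genotype Imputation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genotype imputation of untyped variants from a phased reference
    haplotype panel using the Li-Stephens hidden Markov model evaluated on a
    small genetic-distance window around each target variant. Implements
    forward-backward posterior estimation and Viterbi maximum-likelihood
    mosaic-path inference with numerically rescaled or log-domain dynamic
    programming, optional haplotype block clustering, IMPUTE2 genetic-map
    interpolation, VCF input/output with genotype posteriors and dosages,
    minor-allele-frequency stratified concordance and precision-recall
    evaluation, and a synthetic mosaic-haplotype benchmark generator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    vcfR,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
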