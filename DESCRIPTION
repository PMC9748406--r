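Package: admixsmc
Title: Admixture Time Inference from a Single Diploid Genome via a
    Coalescent Hidden Markov Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extends the pairwise sequentially Markovian coalescent (PSMC)
    hidden Markov model over binned diploid heterozygosity with the time of
    the most recent population admixture event as a free parameter. Provides
    the discrete-time coalescent transition kernel with a three-case
    admixture-aware conditional transition, Baum-Welch expectation
    maximization with a profile search for the admixture time and the
    admixed population size ratio, posterior decoding of the time to the
    most recent common ancestor along the genome, a self-consistent
    sequentially Markovian simulator of ternary heterozygosity tracks with
    ground truth, psmcfa input/output, and accuracy metrics for
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
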