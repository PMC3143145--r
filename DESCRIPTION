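Package: mitonuclear
Title: Mito-Nuclear Population Structure, Demography and Admixture Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to disentangle layered admixture in haplodiploid pest
    populations from paired mitochondrial (haploid) and nuclear (diploid)
    sequence alignments. Provides Bayesian admixture-model clustering with a
    Gibbs sampler and Evanno-style delta-K model choice, linkage-disequilibrium
    robustness filtering, per-isolate diversity statistics (segregating sites,
    haplotype diversity, nucleotide diversity, Tajima's D), AMOVA-based
    Phi-statistics with genotype-unit permutation tests, mismatch-distribution
    fitting under the sudden-expansion model with parametric-bootstrap
    goodness of fit, a rule-based genetic-profile classifier of demographic
    scenarios, and a structured-coalescent simulator of hybridization,
    secondary-contact and founder-bottleneck scenarios with haplodiploid
    inheritance for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tibble,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
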