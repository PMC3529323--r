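Package: retrosig
Title: Meta-Analysis of Transcriptional Responses to Mitochondrial and
    Chloroplast Perturbations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing nuclear transcriptional responses to
    perturbations of mitochondrial and chloroplast function across
    compendia of expression experiments. Implements per-experiment
    differential-response calling with a Bayesian-regularized t statistic
    and a beta-uniform mixture posterior probability of differential
    expression (PPDE), recurrence counting across experiment classes,
    overlap and compartment-enrichment statistics under a hypergeometric
    null with a permutation cross-check, organelle-specific marker-gene
    classification, hierarchical clustering of experiments on fold-change
    profiles, and IUPAC promoter-motif counting with enrichment tests.
    Ships a synthetic-compendium generator with planted ground truth for
    calibration and benchmarking, and a pipeline orchestrator that writes
    reproducible tabular artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml,
    Biostrings,
    ape
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
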