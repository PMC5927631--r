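Package: renaltiming
Title: Molecular Timing of Landmark Events in Clear Cell Renal Cell Carcinoma
Version: 0.1.0
Authors@R:
    person("Renal", "Timing", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative machinery for timing landmark somatic events in
    clear cell renal cell carcinoma (ccRCC) from multi-region whole-genome
    sequencing, and for modelling the early clonal dynamics of the disease.
    Implements mutation-copy-number timing of chromosome-arm gains,
    Dirichlet-process clustering of mutations by cancer cell fraction with
    pigeonhole ordering into a clone tree, random-slope linear mixed-effect
    estimation of the somatic mutation rate per year, a per-cell VHL
    driver-mutation-rate calculus from the trinucleotide mutation spectrum,
    a Gibbs/Metropolis-Hastings sampler for a three-stage waiting-time model
    of kidney-cancer age incidence that estimates the size of the 3p-loss
    precursor clone, preventive-intervention counterfactuals, chromothripsis
    hallmark statistics, and a synthetic-cohort generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
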