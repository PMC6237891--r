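Package: codonlife
Title: Codon Composition, Wobble-Position Statistics and Prediction of
    Protein Homeostasis Parameters
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools linking coding-sequence composition to protein
    homeostasis. Extracts codon and amino-acid percentages, GC3
    (wobble-position) content and physicochemical indices from coding
    sequences; screens features against protein lifetimes and related
    parameters across replicate datasets with synonymous-subgroup
    wobble summaries; fits cross-validated predictive models (random
    forest, elastic net, greedy forward-backward least squares) with
    scaled feature importances; designs translation-preserving
    synonymous gene variants at target G-/C-ending codon percentages;
    and fits pulse-chase fluorescence decay curves with cell-division
    dilution correction. A seeded synthetic-data generator provides
    cohorts with planted, recoverable statistical structure for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    Biostrings,
    glmnet,
    ranger,
    caret,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
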