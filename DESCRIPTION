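Package: dualscreen
Title: Dual-State Signature Drug Screening with ssGSEA Projection and
    Synergy Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An in silico drug-screening pipeline for paired tumor cell
    states. Derives stem-like and differentiated expression signatures from
    matched two-group RNA-seq via the signal-to-noise ranking metric,
    projects a cell-line expression panel onto those signatures with a
    from-scratch single-sample GSEA (ssGSEA), and nominates candidate drugs
    by Pearson correlation of signature scores against a drug-sensitivity
    AUC matrix with Benjamini-Hochberg correction. Validation tooling
    includes four-parameter-logistic IC50 fitting, highest-single-agent
    (HSA) synergy scoring with band classification, a z-score/t-test/
    fold-change differential-expression rule, preranked GSEA with
    permutation significance, and seeded synthetic-data generators that
    emulate matched expression pairs, cell-line panels, AUC screens and
    dose-response surfaces with exposed ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
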