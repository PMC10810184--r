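Package: dbrmeta
Title: Ligand-Aware Evaluation and Transformer Meta-Prediction of DNA-Binding Residues
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating and combining sequence-based predictors of
    DNA-binding residues (DBRs). Implements ligand-aware assessment metrics
    that separate cross-predictions (residues binding non-DNA ligands called
    as DNA-binding) from over-predictions (non-binding residues called as
    DNA-binding): the area under the low false-positive-rate part of the ROC
    curve (AULC) and its random-baseline ratio, cross- and over-prediction
    rates (CPR/OPR) with calibrated operating points, the areas under the
    CPR-vs-TPR and OPR-vs-TPR curves (AUCPC/AUOPC), a stratified subsampling
    protocol for paired significance testing, and a sequence-proximity
    analysis of false positives relative to native binding residues. Also
    provides a transformer-based meta-predictor that fuses per-residue
    propensity tracks from complementary base predictors with
    physicochemical-scale and disorder-aggregate features, and a synthetic
    data generator that emulates the class composition of mixed
    structure- and disorder-annotated benchmark datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    nortest,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
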