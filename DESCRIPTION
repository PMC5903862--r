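Package: nmregen
Title: Lineage Reconstruction and Cell-Fate Prediction for Regenerating Neuromasts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing whole-organ regeneration from single-cell
    time-lapse tracking data of the zebrafish lateral-line neuromast.
    Reconstructs heap-encoded cell lineages from track tables, classifies
    clones and divisions by daughter fate, quantifies division waves,
    generation-resolved cell-cycle lengths and two-segment (change-point)
    cycle-length regressions, extracts 32 spatial and neighbourhood features
    per cell and timepoint, and trains bagged-tree random-forest fate
    predictors evaluated by leave-one-experiment-out cross-validation with
    bootstrapped Matthews correlation. Includes an agent-based simulator of
    neuromast regeneration that emits track tables with ground truth, so the
    full pipeline can be exercised and validated without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ranger,
    stats,
    utils,
    yaml
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
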