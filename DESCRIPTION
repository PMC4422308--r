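Package: fnirsblock
Title: Block-Design Multi-Channel fNIRS Analysis and Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for block-design functional near-infrared
    spectroscopy (fNIRS) studies: modified Beer-Lambert conversion of
    dual-wavelength optical-density changes to hemoglobin concentration
    changes, moving-average filtering, epoch extraction, integral-mode
    baseline correction, repetition and grand averaging, channel-wise
    two-group Student's t statistics with Benjamini-Hochberg false
    discovery rate control, Spearman covariate correlations, and
    topographic t-statistic mapping over a 24-channel prefrontal probe
    montage. Includes a calibrated synthetic-study generator (canonical
    double-gamma hemodynamic responses, drift, physiological oscillations,
    motion spikes) so the whole pipeline is testable without access to
    subject recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
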