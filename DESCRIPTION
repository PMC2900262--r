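Package: beadmiR
Title: Bead-Based Quantification of microRNA Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis of suspension bead-array (xMAP-style)
    microRNA assays. Provides a generative model of per-bead-event
    fluorescence (saturating calibration response, mismatch probes,
    spike-in control, probe aging), the median-fluorescence processing
    pipeline (background correction, spike normalization, replicate
    summaries with quadratic error propagation), two-segment log-log
    calibration fitting with linear-range and limit-of-detection
    estimation, hybridization mismatch-specificity scoring, TaqMan-style
    2^-ddCt relative quantification, and cross-platform Spearman rank
    concordance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
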