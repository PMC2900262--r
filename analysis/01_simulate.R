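#!/usr/bin/env Rscript
# Step 1 — generate the study's synthetic datasets.
#
# One seed drives everything: a calibration dilution series (with a
# multi-day copy for bead-stability assessment), a mismatch-specificity
# plate at 18.75 fmol, an expression plate over the 7-cell-line panel plus
# pooled reference, and matched microarray/qPCR readouts from the same
# latent abundances.  Plates are written as bead-event CSV + layout TSV +
# probe-map TSV + config so later steps exercise the file readers.

suppressPackageStartupMessages(library(beadmiR))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[[1]]) else 1L
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- assay_config(seed = seed)
panel <- cell_line_panel()

message("simulating with seed ", seed)

calib <- simulate_calibration(cfg)
write_plate(calib, file.path(out, "calibration"))

# the multi-day stability plate is regenerated in step 2 from the same seed
write_plate(simulate_specificity(cfg), file.path(out, "specificity"))
write_plate(simulate_expression(cfg, panel), file.path(out, "expression"))

mp <- simulate_matched_platforms(panel, cfg)
write_ct_table(mp$ct, file.path(out, "qpcr_ct.csv"))
write_results(mp$microarray, file.path(out, "microarray_log2.tsv"))

message("wrote plates and matched-platform tables under ", out)
message("calibration wells: ", nrow(calib$layout),
        " | events: ", nrow(calib$events))
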