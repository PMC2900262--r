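#!/usr/bin/env Rscript
# Step 4 — relative expression over the cell-line panel.
#
# Processes the expression plate from step 1: spike-normalized per-well
# values, replicate means with quadratic error propagation, and log2 ratios
# of every sample against the pooled reference.

suppressPackageStartupMessages(library(beadmiR))

sim <- "results/sim"
dir.create("results", showWarnings = FALSE)

events <- read_bead_events(file.path(sim, "expression_events.csv"))
layout <- read_plate_layout(file.path(sim, "expression_layout.tsv"))
probe_map <- utils::read.delim(file.path(sim, "expression_probes.tsv"))

mfis <- compute_mfi(events)
bc <- background_correct(mfis, layout)
norm <- spike_normalize(bc$corrected)
summ <- summarize_expression(norm, layout, reference_sample = "POOL",
                             probe_map = probe_map)
write_results(summ, "results/expression_log2_ratios.tsv")

for (m in setdiff(unique(summ$probe_id), "Spike-18")) {
  d <- summ[summ$probe_id == m & summ$sample != "POOL", ]
  up <- d$sample[order(-d$log2_ratio)][1:2]
  message(m, ": highest log2 ratios in ", paste(up, collapse = ", "),
          sprintf(" (%.2f, %.2f)", sort(d$log2_ratio, TRUE)[1],
                  sort(d$log2_ratio, TRUE)[2]))
}
message("QC-removed readings: ",
        sum(bc$corrected$qc != "ok"), " of ", nrow(bc$corrected))
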