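#!/usr/bin/env Rscript
# Step 5 — ddCt relative quantification and cross-platform concordance.
#
# Converts the qPCR Ct table to 2^-ddCt relative quantities against the
# RNU6B endogenous control with POOL as calibrator, then computes per-miRNA
# Spearman rank correlations between the bead, microarray and qPCR profiles
# (all on a log2 scale; rank correlation is scale-invariant anyway).

suppressPackageStartupMessages(library(beadmiR))

sim <- "results/sim"
dir.create("results", showWarnings = FALSE)

ct <- read_ct_table(file.path(sim, "qpcr_ct.csv"))
rq <- relative_quantification(ct, control_assay = "RNU6B",
                              calibrator_sample = "POOL")
write_results(rq, "results/qpcr_rq.tsv")

summ <- utils::read.delim("results/expression_log2_ratios.tsv")
bead <- data.frame(sample = summ$sample, mirna = summ$probe_id,
                   value = summ$log2_ratio)
bead <- bead[bead$sample != "POOL" & bead$mirna != "Spike-18", ]

arr <- utils::read.delim(file.path(sim, "microarray_log2.tsv"))
arr <- data.frame(sample = arr$sample, mirna = arr$mirna,
                  value = arr$log2_ratio)

qp <- data.frame(sample = rq$sample, mirna = rq$assay,
                 value = -rq$delta_delta_ct)  # log2 of RQ
qp <- qp[qp$sample != "POOL", ]

conc <- spearman_concordance(list(xmap = bead, microarray = arr, qpcr = qp))
write_results(conc, "results/platform_concordance.tsv")
for (i in seq_len(nrow(conc))) {
  message(sprintf("%-9s %s vs %s: rho = %.2f (n = %d)",
                  conc$mirna[i], conc$platform_a[i], conc$platform_b[i],
                  conc$rho[i], conc$n_samples[i]))
}
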