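# beadmiR

Quantifying individual microRNAs with suspension bead arrays (xMAP-style):
an R package that implements the full measurement pipeline for bead-based
miRNA assays and a generative simulator of the assay used to validate every
step against known truth.

In these assays, DNA capture probes complementary to mature miRNAs are
coupled to color-coded microspheres; labeled small-RNA populations
hybridize in solution and a flow reader reports, per well and bead region,
the median fluorescence intensity (MFI) over ≥ 100 beads. Raw MFI is not
comparable across probes or samples: hybridization saturates, each bead set
has its own background, and labeling efficiency varies per sample. The
pipeline here is the standard chain

```
event fluorescence → median MFI (≥100-event rule)
                   → per-region background subtraction + QC removal
                   → per-well spike-control normalization
                   → replicate means, log2(sample/POOL) ratios with
                     quadratic error propagation (relSD quadrature,
                     σ_log2 = relSD/ln 2) and t-based 95% CIs
```

plus:

* **Calibration**: two-segment OLS fit in log10–log10 space with exhaustive
  knot search over observed amounts (segments share the knot point, no
  continuity constraint); linear dynamic range = fitted knot down to the
  mean + 3 SD background limit of detection; bead-stability retention over
  days post-conjugation.
* **Specificity**: mismatch-probe signal as percent of the perfect-match
  probe, with one-sided Welch tests of the decrease.
* **Relative quantification**: TaqMan-style 2^−ΔΔCt against an endogenous
  control and calibrator sample.
* **Concordance**: per-miRNA Spearman rank correlations between bead,
  microarray and qPCR expression profiles.

The simulator (`assay_config()`, `simulate_calibration()`,
`simulate_specificity()`, `simulate_expression()`,
`simulate_matched_platforms()`) generates per-bead-event fluorescence with
a saturating two-slope response (slopes 0.94/0.15 meeting at 18.75 fmol,
3000 MFI at the knot), lognormal event scatter, bead-specific background,
mismatch efficiencies (two-mismatch defaults encode 62%/85% signal drops),
probe aging past 35 days, per-sample labeling-efficiency factors that the
spike normalization must cancel, and a 7-cell-line panel plus pooled
reference shared with matched synthetic microarray/qPCR readouts. See the
methods vignette (`vignettes/bead-mirna-quantification.Rmd`) for the model
and design decisions.

## Worked example

The `analysis/` scripts run the whole study from one seed
(`Rscript analysis/01_simulate.R 1`, then steps 02–05). Condensed:

```r
library(beadmiR)
cfg <- assay_config(seed = 1)

## calibration: fit, linear range
cc  <- build_calibration_curve(simulate_calibration(cfg))
fit <- fit_two_segment(cc$curve)
fit
#> Two-segment log-log fit: slopes 0.9400 / 0.1500, knot 18.75 fmol, R2 0.9998
detect_linear_range(cc$curve, fit, cc$background_mfis)
#> $lower_fmol  0.0732421875
#> $upper_fmol  18.75

## mismatch specificity through the full pipeline
specificity_pipeline(simulate_specificity(cfg))
#>      mirna     probe_id pct_of_pm drop_pct      p_value n
#> 1  miR-27a  miR-27a-1MM      68.7     31.3 7.8e-04      3
#> 2  miR-27a  miR-27a-2MM      37.3     62.7 7.8e-05      3
#> 3 miR-199a miR-199a-1MM      55.9     44.1 1.8e-04      3
#> 4 miR-199a miR-199a-2MM      15.5     84.5 5.2e-04      3
```

(The printed fit above is from the noisy default run; a `noise_free(cfg)`
run recovers slopes 0.94/0.15 and knot 18.75 exactly with R² = 1.) The
linear range spans the seventh dilution point, 0.0732 fmol, up to the
saturation knot at 18.75 fmol; the two-mismatch probes lose ~62% (miR-27a)
and ~85% (miR-199a) of the perfect-match signal, both decreases significant
at p < 0.05. Step 04 recovers the panel's two-group pattern (miR-23a/27a
highest in RH4/RH30), and step 05 reports per-miRNA Spearman ρ between the
three platforms (0.86–1.00 at default noise, exactly 1 at zero noise).

## Layout

* `R/` — simulator (`simassay`), sequence utilities (`probekit`), file
  formats (`beadio`), pipeline (`quantify`), calibration (`calibrate`),
  ΔΔCt/concordance (`relquant`).
* `analysis/01–05_*.R` — the narrative study drivers; tables land in
  `results/`.
* `inst/extdata/capture_probes_table1.tsv` — packaged capture-probe set
  (PM/1MM/2MM variants and the Spike-18 control).
* `tests/testthat/` — unit, property and end-to-end acceptance tests.
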