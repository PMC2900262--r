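---
title: "Bead-based miRNA quantification: model, pipeline and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bead-based miRNA quantification: model, pipeline and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beadmiR)
```

## The measurement problem

Suspension bead arrays quantify individual miRNAs by hybridizing labeled
small-RNA populations to capture probes coupled to color-coded microspheres.
A flow reader classifies each bead by its internal dye code (its *region*)
and reads the reporter fluorescence on its surface; the median fluorescence
intensity (MFI) over at least 100 beads of a region in a well is the assay's
primary measurement. Because hybridization is saturable, because every bead
set has its own nonspecific background, and because labeling efficiency
varies between samples, raw MFI is not directly comparable across probes or
samples. This package implements the processing chain that makes it
comparable, together with a generative simulator of the whole assay so that
every step can be validated against known truth.

The pipeline, in order:

1. **MFI**: median of per-event fluorescence per (well, bead region);
   readings from fewer than 100 events are flagged and excluded.
2. **Background correction**: subtract, per bead region, the mean reading of
   that region in no-target wells; readings below their region's mean
   background are removed (with a QC reason code, never silently).
3. **Spike normalization**: each miRNA reading in a well is divided by the
   same well's spike-control reading. The spike is a synthetic RNA added in
   known amount *before* labeling, so the ratio cancels the per-sample
   labeling-efficiency factor. The ratio is taken per well and averaged,
   not computed from averages.
4. **Replicate summary**: per (sample, probe), mean and SD over wells; the
   log2 ratio against a pooled reference; the ratio's uncertainty by
   quadratic propagation of the relative SDs,
   $\mathrm{relSD}_R = \sqrt{\mathrm{relSD}_s^2 + \mathrm{relSD}_{ref}^2}$,
   mapped to the log2 scale by the delta method
   ($\sigma_{\log_2} = \mathrm{relSD}_R / \ln 2$); 95% CIs from Student *t*
   on $n-1$ degrees of freedom on the normalized scale.

Quadratic propagation is named as the principle but not given a scale in
the protocol this mirrors; relative-SD quadrature for the test/reference
ratio with a delta-method map to log2 is this package's reading, chosen
because the reported quantity is a log2 ratio of replicate means.

## The generative model

`assay_config()` holds every parameter. Signal for target amount $C$ (fmol)
is, in the default `piecewise` mode, a two-slope power law anchored at the
saturation knot:

$$
\log_{10} S(C) = \log_{10} S_k + s \cdot (\log_{10} C - \log_{10} C_k),
\qquad s = \begin{cases} s_1 = 0.94 & C \le C_k \\ s_2 = 0.15 & C > C_k
\end{cases}
$$

with $C_k = 18.75$ fmol and $S_k = 3000$ MFI. A `langmuir` mode
($B_{max} C/(K_d + C)$, defaults $B_{max} = 4000$ MFI, $K_d = 40$ fmol —
round values chosen only to place the half-saturation near the knot) is
provided as the mechanistic alternative; its low-concentration log-log slope
tends to 1, which the piecewise mode approximates with 0.94.

Around the model median, per-event fluorescence is lognormal with CV 0.25,
*median*-parameterized so the per-region sample median estimates the model
signal without transformation bias. Each (well, region) additionally draws a
background level $\mathcal{N}(30, 4^2)$ MFI; background wells contain only
that level. Mismatch probes scale the perfect-match signal by configured
efficiencies: the two-mismatch defaults 0.38 (miR-27a) and 0.15 (miR-199a)
encode the measured 62%/85% signal drops; the one-mismatch defaults
0.70/0.55 are placeholders that only respect the ordering
PM > 1MM > 2MM and are not measured values. Probe aging keeps full signal
to 35 days post-conjugation and decays as $e^{-0.004(d-35)}$ after.

Two response regimes are deliberately distinct:

* **Calibration and pure-target specificity plates** use the saturating
  model above — they exist to characterize the response curve itself.
* **Expression and complex-RNA plates** use the ideal proportional response
  $S = g\,C$ with $g = S_k / C_k$ (the chord through the knot). Within the
  linear range the assay is treated as proportional, which is the premise
  of ratio-based quantification; it also makes the zero-noise pipeline
  identity exact (recovered log2 ratio = latent log2 ratio), which is what
  the exactness tests assert. Latent panel abundances (0.7–4.8
  fmol-equivalents) sit inside the linear range.

Per-sample labeling efficiency is lognormal with log-SD 0.3 and multiplies
miRNA and spike signal alike — this is precisely what spike normalization
is designed to cancel, and the tests verify it cancels exactly at zero
noise.

**What "zero noise" means here:** `noise_free()` sets both the event CV and
the well-level background SD to zero. Both are needed for exact recovery:
with only the event scatter off, well-to-well background variation still
perturbs corrected MFIs.

### Fixed design choices of the simulator

* Dilution series: 8 points, 4-fold from 300 fmol. The printed endpoints
  (15 amol, 300 fmol) and interior values (18.75, 0.073 fmol) are jointly
  consistent with exactly this series (terminal point 18.3 amol).
* 8 background wells per plate (one plate column) — enough to estimate the
  per-region background mean and SD stably.
* Spike amount 4.6875 fmol: a mid-linear-range member of the series, so the
  spike reading is strong but unsaturated.
* Expression plate: 8 samples (7 lines + POOL) × 3 wells, 4 bead regions
  per well (miR-23a, miR-27a, miR-199a, Spike-18 on regions 1/21/51/57).
* Panel abundances: miR-23a and miR-27a elevated ~4-fold in the two
  fusion-positive lines (RH4, RH30), miR-199a elevated in the five
  fusion-negative lines; POOL is the arithmetic mean of the seven samples,
  enforced by construction.
* Matched platforms: microarray log2 ratios get Gaussian noise (SD 0.25
  log2 units, a typical two-channel array replicate spread); qPCR Ct is
  $30 - \log_2(\text{abundance})$ with replicate SD 0.15 cycles and an
  RNU6B control at constant abundance 50 (Ct ≈ 24.4).

These values were fixed once when the generator was designed; none of them
is a fitted quantity.

## Calibration fitting and the linear range

`fit_two_segment()` works on per-amount replicate means in
(log10 amount, log10 MFI) space. Every observed amount that leaves at least
3 points on each side is a candidate knot; the knot point is shared by both
segments; each side gets its own unconstrained OLS line (the two lines are
*not* forced to meet — the model is two straight lines, and an exact
piecewise dataset is recovered exactly this way). The knot minimizing total
SSE wins; SSE ties break toward the larger knot, the conservative choice
for the claimed extent of the linear range. $R^2$ is computed from the
combined residuals of both segments against the global mean. Readings
flagged below background are excluded before averaging — the same QC rule
the expression pipeline applies; without it, a lowest-dilution mean can be
non-positive under default noise and the log transform would be undefined.

The linear range is bounded above by the fitted knot (saturation onset) and
below by the limit of detection: the smallest measured amount whose raw MFI
exceeds mean + 3 SD of the background-well readings *in every replicate
well*. The 3-sigma rule is the conventional detection criterion, adopted
here as a stated decision (the protocol this mirrors reports the limit but
not the rule behind it). Under the default noise settings the
seventh dilution point (0.0732 fmol) clears the threshold by about one
background SD per well, so the detected LOD is the seventh point on most
seeds but can land one step higher on unlucky ones — an honest property of
a detection limit estimated from three wells.

Bead stability is summarized as retention: the geometric mean over amounts
of MFI(day)/MFI(reference day) on per-amount means, flagged stable at
retention ≥ 0.90. Retention should be assessed over detectable amounts;
sub-LOD points contribute background-noise ratios (the analysis scripts
filter them out).

## Relative quantification and concordance

`relative_quantification()` implements plain $2^{-\Delta\Delta Ct}$ against
an endogenous control and a calibrator sample, with no amplification-
efficiency correction. `spearman_concordance()` ranks each platform's
per-miRNA profile over shared samples (average ranks for ties) and reports
$\rho$ for every platform pair; profiles are passed on a log2 scale (bead
and array log2 ratios, $-\Delta\Delta Ct$ for qPCR) for plot comparability,
though rank correlation does not depend on it. The pooled reference is
excluded from concordance: it is the bead/array denominator, not a sample.

## Problem sizes and what the tests show

The packaged analyses and tests run at the assay's native scale: 100 events
per bead region, 3 replicate wells, 8-point dilution series, 7 + 1 samples.
Property tests use 50–200 simulated plates or 1000 random curves per
invariant. The simulator reproduces the *structure* of bead-array data —
saturation, bead-specific background, labeling-efficiency variation,
mismatch cross-talk, probe aging — but not sequence-driven
cross-hybridization (efficiencies are configured, not predicted from the
mismatch positions), carry-over between wells, or PCR amplification bias in
the labeling reaction. Passing tests therefore validate the processing
pipeline and its error propagation against a faithful generative model,
not the chemistry of any particular instrument run; printed cross-platform
correlations from the original cell-line study are context, not a target,
because those data were never deposited.

## Known limitations

* No 4PL/5PL logistic calibration or inverse prediction of unknown
  concentrations: the calibration curve is used only to state the linear
  range.
* Equal-length Hamming comparison only for probe variants; no alignment,
  no duplex thermodynamics (ΔG/Tm/LNA).
* No between-plate batch correction and no multiple-testing adjustment
  (two mismatch probes per miRNA; raw p-values are reported).
* The LOD rule and the significance test behind the mismatch drops are
  conventional choices (3-sigma; one-sided Welch t), stated as such.
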