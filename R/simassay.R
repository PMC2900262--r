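#' Assay configuration for the bead-array simulator
#'
#' Bundles every parameter of the generative model: the saturating
#' signal-vs-amount response, per-event lognormal scatter, bead-specific
#' background, mismatch hybridization efficiencies, probe-aging decay and
#' labeling-efficiency variation.  Defaults encode the measured assay
#' behaviour: a two-slope log-log calibration (slopes 0.94 / 0.15 meeting at
#' 18.75 fmol), two-mismatch signal drops of 62% (miR-27a) and 85%
#' (miR-199a), stability to 35 days post-conjugation, and 100 flow events
#' per bead region.
#'
#' @param seed Integer seed; all randomness in `simulate_*` flows from it.
#' @param events_per_bead Flow events recorded per bead region per well.
#' @param signal_mode `"piecewise"` (two-slope log-log response) or
#'   `"langmuir"` (bmax*C/(kd+C) binding isotherm).
#' @param s1,s2 Log10-MFI per log10-fmol slopes below/above the knot.
#' @param knot_fmol Target amount (fmol) at which the two segments meet.
#' @param mfi_at_knot Net signal MFI at the knot.
#' @param langmuir_bmax,langmuir_kd Langmuir-mode saturation MFI and
#'   half-saturation amount (fmol).
#' @param event_cv Coefficient of variation of per-event lognormal scatter
#'   (median-parameterized, so the per-region median estimates the model
#'   signal without bias).
#' @param bg_median Median background MFI (no-target signal).
#' @param bg_well_sd SD of the well-to-well (per bead region) background
#'   level around `bg_median`.
#' @param eff_1mm,eff_2mm Named numeric vectors: relative hybridization
#'   efficiency of one-/two-mismatch probes per miRNA (fraction of the
#'   perfect-match signal).  The two-mismatch defaults follow the measured
#'   62%/85% drops; the one-mismatch defaults are placeholders chosen only
#'   to respect PM > 1MM > 2MM.
#' @param aging_lambda Exponential decay rate (per day) of hybridization
#'   signal beyond `stable_days`.
#' @param stable_days Days post-conjugation with full signal retention.
#' @param labeling_eff_sd SD (log scale) of the per-sample lognormal
#'   labeling-efficiency factor; applied equally to miRNA and spike signal.
#' @param spike_fmol Amount of the pre-labeling spike control per well
#'   (fmol), constant per plate.
#' @param array_noise_sd SD (log2 units) of simulated microarray log-ratios.
#' @param ct_noise_sd SD (cycles) of simulated qPCR Ct replicates.
#' @param ct_intercept Ct of one latent abundance unit at zero noise.
#' @param u6_abundance Constant latent abundance of the RNU6B endogenous
#'   control, in the same relative units as the panel.
#' @param bead_regions Integer codes of the color-coded bead sets used.
#' @param n_background Number of no-target (background) wells per plate.
#' @return A validated `assay_config` list.
#' @export
assay_config <- function(seed = 1L,
                         events_per_bead = 100L,
                         signal_mode = c("piecewise", "langmuir"),
                         s1 = 0.94, s2 = 0.15,
                         knot_fmol = 18.75, mfi_at_knot = 3000,
                         langmuir_bmax = 4000, langmuir_kd = 40,
                         event_cv = 0.25,
                         bg_median = 30, bg_well_sd = 4,
                         eff_1mm = c("miR-27a" = 0.70, "miR-199a" = 0.55),
                         eff_2mm = c("miR-27a" = 0.38, "miR-199a" = 0.15),
                         aging_lambda = 0.004, stable_days = 35,
                         labeling_eff_sd = 0.3,
                         spike_fmol = 4.6875,
                         array_noise_sd = 0.25,
                         ct_noise_sd = 0.15,
                         ct_intercept = 30,
                         u6_abundance = 50,
                         bead_regions = c(1L, 21L, 51L, 57L),
                         n_background = 8L) {
  signal_mode <- match.arg(signal_mode)
  cfg <- list(seed = as.integer(seed),
              events_per_bead = as.integer(events_per_bead),
              signal_mode = signal_mode,
              s1 = s1, s2 = s2,
              knot_fmol = knot_fmol, mfi_at_knot = mfi_at_knot,
              langmuir_bmax = langmuir_bmax, langmuir_kd = langmuir_kd,
              event_cv = event_cv,
              bg_median = bg_median, bg_well_sd = bg_well_sd,
              eff_1mm = eff_1mm, eff_2mm = eff_2mm,
              aging_lambda = aging_lambda, stable_days = stable_days,
              labeling_eff_sd = labeling_eff_sd,
              spike_fmol = spike_fmol,
              array_noise_sd = array_noise_sd,
              ct_noise_sd = ct_noise_sd,
              ct_intercept = ct_intercept,
              u6_abundance = u6_abundance,
              bead_regions = as.integer(bead_regions),
              n_background = as.integer(n_background))
  validate_assay_config(cfg)
  structure(cfg, class = "assay_config")
}

validate_assay_config <- function(cfg) {
  stopifnot(cfg$events_per_bead >= 1L,
            cfg$event_cv >= 0, cfg$bg_well_sd >= 0,
            cfg$labeling_eff_sd >= 0,
            cfg$knot_fmol > 0, cfg$mfi_at_knot > 0,
            cfg$langmuir_bmax > 0, cfg$langmuir_kd > 0,
            cfg$spike_fmol > 0, cfg$aging_lambda >= 0,
            cfg$stable_days >= 0, cfg$n_background >= 1L)
  if (is.null(names(cfg$eff_1mm)) || is.null(names(cfg$eff_2mm)) ||
      !setequal(names(cfg$eff_1mm), names(cfg$eff_2mm))) {
    stop("eff_1mm and eff_2mm must be named vectors over the same probes")
  }
  for (p in names(cfg$eff_1mm)) {
    e1 <- cfg$eff_1mm[[p]]
    e2 <- cfg$eff_2mm[[p]]
    if (!(e2 > 0 && e1 > 0 && e2 <= 1 && e1 <= 1)) {
      stop("mismatch efficiencies for ", p, " must lie in (0, 1]")
    }
    if (!(e2 < e1 && e1 < 1)) {
      stop("require eff_2mm < eff_1mm < 1 for probe ", p)
    }
  }
  invisible(cfg)
}

#' Noise-free copy of an assay configuration
#'
#' Sets per-event scatter and well-level background scatter to zero, so
#' every per-region median equals the model signal plus the fixed background
#' exactly.  Used for exact-recovery checks of the calibration fit and the
#' quantification pipeline.
#'
#' @param config An [assay_config()].
#' @return The same configuration with `event_cv = 0` and `bg_well_sd = 0`.
#' @export
noise_free <- function(config) {
  stopifnot(inherits(config, "assay_config"))
  config$event_cv <- 0
  config$bg_well_sd <- 0
  config
}

#' Serial dilution design
#'
#' @param start_fmol Highest target amount (fmol).
#' @param fold Dilution factor between consecutive points (> 1).
#' @param n_points Number of points in the series.
#' @return A `dilution_design` list.
#' @export
dilution_design <- function(start_fmol = 300, fold = 4, n_points = 8L) {
  stopifnot(start_fmol > 0, n_points >= 1)
  if (fold <= 1) stop("dilution fold must be > 1")
  structure(list(start_fmol = start_fmol, fold = fold,
                 n_points = as.integer(n_points)),
            class = "dilution_design")
}

#' Amounts of a geometric dilution series
#'
#' The default 4-fold, 8-point series from 300 fmol spans 300 fmol down to
#' 18.3 amol and contains the interior calibration landmarks 18.75 fmol and
#' 0.073 fmol.
#'
#' @param design A [dilution_design()].
#' @return Numeric vector of amounts (fmol), strictly decreasing.
#' @export
make_dilution_series <- function(design = dilution_design()) {
  stopifnot(inherits(design, "dilution_design"))
  design$start_fmol / design$fold^(seq_len(design$n_points) - 1)
}

#' Model net signal (MFI) for a target amount
#'
#' Piecewise mode: log10 signal follows two connected lines with slopes
#' `s1` (below the knot) and `s2` (above), passing through
#' (`knot_fmol`, `mfi_at_knot`).  Langmuir mode: `bmax*C/(kd+C)`.
#'
#' @param amount Target amount(s) in fmol (> 0).
#' @param config An [assay_config()].
#' @return Net signal MFI (background excluded), vectorized over `amount`.
#' @export
signal_model <- function(amount, config) {
  stopifnot(all(amount > 0))
  if (config$signal_mode == "piecewise") {
    slope <- ifelse(amount <= config$knot_fmol, config$s1, config$s2)
    config$mfi_at_knot * (amount / config$knot_fmol)^slope
  } else {
    config$langmuir_bmax * amount / (config$langmuir_kd + amount)
  }
}

#' Signal retention due to probe aging
#'
#' Retention is 1 up to `stable_days` post-conjugation and decays
#' exponentially at rate `aging_lambda` per day afterwards.
#'
#' @param day Days post-conjugation (>= 0), vectorized.
#' @param config An [assay_config()].
#' @return Retention fraction in (0, 1].
#' @export
aging_retention <- function(day, config) {
  stopifnot(all(day >= 0))
  ifelse(day <= config$stable_days, 1,
         exp(-config$aging_lambda * (day - config$stable_days)))
}

# draw per-event fluorescence for a table of (well, region, median) rows;
# lognormal parameterized by its median so the sample median is unbiased
draw_events <- function(medians, config) {
  n <- config$events_per_bead
  total <- nrow(medians) * n
  med <- rep(medians$median_mfi, each = n)
  if (config$event_cv > 0) {
    sigma <- sqrt(log(1 + config$event_cv^2))
    fl <- med * exp(sigma * stats::rnorm(total))
  } else {
    fl <- med
  }
  data.frame(well = rep(medians$well, each = n),
             region = rep(medians$region, each = n),
             event = rep(seq_len(n), times = nrow(medians)),
             fluorescence = pmax(fl, 0),
             stringsAsFactors = FALSE)
}

# per-(well, region) background level draw
draw_background <- function(n, config) {
  pmax(config$bg_median + stats::rnorm(n, 0, config$bg_well_sd), 0)
}

new_simulated_plate <- function(events, layout, probe_map, truth, config) {
  structure(list(events = events, layout = layout, probe_map = probe_map,
                 truth = truth, config = config),
            class = "simulated_plate")
}

#' @export
print.simulated_plate <- function(x, ...) {
  cat("Simulated bead plate:", length(unique(x$layout$well)), "wells,",
      nrow(x$events), "events,",
      length(unique(x$events$region)), "bead regions\n")
  invisible(x)
}

#' Simulate a calibration (dilution-series) experiment
#'
#' One bead region (default the miR-199a probe region) hybridized against a
#' serial dilution of its synthetic target, with replicate wells, no-target
#' background wells, and optionally several days post-conjugation to probe
#' bead aging.  Per-well medians are `signal_model(amount) * retention(day)`
#' plus a well-level background draw; events scatter lognormally around the
#' median.
#'
#' @param config An [assay_config()].
#' @param design A [dilution_design()].
#' @param n_replicates Replicate wells per amount.
#' @param days Integer vector of days post-conjugation (each day gets its
#'   own set of wells; the `day` column in layout/events distinguishes them).
#' @param target_region Bead region code carrying the titrated probe.
#' @param target_probe Probe id for the region (annotation only).
#' @return A `simulated_plate` (events, layout, probe_map, truth, config).
#' @export
simulate_calibration <- function(config = assay_config(),
                                 design = dilution_design(),
                                 n_replicates = 3L,
                                 days = 0L,
                                 target_region = 51L,
                                 target_probe = "miR-199a") {
  stopifnot(inherits(config, "assay_config"), all(days >= 0),
            n_replicates >= 1)
  amounts <- make_dilution_series(design)
  with_seed(config$seed, {
    events_list <- list()
    layout_list <- list()
    truth_list <- list()
    for (d in days) {
      ret <- aging_retention(d, config)
      n_sig <- length(amounts) * n_replicates
      wells <- plate_wells(n_sig + config$n_background)
      sig_wells <- wells[seq_len(n_sig)]
      bg_wells <- wells[n_sig + seq_len(config$n_background)]
      amt <- rep(amounts, each = n_replicates)
      repl <- rep(seq_len(n_replicates), times = length(amounts))
      bg_levels <- draw_background(n_sig + config$n_background, config)
      med <- data.frame(
        well = c(sig_wells, bg_wells),
        region = target_region,
        median_mfi = c(signal_model(amt, config) * ret +
                         bg_levels[seq_len(n_sig)],
                       bg_levels[n_sig + seq_len(config$n_background)]),
        stringsAsFactors = FALSE)
      ev <- draw_events(med, config)
      ev$day <- d
      lay <- data.frame(
        well = c(sig_wells, bg_wells),
        sample_id = c(sprintf("cal_%gfmol", amt),
                      rep("background", config$n_background)),
        role = c(rep("test", n_sig),
                 rep("background", config$n_background)),
        replicate_index = c(repl, seq_len(config$n_background)),
        day = d,
        amount_fmol = c(amt, rep(NA_real_, config$n_background)),
        stringsAsFactors = FALSE)
      truth_list[[as.character(d)]] <- data.frame(
        well = med$well, day = d,
        amount_fmol = c(amt, rep(NA_real_, config$n_background)),
        signal = c(signal_model(amt, config) * ret,
                   rep(0, config$n_background)),
        bg_level = bg_levels, stringsAsFactors = FALSE)
      events_list[[as.character(d)]] <- ev
      layout_list[[as.character(d)]] <- lay
    }
    probe_map <- data.frame(region = target_region, probe_id = target_probe,
                            stringsAsFactors = FALSE)
    new_simulated_plate(
      events = do.call(rbind, events_list),
      layout = do.call(rbind, layout_list),
      probe_map = probe_map,
      truth = list(wells = do.call(rbind, truth_list),
                   amounts = amounts, days = days),
      config = config)
  })
}

# region codes used inside one specificity well group
spec_regions <- function(config) {
  r <- config$bead_regions
  if (length(r) < 4) stop("need at least 4 bead regions (PM, 1MM, 2MM, spike)")
  c(pm = r[1], mm1 = r[2], mm2 = r[3], spike = r[4])
}

#' Simulate a mismatch-specificity experiment
#'
#' For each miRNA with configured mismatch efficiencies, replicate wells
#' carry four bead regions: the perfect-match probe, its one- and
#' two-mismatch variants, and the spike control.  Mismatch signal is the
#' perfect-match signal scaled by the configured efficiency.  In
#' `complex_background` mode the wells represent labeled total-RNA samples
#' from a cell-line panel: target signal follows each sample's latent
#' abundance (proportional response) and a per-sample lognormal labeling
#' factor scales miRNA and spike signal equally.
#'
#' @param config An [assay_config()].
#' @param target_amount Target amount per well (fmol), simple mode.
#' @param n_replicates Replicate wells per miRNA (and per sample in complex
#'   mode).
#' @param complex_background Simulate complex RNA populations from `panel`
#'   instead of a pure synthetic target.
#' @param panel A [cell_line_panel()]; required when `complex_background`.
#' @return A `simulated_plate`; `probe_map` maps (well, region) to probe id.
#' @export
simulate_specificity <- function(config = assay_config(),
                                 target_amount = 18.75,
                                 n_replicates = 3L,
                                 complex_background = FALSE,
                                 panel = NULL) {
  stopifnot(inherits(config, "assay_config"), target_amount > 0,
            n_replicates >= 1)
  mirnas <- names(config$eff_2mm)
  for (m in mirnas) {
    if (is.na(config$eff_1mm[m]) || is.na(config$eff_2mm[m])) {
      stop("probe ", m, " lacks a configured mismatch efficiency")
    }
  }
  regions <- spec_regions(config)
  if (complex_background && is.null(panel)) panel <- cell_line_panel()

  with_seed(config$seed, {
    groups <- if (complex_background) {
      expand.grid(sample_id = panel$samples$sample, mirna = mirnas,
                  stringsAsFactors = FALSE)
    } else {
      data.frame(sample_id = paste0(mirnas, "_target"), mirna = mirnas,
                 stringsAsFactors = FALSE)
    }
    lab_factor <- if (complex_background) {
      f <- stats::rlnorm(nrow(panel$samples), 0, config$labeling_eff_sd)
      stats::setNames(f, panel$samples$sample)
    } else NULL
    g_lin <- config$mfi_at_knot / config$knot_fmol

    med_list <- list(); lay_list <- list(); map_list <- list()
    well_offset <- 0
    for (i in seq_len(nrow(groups))) {
      m <- groups$mirna[i]
      sid <- groups$sample_id[i]
      wells <- plate_wells(n_replicates, well_offset)
      well_offset <- well_offset + n_replicates
      if (complex_background) {
        f <- lab_factor[[sid]]
        base <- g_lin * panel$latent[sid, m] * f
        spike_sig <- g_lin * config$spike_fmol * f
      } else {
        base <- signal_model(target_amount, config)
        spike_sig <- signal_model(config$spike_fmol, config)
      }
      sig <- c(base, config$eff_1mm[[m]] * base, config$eff_2mm[[m]] * base,
               spike_sig)
      probe_ids <- c(m, paste0(m, "-1MM"), paste0(m, "-2MM"), "Spike-18")
      med_list[[i]] <- data.frame(
        well = rep(wells, each = 4),
        region = rep(unname(regions), times = n_replicates),
        median_mfi = rep(sig, times = n_replicates),
        stringsAsFactors = FALSE)
      lay_list[[i]] <- data.frame(
        well = wells, sample_id = sid, role = "test",
        replicate_index = seq_len(n_replicates), stringsAsFactors = FALSE)
      map_list[[i]] <- data.frame(
        well = rep(wells, each = 4),
        region = rep(unname(regions), times = n_replicates),
        probe_id = rep(probe_ids, times = n_replicates),
        stringsAsFactors = FALSE)
    }
    bg_wells <- plate_wells(config$n_background, well_offset)
    med_bg <- data.frame(
      well = rep(bg_wells, each = 4),
      region = rep(unname(regions), times = config$n_background),
      median_mfi = 0, stringsAsFactors = FALSE)
    medians <- rbind(do.call(rbind, med_list), med_bg)
    medians$bg_level <- draw_background(nrow(medians), config)
    signal_only <- medians$median_mfi
    medians$median_mfi <- medians$median_mfi + medians$bg_level
    layout <- rbind(
      do.call(rbind, lay_list),
      data.frame(well = bg_wells, sample_id = "background",
                 role = "background",
                 replicate_index = seq_len(config$n_background),
                 stringsAsFactors = FALSE))
    events <- draw_events(medians, config)
    truth <- list(medians = cbind(medians, signal = signal_only),
                  labeling_factor = lab_factor,
                  regions = regions)
    new_simulated_plate(events, layout, do.call(rbind, map_list),
                        truth, config)
  })
}

#' Cell-line panel with a two-group expression pattern
#'
#' Seven cell lines (five fusion-negative, two fusion-positive) plus a
#' pooled reference mixed in equal amounts, so the pool's latent abundance
#' is the arithmetic mean of the seven samples for every miRNA.  The default
#' pattern has miR-23a and miR-27a elevated in the fusion-positive lines and
#' miR-199a elevated in the fusion-negative lines.
#'
#' @param latent Numeric matrix of latent abundances (relative units,
#'   fmol-equivalents in the assay's linear range), rows = 7 sample names,
#'   columns = miRNA names.  The POOL row is always recomputed as the mean.
#' @param groups Named character vector mapping samples to
#'   `"fusion_pos"`/`"fusion_neg"`.
#' @return A `cell_line_panel` list with elements `samples` (data.frame of
#'   sample, group; POOL has group `"reference"`) and `latent` (matrix
#'   including the POOL row).
#' @export
cell_line_panel <- function(latent = NULL, groups = NULL) {
  if (is.null(latent)) {
    latent <- rbind(
      "RD"      = c(0.8, 0.9, 2.8),
      "CCA"     = c(1.0, 1.2, 3.4),
      "SMS-CTR" = c(0.9, 0.7, 2.2),
      "RH36"    = c(1.1, 1.0, 3.0),
      "RH18"    = c(1.2, 1.1, 2.6),
      "RH4"     = c(3.5, 4.8, 0.7),
      "RH30"    = c(4.2, 3.9, 0.9))
    colnames(latent) <- c("miR-23a", "miR-27a", "miR-199a")
  }
  latent <- as.matrix(latent)
  stopifnot(all(latent > 0), nrow(latent) >= 2)
  if (is.null(groups)) {
    groups <- stats::setNames(
      ifelse(rownames(latent) %in% c("RH4", "RH30"),
             "fusion_pos", "fusion_neg"),
      rownames(latent))
  }
  stopifnot(setequal(names(groups), rownames(latent)))
  pool <- colMeans(latent)
  latent <- rbind(latent, POOL = pool)
  samples <- data.frame(
    sample = rownames(latent),
    group = c(unname(groups[rownames(latent)[-nrow(latent)]]), "reference"),
    stringsAsFactors = FALSE)
  structure(list(samples = samples, latent = latent),
            class = "cell_line_panel")
}

#' Simulate an expression experiment over a cell-line panel
#'
#' Each sample (including the pooled reference) is assayed in `n_wells`
#' wells; each well carries four bead regions: the three miRNA
#' perfect-match probes and the spike control.  Within the assay's linear
#' range the response is proportional: miRNA signal is
#' `gain * latent * labeling_factor` with `gain = mfi_at_knot / knot_fmol`;
#' the spike signal is `gain * spike_fmol * labeling_factor`, so spike
#' normalization cancels the per-sample labeling factor exactly.
#'
#' @param config An [assay_config()].
#' @param panel A [cell_line_panel()].
#' @param n_wells Replicate wells per sample.
#' @return A `simulated_plate`; the POOL sample has role `"reference"`.
#' @export
simulate_expression <- function(config = assay_config(),
                                panel = cell_line_panel(),
                                n_wells = 3L) {
  stopifnot(inherits(config, "assay_config"),
            inherits(panel, "cell_line_panel"), n_wells >= 1)
  mirnas <- colnames(panel$latent)
  if (length(mirnas) + 1 > length(config$bead_regions)) {
    stop("more probes than available bead regions")
  }
  regions <- config$bead_regions[seq_len(length(mirnas) + 1)]
  probe_ids <- c(mirnas, "Spike-18")
  g_lin <- config$mfi_at_knot / config$knot_fmol

  with_seed(config$seed, {
    samples <- panel$samples$sample
    f <- stats::setNames(
      stats::rlnorm(length(samples), 0, config$labeling_eff_sd), samples)
    med_list <- list(); lay_list <- list()
    well_offset <- 0
    for (s in samples) {
      wells <- plate_wells(n_wells, well_offset)
      well_offset <- well_offset + n_wells
      sig <- c(g_lin * panel$latent[s, mirnas] * f[[s]],
               g_lin * config$spike_fmol * f[[s]])
      med_list[[s]] <- data.frame(
        well = rep(wells, each = length(regions)),
        region = rep(regions, times = n_wells),
        median_mfi = rep(unname(sig), times = n_wells),
        stringsAsFactors = FALSE)
      lay_list[[s]] <- data.frame(
        well = wells, sample_id = s,
        role = if (s == "POOL") "reference" else "test",
        replicate_index = seq_len(n_wells), stringsAsFactors = FALSE)
    }
    bg_wells <- plate_wells(config$n_background, well_offset)
    med_bg <- data.frame(
      well = rep(bg_wells, each = length(regions)),
      region = rep(regions, times = config$n_background),
      median_mfi = 0, stringsAsFactors = FALSE)
    medians <- rbind(do.call(rbind, med_list), med_bg)
    medians$bg_level <- draw_background(nrow(medians), config)
    signal_only <- medians$median_mfi
    medians$median_mfi <- medians$median_mfi + medians$bg_level
    layout <- rbind(
      do.call(rbind, lay_list),
      data.frame(well = bg_wells, sample_id = "background",
                 role = "background",
                 replicate_index = seq_len(config$n_background),
                 stringsAsFactors = FALSE))
    events <- draw_events(medians, config)
    probe_map <- data.frame(region = regions, probe_id = probe_ids,
                            stringsAsFactors = FALSE)
    truth <- list(latent = panel$latent, labeling_factor = f,
                  medians = cbind(medians, signal = signal_only),
                  spike_fmol = config$spike_fmol, gain = g_lin)
    new_simulated_plate(events, layout, probe_map, truth, config)
  })
}

#' Simulate matched microarray and qPCR readouts from shared abundances
#'
#' Drives a two-channel microarray (log2 sample/POOL ratios with Gaussian
#' noise) and a TaqMan-style qPCR (Ct = intercept - log2(abundance) plus
#' replicate noise, with a constant-abundance RNU6B endogenous control) from
#' the same latent abundances as the bead plates, so cross-platform rank
#' concordance can be studied under known truth.
#'
#' @param panel A [cell_line_panel()].
#' @param config An [assay_config()]; `array_noise_sd`, `ct_noise_sd`,
#'   `ct_intercept`, `u6_abundance` and `seed` are used.
#' @param n_ct_replicates qPCR replicates per (sample, assay).
#' @return List with `microarray` (sample, mirna, log2_ratio; test samples
#'   only) and `ct` (sample, assay, replicate, ct; includes RNU6B and POOL).
#' @export
simulate_matched_platforms <- function(panel = cell_line_panel(),
                                       config = assay_config(),
                                       n_ct_replicates = 3L) {
  stopifnot(inherits(panel, "cell_line_panel"),
            inherits(config, "assay_config"))
  mirnas <- colnames(panel$latent)
  test <- panel$samples$sample[panel$samples$group != "reference"]
  with_seed(config$seed, {
    arr <- expand.grid(sample = test, mirna = mirnas,
                       stringsAsFactors = FALSE)
    arr$log2_ratio <- log2(panel$latent[cbind(arr$sample, arr$mirna)] /
                             panel$latent["POOL", arr$mirna]) +
      stats::rnorm(nrow(arr), 0, config$array_noise_sd)

    assays <- c(mirnas, "RNU6B")
    ct <- expand.grid(sample = rownames(panel$latent), assay = assays,
                      replicate = seq_len(n_ct_replicates),
                      stringsAsFactors = FALSE)
    abundance <- ifelse(ct$assay == "RNU6B", config$u6_abundance,
                        panel$latent[cbind(ct$sample,
                                           ifelse(ct$assay == "RNU6B",
                                                  mirnas[1], ct$assay))])
    ct$ct <- config$ct_intercept - log2(abundance) +
      stats::rnorm(nrow(ct), 0, config$ct_noise_sd)
    list(microarray = arr[order(arr$mirna, arr$sample), ],
         ct = ct[order(ct$assay, ct$sample, ct$replicate), ])
  })
}
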