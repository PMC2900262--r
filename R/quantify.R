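# The core MFI processing pipeline:
#   per-event fluorescence -> per-(well, region) median (MFI)
#   -> bead-specific background subtraction + QC removal
#   -> per-well spike normalization
#   -> replicate means, log2 ratios vs the pooled reference,
#      quadratic (relative-SD) error propagation
# plus mismatch-specificity scoring against the perfect-match probe.

#' Median fluorescence intensity per (well, bead region)
#'
#' The assay's primary measurement: the median of per-event fluorescence
#' over all beads of one region in one well.  Groups with fewer than
#' `min_events` events are flagged `low_count` and excluded by the default
#' downstream pipeline (the at-least-100-beads rule).
#'
#' @param events Bead-event data.frame (well, region, event, fluorescence).
#' @param min_events Minimum events per (well, region).
#' @return Data.frame (well, region, mfi, n_events, low_count).
#' @export
compute_mfi <- function(events, min_events = 100L) {
  if (nrow(events) == 0) stop("empty event table")
  key <- interaction(events$well, events$region, drop = TRUE)
  mfi <- tapply(events$fluorescence, key, stats::median)
  n <- tapply(events$fluorescence, key, length)
  first <- !duplicated(key)
  out <- data.frame(well = events$well[first],
                    region = events$region[first],
                    stringsAsFactors = FALSE)
  k <- as.character(key[first])
  out$mfi <- as.numeric(mfi[k])
  out$n_events <- as.integer(n[k])
  out$low_count <- out$n_events < min_events
  out[order(out$well, out$region), , drop = FALSE]
}

#' Subtract bead-specific background and remove sub-background readings
#'
#' The background model is, per bead region, the mean (and SD) of MFIs in
#' the no-target wells.  Test/reference readings get `net = mfi - bg_mean`;
#' readings below their region's mean background are marked
#' `below_background` (kept in the table with a QC reason, excluded from
#' quantification), as are low-count readings.
#'
#' @param mfis Output of [compute_mfi()].
#' @param layout Plate layout (well, sample_id, role, replicate_index).
#' @return List with `corrected` (non-background wells: well, region, mfi,
#'   n_events, net, qc) and `background` (region, bg_mean, bg_sd, n_wells,
#'   plus the raw background-well MFIs as attribute `"mfis"`).
#' @export
background_correct <- function(mfis, layout) {
  m <- merge(mfis, layout[, c("well", "role")], by = "well")
  bg <- m[m$role == "background" & !m$low_count, , drop = FALSE]
  test <- m[m$role != "background", , drop = FALSE]
  if (nrow(bg) == 0) stop("no background wells available")
  regions <- sort(unique(test$region))
  missing <- setdiff(regions, unique(bg$region))
  if (length(missing) > 0) {
    stop("no background wells for region(s) ",
         paste(missing, collapse = ", "))
  }
  bg_stats <- do.call(rbind, lapply(split(bg, bg$region), function(d) {
    data.frame(region = d$region[1], bg_mean = mean(d$mfi),
               bg_sd = stats::sd(d$mfi), n_wells = nrow(d))
  }))
  bg_stats$bg_sd[is.na(bg_stats$bg_sd)] <- 0
  rownames(bg_stats) <- NULL
  attr(bg_stats, "mfis") <- bg$mfi

  idx <- match(test$region, bg_stats$region)
  test$net <- test$mfi - bg_stats$bg_mean[idx]
  test$qc <- ifelse(test$low_count, "low_count",
                    ifelse(test$mfi < bg_stats$bg_mean[idx],
                           "below_background", "ok"))
  corrected <- test[, c("well", "region", "mfi", "n_events", "net", "qc")]
  rownames(corrected) <- NULL
  list(corrected = corrected, background = bg_stats)
}

#' Per-well spike normalization
#'
#' Scales every miRNA reading in a well by that well's spike-control net
#' signal: `norm = net_miRNA / net_spike`.  The ratio is taken per well and
#' averaged later (not ratio of averages).  Wells whose spike reading was
#' removed by QC or is non-positive are excluded with a warning.
#'
#' @param corrected `corrected` table from [background_correct()].
#' @param spike_region Bead-region code of the spike control.
#' @return Data.frame (well, region, net, norm, spike_net) for miRNA
#'   regions in surviving wells, QC-passing rows only.
#' @export
spike_normalize <- function(corrected, spike_region = 57L) {
  spikes <- corrected[corrected$region == spike_region &
                        corrected$qc == "ok", , drop = FALSE]
  targets <- corrected[corrected$region != spike_region, , drop = FALSE]
  wells <- unique(targets$well)
  bad <- setdiff(wells, spikes$well[spikes$net > 0])
  if (length(bad) > 0) {
    warning("excluding well(s) with missing/non-positive spike: ",
            paste(bad, collapse = ", "))
  }
  keep <- targets$qc == "ok" & targets$well %in% setdiff(wells, bad)
  out <- targets[keep, c("well", "region", "net"), drop = FALSE]
  if (nrow(out) == 0) stop("all wells excluded by spike QC")
  out$spike_net <- spikes$net[match(out$well, spikes$well)]
  out$norm <- out$net / out$spike_net
  rownames(out) <- NULL
  out[, c("well", "region", "net", "norm", "spike_net")]
}

# attach probe ids from a probe map with either (region, probe_id) or
# (well, region, probe_id) columns
annotate_probes <- function(tbl, probe_map) {
  by <- intersect(c("well", "region"), names(probe_map))
  merge(tbl, probe_map, by = by)
}

#' Replicate summary and log2 ratios versus a reference sample
#'
#' Per (sample, probe): mean and SD of the spike-normalized values over
#' wells; ratio of sample mean to reference mean; relative SDs combined in
#' quadrature (`relSD_R = sqrt(relSD_sample^2 + relSD_ref^2)` — quadratic
#' error propagation for a ratio); `log2_sd = relSD_R / ln 2` by the delta
#' method; 95% CI from Student t on the normalized scale.  Samples with a
#' single surviving well are reported with missing SD/CI.
#'
#' @param normalized Output of [spike_normalize()].
#' @param layout Plate layout.
#' @param reference_sample Sample id of the pooled reference (needs >= 2
#'   surviving wells).
#' @param probe_map Data.frame mapping region (optionally per well) to
#'   probe_id; when `NULL`, probes are reported as `region_<code>`.
#' @return Data.frame (sample, probe_id, n_wells, norm_mfi_mean,
#'   norm_mfi_sd, ci95_low, ci95_high, log2_ratio, log2_sd).
#' @export
summarize_expression <- function(normalized, layout,
                                 reference_sample = "POOL",
                                 probe_map = NULL) {
  tbl <- merge(normalized, layout[, c("well", "sample_id")], by = "well")
  if (is.null(probe_map)) {
    tbl$probe_id <- paste0("region_", tbl$region)
  } else {
    tbl <- annotate_probes(tbl, probe_map)
  }
  groups <- split(tbl, list(tbl$sample_id, tbl$probe_id), drop = TRUE)
  summ <- do.call(rbind, lapply(groups, function(d) {
    n <- nrow(d)
    m <- mean(d$norm)
    s <- if (n >= 2) stats::sd(d$norm) else NA_real_
    half <- if (n >= 2) stats::qt(0.975, n - 1) * s / sqrt(n) else NA_real_
    data.frame(sample = d$sample_id[1], probe_id = d$probe_id[1],
               n_wells = n, norm_mfi_mean = m, norm_mfi_sd = s,
               ci95_low = m - half, ci95_high = m + half,
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  ref <- summ[summ$sample == reference_sample, , drop = FALSE]
  if (nrow(ref) == 0) stop("reference sample '", reference_sample,
                           "' not present")
  if (any(ref$n_wells < 2)) {
    stop("reference sample needs >= 2 surviving wells for every probe")
  }
  idx <- match(summ$probe_id, ref$probe_id)
  ref_mean <- ref$norm_mfi_mean[idx]
  ref_relsd <- ref$norm_mfi_sd[idx] / ref_mean
  relsd <- summ$norm_mfi_sd / summ$norm_mfi_mean
  summ$log2_ratio <- log2(summ$norm_mfi_mean / ref_mean)
  summ$log2_sd <- sqrt(relsd^2 + ref_relsd^2) / log(2)
  summ[order(summ$probe_id, summ$sample), , drop = FALSE]
}

#' Mismatch specificity relative to the perfect-match probe
#'
#' Expresses each mismatch probe's spike-normalized signal as a percentage
#' of the perfect-match probe's signal over the same wells (perfect match =
#' 100%), with the percent drop and a one-sided Welch two-sample t test of
#' the decrease.
#'
#' @param normalized Output of [spike_normalize()], annotated with
#'   `probe_id` (or supply `probe_map`).
#' @param pm_probe Perfect-match probe id.
#' @param mm_probes Character vector of mismatch probe ids.
#' @param probe_map Optional (well,) region -> probe_id map used to
#'   annotate `normalized`.
#' @return Data.frame (probe_id, pct_of_pm, drop_pct, p_value, n).
#' @export
specificity_score <- function(normalized, pm_probe, mm_probes,
                              probe_map = NULL) {
  tbl <- if (!is.null(probe_map)) annotate_probes(normalized, probe_map)
    else normalized
  if (is.null(tbl$probe_id)) {
    stop("normalized table lacks probe_id; supply probe_map")
  }
  pm <- tbl[tbl$probe_id == pm_probe, , drop = FALSE]
  if (nrow(pm) == 0 || mean(pm$norm) <= 0) {
    stop("perfect-match probe '", pm_probe,
         "' missing or non-positive mean")
  }
  out <- do.call(rbind, lapply(mm_probes, function(p) {
    mm <- tbl[tbl$probe_id == p & tbl$well %in% pm$well, , drop = FALSE]
    if (nrow(mm) == 0) stop("mismatch probe '", p, "' not measured in the ",
                            "perfect-match wells")
    pmw <- pm[pm$well %in% mm$well, , drop = FALSE]
    pct <- 100 * mean(mm$norm) / mean(pmw$norm)
    pval <- if (nrow(mm) >= 2 && nrow(pmw) >= 2 &&
                (stats::sd(mm$norm) > 0 || stats::sd(pmw$norm) > 0)) {
      stats::t.test(mm$norm, pmw$norm, alternative = "less")$p.value
    } else NA_real_
    data.frame(probe_id = p, pct_of_pm = pct, drop_pct = 100 - pct,
               p_value = pval, n = nrow(mm), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Run the full specificity pipeline on a simulated plate
#'
#' Convenience wrapper: events -> MFI -> background correction -> spike
#' normalization -> percent-of-perfect-match scoring for every miRNA with
#' mismatch variants on the plate.
#'
#' @param plate A `simulated_plate` from [simulate_specificity()].
#' @param min_events Minimum events per (well, region).
#' @return Data.frame (mirna, probe_id, pct_of_pm, drop_pct, p_value, n).
#' @export
specificity_pipeline <- function(plate, min_events = 100L) {
  stopifnot(inherits(plate, "simulated_plate"))
  mfis <- compute_mfi(plate$events, min_events)
  bc <- background_correct(mfis, plate$layout)
  spike_region <- plate$probe_map$region[
    plate$probe_map$probe_id == "Spike-18"][1]
  norm <- spike_normalize(bc$corrected, spike_region)
  ann <- annotate_probes(norm, plate$probe_map)
  pm_probes <- setdiff(unique(sub("-[12]MM$", "", ann$probe_id)), "Spike-18")
  out <- do.call(rbind, lapply(pm_probes, function(pm) {
    mm <- unique(ann$probe_id[grepl(paste0("^", pm, "-[12]MM$"),
                                    ann$probe_id)])
    res <- specificity_score(ann, pm, sort(mm))
    cbind(mirna = pm, res, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
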