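# Two-segment log-log calibration fitting, linear dynamic range / limit of
# detection, and bead-stability assessment.

#' Build a calibration curve from a simulated (or loaded) plate
#'
#' Runs the measurement pipeline per day: per-(well, region) medians,
#' bead-specific background subtraction, then collects the
#' background-corrected MFI per (amount, replicate, day) for the titrated
#' region, together with the raw background-well MFIs needed by the
#' limit-of-detection rule.
#'
#' @param plate A `simulated_plate` from [simulate_calibration()] (layout
#'   must carry `amount_fmol` and `day` columns).
#' @param min_events Minimum events per (well, region).
#' @return List with `curve` (amount, mfi, day, replicate, qc; corrected
#'   MFI; `qc` is `"ok"` or `"below_background"` — below-background
#'   readings are removed before fitting but still count against the
#'   limit-of-detection rule) and `background_mfis` (raw MFIs of background
#'   wells, all days).
#' @export
build_calibration_curve <- function(plate, min_events = 100L) {
  stopifnot(inherits(plate, "simulated_plate"))
  lay <- plate$layout
  if (is.null(lay$day)) lay$day <- 0
  ev <- plate$events
  if (is.null(ev$day)) ev$day <- 0
  curves <- list()
  bg_mfis <- numeric(0)
  for (d in unique(lay$day)) {
    lday <- lay[lay$day == d, , drop = FALSE]
    eday <- ev[ev$day == d, , drop = FALSE]
    mfis <- compute_mfi(eday, min_events)
    bc <- background_correct(mfis, lday)
    bg_mfis <- c(bg_mfis, attr(bc$background, "mfis"))
    keep <- bc$corrected[bc$corrected$qc != "low_count", , drop = FALSE]
    idx <- match(keep$well, lday$well)
    curves[[as.character(d)]] <- data.frame(
      amount = lday$amount_fmol[idx],
      mfi = keep$net,
      day = d,
      replicate = lday$replicate_index[idx],
      qc = keep$qc,
      stringsAsFactors = FALSE)
  }
  list(curve = do.call(rbind, curves), background_mfis = bg_mfis)
}

#' Fit a two-segment line in log10-log10 space
#'
#' Replicate MFIs are averaged per amount (arithmetic mean, pooling days),
#' transformed to (log10 amount, log10 MFI), and for every candidate knot
#' among the observed amounts that leaves at least 3 points per side (the
#' knot point belongs to both sides) an ordinary least-squares line is
#' fitted per side.  The knot minimizing the total SSE wins; SSE ties break
#' toward the larger knot (the conservative, wider-linear-range choice).
#' No continuity constraint links the two segments.  R-squared is computed
#' on the combined residuals of both segments against the global mean.
#'
#' Readings flagged `below_background` (a `qc` column, when present) are
#' removed before averaging — the standard below-background QC rule; an
#' amount whose replicates were all removed drops out of the fit.
#'
#' @param curve Data.frame (amount, mfi, ...) with background-corrected MFI;
#'   needs >= 6 distinct amounts, and positive per-amount mean MFI.
#' @return A `segmented_fit` list: knot, slope_low, slope_high,
#'   intercept_low, intercept_high, r2, sse, n_low, n_high, and the
#'   per-amount means used (`points`).
#' @export
fit_two_segment <- function(curve) {
  stopifnot(all(c("amount", "mfi") %in% names(curve)))
  if (any(curve$amount <= 0)) stop("amounts must be positive")
  if (!is.null(curve$qc)) curve <- curve[curve$qc == "ok", , drop = FALSE]
  means <- tapply(curve$mfi, curve$amount, mean)
  amounts <- as.numeric(names(means))
  ord <- order(amounts)
  amounts <- amounts[ord]
  means <- as.numeric(means)[ord]
  if (length(amounts) < 6) {
    stop("need >= 6 distinct amounts to fit two segments (got ",
         length(amounts), ")")
  }
  if (any(means <= 0)) {
    stop("non-positive mean MFI after background correction at amount(s) ",
         paste(signif(amounts[means <= 0], 4), collapse = ", "))
  }
  x <- log10(amounts)
  y <- log10(means)
  n <- length(x)

  ols <- function(xi, yi) {
    xb <- mean(xi); yb <- mean(yi)
    b <- sum((xi - xb) * (yi - yb)) / sum((xi - xb)^2)
    a <- yb - b * xb
    res <- yi - (a + b * xi)
    list(slope = b, intercept = a, sse = sum(res^2))
  }

  best <- NULL
  for (k in 3:(n - 2)) {  # knot index: >= 3 points on each side, shared
    low <- ols(x[1:k], y[1:k])
    high <- ols(x[k:n], y[k:n])
    sse <- low$sse + high$sse
    # strict improvement required, so equal-SSE ties keep the larger knot
    # (larger k = larger amount since x is ascending)
    if (is.null(best) || sse < best$sse - 1e-12 ||
        (abs(sse - best$sse) <= 1e-12 && k > best$k)) {
      best <- list(k = k, sse = sse, low = low, high = high)
    }
  }
  sst <- sum((y - mean(y))^2)
  structure(list(
    knot = amounts[best$k],
    slope_low = best$low$slope, slope_high = best$high$slope,
    intercept_low = best$low$intercept,
    intercept_high = best$high$intercept,
    r2 = 1 - best$sse / sst, sse = best$sse,
    n_low = best$k, n_high = n - best$k + 1,
    points = data.frame(amount = amounts, mean_mfi = means)),
    class = "segmented_fit")
}

#' @export
print.segmented_fit <- function(x, ...) {
  cat(sprintf(
    "Two-segment log-log fit: slopes %.4f / %.4f, knot %.6g fmol, R2 %.4f\n",
    x$slope_low, x$slope_high, x$knot, x$r2))
  invisible(x)
}

#' Linear dynamic range and limit of detection
#'
#' The upper bound of the linear range is the fitted knot (saturation
#' onset).  The lower bound (LOD) is the smallest measured amount whose raw
#' MFI exceeds mean + 3 SD of the background-well MFIs in every replicate
#' well; since the curve stores background-corrected MFI, the rule is
#' applied as `net > 3 * SD(background)` (the subtracted mean cancels).
#'
#' @param curve Calibration curve (amount, mfi, replicate) with corrected
#'   MFI.
#' @param fit A [fit_two_segment()] result.
#' @param background_mfis Raw MFIs of the background wells.
#' @return List (`lower_fmol`, `upper_fmol`), both members of the measured
#'   series.
#' @export
detect_linear_range <- function(curve, fit, background_mfis) {
  stopifnot(inherits(fit, "segmented_fit"), length(background_mfis) >= 1)
  threshold <- 3 * stats::sd(background_mfis)
  if (is.na(threshold)) threshold <- 0
  passes <- tapply(curve$mfi, curve$amount, function(v) all(v > threshold))
  amounts <- as.numeric(names(passes))
  detected <- amounts[passes]
  if (length(detected) == 0) {
    stop("below detection: no amount exceeds the background 3-sigma rule")
  }
  lower <- min(detected)
  upper <- fit$knot
  if (lower >= upper) {
    stop("degenerate linear range: LOD (", signif(lower, 4),
         ") not below the saturation knot (", signif(upper, 4), ")")
  }
  list(lower_fmol = lower, upper_fmol = upper)
}

#' Bead stability across days post-conjugation
#'
#' Retention for each day is the geometric mean over amounts of
#' MFI(day)/MFI(reference day), using per-amount replicate means; a day is
#' flagged stable when retention >= `stable_threshold`.
#'
#' @param curves_by_day Named list (names = days) of calibration curves
#'   (amount, mfi, ...), all on the same amount grid.
#' @param reference_day Day used as the retention reference.
#' @param stable_threshold Retention fraction counted as stable.
#' @return Data.frame (day, retention, stable), ordered by day.
#' @export
assess_stability <- function(curves_by_day, reference_day = 0,
                             stable_threshold = 0.90) {
  days <- as.numeric(names(curves_by_day))
  if (!reference_day %in% days) {
    stop("reference day ", reference_day, " not present")
  }
  per_amount_means <- lapply(curves_by_day, function(cv) {
    m <- tapply(cv$mfi, cv$amount, mean)
    m[order(as.numeric(names(m)))]
  })
  grid <- names(per_amount_means[[1]])
  for (m in per_amount_means) {
    if (!identical(names(m), grid)) {
      stop("amount grids differ across days")
    }
  }
  # amounts must be positive on every day for the geometric mean of ratios
  pos <- Reduce(`&`, lapply(per_amount_means, function(m) m > 0))
  if (!any(pos)) stop("no amount has positive mean MFI on every day")
  ref <- per_amount_means[[as.character(reference_day)]][pos]
  retention <- vapply(per_amount_means, function(m) {
    exp(mean(log(m[pos] / ref)))
  }, numeric(1))
  out <- data.frame(day = days, retention = as.numeric(retention),
                    stable = as.numeric(retention) >= stable_threshold)
  out[order(out$day), , drop = FALSE]
}

#' Split a multi-day calibration plate into per-day curves
#'
#' @param plate A `simulated_plate` from [simulate_calibration()] with
#'   multiple `days`.
#' @param min_events Minimum events per (well, region).
#' @return Named list (day -> curve data.frame) for [assess_stability()].
#' @export
calibration_curves_by_day <- function(plate, min_events = 100L) {
  cc <- build_calibration_curve(plate, min_events)
  split(cc$curve, cc$curve$day)
}
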