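# TaqMan-style 2^-ddCt relative quantification and cross-platform Spearman
# rank concordance.

#' Relative quantification by the 2^-ddCt method
#'
#' Per sample, dCt is the mean Ct of the target assay minus the mean Ct of
#' the endogenous control; ddCt subtracts the calibrator sample's dCt; the
#' relative quantity is `RQ = 2^-ddCt` (the calibrator's RQ is 1 by
#' construction).  Samples lacking the control assay are reported with
#' missing values rather than dropped.
#'
#' @param ct_table Data.frame (sample, assay, replicate, ct), e.g. from
#'   [read_ct_table()] or [simulate_matched_platforms()].
#' @param control_assay Endogenous-control assay id.
#' @param calibrator_sample Calibrator sample id (must carry the control).
#' @return Data.frame (sample, assay, delta_ct, delta_delta_ct, rq) for
#'   every non-control assay.
#' @export
relative_quantification <- function(ct_table, control_assay = "RNU6B",
                                    calibrator_sample = "POOL") {
  stopifnot(all(c("sample", "assay", "ct") %in% names(ct_table)))
  mean_ct <- stats::aggregate(ct ~ sample + assay, data = ct_table,
                              FUN = mean)
  ctrl <- mean_ct[mean_ct$assay == control_assay, , drop = FALSE]
  if (nrow(ctrl) == 0) stop("control assay '", control_assay,
                            "' not present")
  targets <- mean_ct[mean_ct$assay != control_assay, , drop = FALSE]
  targets$delta_ct <- targets$ct -
    ctrl$ct[match(targets$sample, ctrl$sample)]
  cal <- targets[targets$sample == calibrator_sample, , drop = FALSE]
  if (nrow(cal) == 0 || any(is.na(cal$delta_ct))) {
    stop("calibrator sample '", calibrator_sample,
         "' missing or lacks the control assay")
  }
  targets$delta_delta_ct <- targets$delta_ct -
    cal$delta_ct[match(targets$assay, cal$assay)]
  targets$rq <- 2^(-targets$delta_delta_ct)
  out <- targets[, c("sample", "assay", "delta_ct", "delta_delta_ct", "rq")]
  out <- out[order(out$assay, out$sample), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-platform Spearman rank concordance
#'
#' For every miRNA and every pair of platforms, the Spearman rank
#' correlation over the shared samples (average ranks for ties).  Pairs
#' sharing fewer than `min_samples` samples are skipped with a warning.
#' Rank correlation is invariant to monotone rescaling, so each platform
#' may be supplied on its own scale (log2 ratios, -ddCt, RQ, ...).
#'
#' @param profiles Named list of data.frames, one per platform, each with
#'   columns (sample, mirna, value).
#' @param min_samples Minimum shared samples per pair.
#' @return Data.frame (mirna, platform_a, platform_b, rho, n_samples).
#' @export
spearman_concordance <- function(profiles, min_samples = 4L) {
  stopifnot(is.list(profiles), length(profiles) >= 2,
            !is.null(names(profiles)))
  for (p in names(profiles)) {
    stopifnot(all(c("sample", "mirna", "value") %in% names(profiles[[p]])))
  }
  platforms <- names(profiles)
  mirnas <- sort(unique(unlist(lapply(profiles, function(d) d$mirna))))
  pairs <- utils::combn(platforms, 2, simplify = FALSE)
  rows <- list()
  for (m in mirnas) {
    for (pr in pairs) {
      a <- profiles[[pr[1]]]; a <- a[a$mirna == m, , drop = FALSE]
      b <- profiles[[pr[2]]]; b <- b[b$mirna == m, , drop = FALSE]
      shared <- intersect(a$sample, b$sample)
      if (length(shared) < min_samples) {
        warning("skipping ", m, " ", pr[1], " vs ", pr[2], ": only ",
                length(shared), " shared sample(s)")
        next
      }
      rho <- stats::cor(a$value[match(shared, a$sample)],
                        b$value[match(shared, b$sample)],
                        method = "spearman")
      rows[[length(rows) + 1]] <- data.frame(
        mirna = m, platform_a = pr[1], platform_b = pr[2],
        rho = rho, n_samples = length(shared), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) stop("no platform pair had enough shared samples")
  do.call(rbind, rows)
}
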