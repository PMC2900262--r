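mfi_events <- function(well, region, values) {
  data.frame(well = well, region = region, event = seq_along(values),
             fluorescence = values, stringsAsFactors = FALSE)
}

test_that("compute_mfi takes per-(well, region) medians and flags counts", {
  ev <- mfi_events("A1", 1L, rep(7.5, 100))
  res <- compute_mfi(ev)
  expect_equal(res$mfi, 7.5)
  expect_false(res$low_count)

  res <- compute_mfi(mfi_events("A1", 1L, c(1, 2, 3, 4, 5)), min_events = 5)
  expect_equal(res$mfi, 3)
  expect_false(res$low_count)

  res <- compute_mfi(mfi_events("A1", 1L, rnorm(99, 100)))
  expect_true(res$low_count)

  # invariant to event order
  ev <- mfi_events("A1", 1L, c(5, 1, 9, 3, 7))
  shuffled <- ev[c(3, 1, 5, 2, 4), ]
  expect_equal(compute_mfi(ev, 5)$mfi, compute_mfi(shuffled, 5)$mfi)

  expect_error(compute_mfi(ev[0, ]), "empty event table")
})

test_that("background correction follows the subtract-and-remove rule", {
  mfis <- data.frame(
    well = c("A1", "A2", "B1", "B2", "B3"),
    region = 1L,
    mfi = c(500, 25, 30, 34, 32),
    n_events = 100L, low_count = FALSE, stringsAsFactors = FALSE)
  layout <- data.frame(
    well = c("A1", "A2", "B1", "B2", "B3"),
    sample_id = c("s1", "s2", rep("background", 3)),
    role = c("test", "test", rep("background", 3)),
    replicate_index = c(1L, 1L, 1L, 2L, 3L), stringsAsFactors = FALSE)
  bc <- background_correct(mfis, layout)
  expect_equal(bc$background$bg_mean, 32)
  expect_equal(bc$corrected$net[bc$corrected$well == "A1"], 468)
  expect_identical(bc$corrected$qc[bc$corrected$well == "A2"],
                   "below_background")
  # low-count readings carry their own reason code
  mfis$low_count[1] <- TRUE
  bc <- background_correct(mfis, layout)
  expect_identical(bc$corrected$qc[bc$corrected$well == "A1"], "low_count")
})

test_that("spike normalization is a per-well ratio with spike QC", {
  corrected <- data.frame(
    well = c("A1", "A1", "A2", "A2"),
    region = c(1L, 57L, 1L, 57L),
    mfi = c(500, 2372, 400, 32), n_events = 100L,
    net = c(468, 2340, 368, 0),
    qc = "ok", stringsAsFactors = FALSE)
  expect_warning(norm <- spike_normalize(corrected), "A2")
  expect_equal(norm$norm, 0.2)
  expect_identical(norm$well, "A1")
  dead <- corrected[corrected$well == "A2", ]
  expect_warning(expect_error(spike_normalize(dead), "all wells excluded"))
})

test_that("ratio summary reproduces the direct-formula oracle", {
  sample_wells <- c(0.2, 0.25, 0.21)
  ref_wells <- c(0.10, 0.10, 0.12)
  normalized <- data.frame(
    well = paste0("A", 1:6), region = 1L, net = 1,
    norm = c(sample_wells, ref_wells), spike_net = 1,
    stringsAsFactors = FALSE)
  layout <- data.frame(
    well = paste0("A", 1:6),
    sample_id = rep(c("s1", "POOL"), each = 3),
    role = rep(c("test", "reference"), each = 3),
    replicate_index = rep(1:3, 2), stringsAsFactors = FALSE)
  summ <- summarize_expression(normalized, layout, "POOL")
  s1 <- summ[summ$sample == "s1", ]
  orc <- oracle_ratio_summary(sample_wells, ref_wells)
  expect_equal(2^s1$log2_ratio, orc$ratio)
  expect_equal(s1$log2_ratio, orc$log2_ratio)
  expect_equal(s1$log2_sd, orc$log2_sd)
  # frozen values computed from the oracle formulas
  expect_equal(orc$ratio, 2.0625, tolerance = 1e-6)
  expect_equal(orc$log2_ratio, 1.044394, tolerance = 1e-5)
  expect_equal(orc$rel_sd, 0.1618070, tolerance = 1e-5)
  # reference relative to itself is exactly zero
  expect_equal(summ$log2_ratio[summ$sample == "POOL"], 0)
  # zero reference spread degenerates the quadrature to the sample term
  norm0 <- normalized
  norm0$norm[4:6] <- 0.10
  summ0 <- summarize_expression(norm0, layout, "POOL")
  s10 <- summ0[summ0$sample == "s1", ]
  expect_equal(s10$log2_sd,
               (sd(sample_wells) / mean(sample_wells)) / log(2))
  # CI is centred on the replicate mean with the t(n-1) half-width
  expect_equal(s1$ci95_high - s1$norm_mfi_mean,
               qt(0.975, 2) * sd(sample_wells) / sqrt(3))
})

test_that("degenerate replicate structure is reported, not dropped", {
  normalized <- data.frame(
    well = paste0("A", 1:4), region = 1L, net = 1,
    norm = c(0.2, 0.1, 0.1, 0.12), spike_net = 1, stringsAsFactors = FALSE)
  layout <- data.frame(
    well = paste0("A", 1:4),
    sample_id = c("s1", rep("POOL", 3)),
    role = c("test", rep("reference", 3)),
    replicate_index = c(1L, 1:3), stringsAsFactors = FALSE)
  summ <- summarize_expression(normalized, layout, "POOL")
  s1 <- summ[summ$sample == "s1", ]
  expect_identical(s1$n_wells, 1L)
  expect_true(is.na(s1$norm_mfi_sd) && is.na(s1$ci95_low))
  expect_true(is.finite(s1$log2_ratio))
  # a reference with one surviving well cannot anchor ratios
  one_ref <- layout
  one_ref$sample_id <- c(rep("s1", 3), "POOL")
  one_ref$role <- c(rep("test", 3), "reference")
  expect_error(summarize_expression(normalized, one_ref, "POOL"),
               ">= 2 surviving wells")
})

test_that("specificity scoring matches arithmetic and the Welch oracle", {
  tbl <- data.frame(
    well = rep(paste0("A", 1:3), 2),
    region = rep(c(1L, 21L), each = 3),
    norm = c(1000, 1000, 1000, 380, 380, 380),
    probe_id = rep(c("PM", "MM"), each = 3), stringsAsFactors = FALSE)
  res <- specificity_score(tbl, "PM", "MM")
  expect_equal(res$pct_of_pm, 38)
  expect_equal(res$drop_pct, 62)

  tbl$norm <- c(5, 6, 7, 1, 2, 3)
  res <- specificity_score(tbl, "PM", "MM")
  orc <- oracle_welch_less(c(1, 2, 3), c(5, 6, 7))
  expect_equal(res$p_value, orc$p)
  expect_equal(orc$t, -4.898979, tolerance = 1e-6)

  tbl$norm <- rep(c(5, 6, 7), 2)  # MM identical to PM
  res <- specificity_score(tbl, "PM", "MM")
  expect_equal(res$pct_of_pm, 100)
  expect_gt(res$p_value, 0.4)

  tbl$norm <- rep(0, 6)
  expect_error(specificity_score(tbl, "PM", "MM"), "non-positive mean")
})

test_that("pipeline output is invariant to a global fluorescence gain", {
  cfg <- noise_free(default_config())
  pl <- simulate_expression(cfg)
  base <- run_expression_pipeline(pl)
  gained <- pl
  gained$events$fluorescence <- gained$events$fluorescence * 2.5
  rescaled <- run_expression_pipeline(gained)
  expect_equal(rescaled$norm_mfi_mean, base$norm_mfi_mean)
  expect_equal(rescaled$log2_ratio, base$log2_ratio)
})

test_that("default-noise 95% CIs cover the latent truth in most runs", {
  pan <- cell_line_panel()
  truth <- pan$latent / assay_config()$spike_fmol
  covered <- 0; total <- 0
  for (s in 1:200) {
    summ <- run_expression_pipeline(
      simulate_expression(default_config(seed = s), pan))
    summ <- summ[summ$probe_id != "Spike-18", ]
    tv <- truth[cbind(summ$sample, summ$probe_id)]
    hit <- summ$ci95_low <= tv & tv <= summ$ci95_high
    covered <- covered + sum(hit, na.rm = TRUE)
    total <- total + sum(!is.na(hit))
  }
  expect_gt(covered / total, 0.90)
})
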