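test_that("dilution series is the expected geometric progression", {
  expect_equal(make_dilution_series(),
               c(300, 75, 18.75, 4.6875, 1.171875, 0.29296875,
                 0.0732421875, 0.018310546875))
  expect_equal(make_dilution_series(dilution_design(10, 2, 3)),
               c(10, 5, 2.5))
  expect_equal(make_dilution_series(dilution_design(n_points = 1)), 300)
  expect_error(dilution_design(fold = 1), "fold must be > 1")
  expect_error(dilution_design(fold = 0.5), "fold must be > 1")
})

test_that("assay configuration rejects inconsistent efficiencies", {
  expect_error(assay_config(eff_1mm = c(a = 0.3), eff_2mm = c(a = 0.5)),
               "eff_2mm < eff_1mm")
  expect_error(assay_config(eff_1mm = c(a = 0.7), eff_2mm = c(b = 0.3)),
               "same probes")
  expect_error(assay_config(eff_1mm = c(a = 0.7), eff_2mm = c(a = -0.1)),
               "\\(0, 1\\]")
})

test_that("piecewise signal model anchors the knot and segment slopes", {
  cfg <- noise_free(default_config())
  pl <- simulate_calibration(cfg)
  cc <- build_calibration_curve(pl)
  means <- tapply(cc$curve$mfi, cc$curve$amount, mean)
  # corrected MFI at the knot is exactly the configured knot MFI
  expect_equal(unname(means[["18.75"]]), cfg$mfi_at_knot)
  # upper-segment ratio follows the plateau slope in closed form
  expect_equal(unname(means[["300"]] / means[["75"]]), 4^cfg$s2)
  # lower-segment ratio follows the linear-phase slope
  expect_equal(unname(means[["4.6875"]] / means[["1.171875"]]), 4^cfg$s1)
})

test_that("langmuir mode approaches unit log-log slope at low amounts", {
  cfg <- assay_config(signal_mode = "langmuir")
  c0 <- cfg$langmuir_kd / 1e4
  slope <- (log10(signal_model(c0 * 1.01, cfg)) -
              log10(signal_model(c0, cfg))) / log10(1.01)
  expect_lt(abs(slope - 1), 0.01)
})

test_that("simulations are deterministic in the seed", {
  cfg <- default_config(seed = 7)
  expect_identical(simulate_calibration(cfg), simulate_calibration(cfg))
  expect_identical(simulate_specificity(cfg), simulate_specificity(cfg))
  expect_identical(simulate_expression(cfg), simulate_expression(cfg))
  expect_identical(simulate_matched_platforms(config = cfg),
                   simulate_matched_platforms(config = cfg))
  other <- simulate_calibration(default_config(seed = 8))
  expect_false(identical(simulate_calibration(cfg)$events$fluorescence,
                         other$events$fluorescence))
  # and the simulator leaves the caller's RNG stream untouched
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(simulate_calibration(cfg)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("specificity plate encodes mismatch efficiencies generatively", {
  cfg <- noise_free(default_config())
  pl <- simulate_specificity(cfg)
  tr <- merge(pl$truth$medians, pl$probe_map, by = c("well", "region"))
  for (m in names(cfg$eff_2mm)) {
    pm <- tr$signal[tr$probe_id == m]
    mm1 <- tr$signal[tr$probe_id == paste0(m, "-1MM")]
    mm2 <- tr$signal[tr$probe_id == paste0(m, "-2MM")]
    expect_equal(mm1 / pm, rep(cfg$eff_1mm[[m]], length(pm)))
    expect_equal(mm2 / pm, rep(cfg$eff_2mm[[m]], length(pm)))
  }
})

test_that("complex-background labeling factors scale miRNA and spike alike", {
  cfg <- noise_free(default_config())
  pl <- simulate_specificity(cfg, complex_background = TRUE)
  f <- pl$truth$labeling_factor
  expect_true(length(unique(round(f, 10))) > 1)  # factors genuinely vary
  tr <- merge(pl$truth$medians, pl$probe_map, by = c("well", "region"))
  tr <- merge(tr, pl$layout[, c("well", "sample_id")], by = "well")
  tr <- tr[tr$sample_id != "background", ]
  g <- cfg$mfi_at_knot / cfg$knot_fmol
  spike <- tr[tr$probe_id == "Spike-18", ]
  expect_equal(spike$signal,
               g * cfg$spike_fmol * unname(f[spike$sample_id]))
  # spike/miRNA ratio is therefore labeling-free within each well
  pan <- cell_line_panel()
  pm <- tr[tr$probe_id %in% colnames(pan$latent), ]
  sp_by_well <- setNames(spike$signal, spike$well)
  expect_equal(pm$signal / sp_by_well[pm$well],
               unname(pan$latent[cbind(pm$sample_id, pm$probe_id)]) /
                 cfg$spike_fmol,
               ignore_attr = TRUE)
})

test_that("cell-line panel pools the seven samples in equal amounts", {
  pan <- cell_line_panel()
  expect_equal(pan$latent["POOL", ],
               colMeans(pan$latent[rownames(pan$latent) != "POOL", ]))
  expect_identical(pan$samples$group[pan$samples$sample == "POOL"],
                   "reference")
  expect_setequal(
    pan$samples$sample[pan$samples$group == "fusion_pos"],
    c("RH4", "RH30"))
})

test_that("expression plate has the documented well structure", {
  pl <- simulate_expression(default_config())
  lay <- pl$layout
  expect_identical(sum(lay$role != "background"), 24L)  # 8 samples x 3 wells
  expect_identical(sum(lay$role == "background"), 8L)
  counts <- table(pl$events$well, pl$events$region)
  expect_true(all(counts == 100))
  expect_identical(sort(unique(pl$events$region)), c(1L, 21L, 51L, 57L))
  # more probes than regions is rejected
  wide <- cell_line_panel(latent = matrix(
    1, 7, 5, dimnames = list(paste0("s", 1:7), paste0("m", 1:5))))
  expect_error(simulate_expression(default_config(), wide),
               "more probes than available bead regions")
})

test_that("matched platforms share the latent abundances", {
  pan <- cell_line_panel()
  cfg <- assay_config(array_noise_sd = 0, ct_noise_sd = 0)
  mp <- simulate_matched_platforms(pan, cfg)
  arr <- mp$microarray
  expect_equal(arr$log2_ratio,
               log2(pan$latent[cbind(arr$sample, arr$mirna)] /
                      pan$latent["POOL", arr$mirna]),
               ignore_attr = TRUE)
  ct <- mp$ct
  # doubling a latent abundance lowers Ct by exactly one cycle
  rd <- ct$ct[ct$sample == "RD" & ct$assay == "miR-23a"][1]
  pan2 <- pan
  pan2$latent["RD", "miR-23a"] <- 2 * pan$latent["RD", "miR-23a"]
  ct2 <- simulate_matched_platforms(pan2, cfg)$ct
  rd2 <- ct2$ct[ct2$sample == "RD" & ct2$assay == "miR-23a"][1]
  expect_equal(rd2, rd - 1)
  # the endogenous control is constant across samples at zero noise
  u6 <- ct$ct[ct$assay == "RNU6B"]
  expect_equal(u6, rep(u6[1], length(u6)))
})
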