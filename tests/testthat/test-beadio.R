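events_fixture <- function() {
  data.frame(well = c("A1", "A1", "A2"), region = c(1L, 1L, 1L),
             event = c(1L, 2L, 1L), fluorescence = c(10.5, 11.25, 9),
             stringsAsFactors = FALSE)
}

test_that("bead-event tables round-trip and validate line by line", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_bead_events(events_fixture(), path)
  back <- read_bead_events(path)
  expect_equal(back, events_fixture())

  writeLines(c("well,region,event,fluorescence",
               "A1,1,1,10", "A1,1,2,-1"), path)
  expect_error(read_bead_events(path), "line 3")
  writeLines(c("well,region,event,fluorescence",
               "A1,1,1,10", "Z9,1,1,10"), path)
  expect_error(read_bead_events(path), "malformed well 'Z9' at line 3")
  writeLines(c("well,region,event,fluorescence",
               "A1,1,1,10", "A1,1,1,11"), path)
  expect_error(read_bead_events(path), "duplicate")
  writeLines(c("well,region,fluorescence", "A1,1,10"), path)
  expect_error(read_bead_events(path), "missing column")
})

test_that("plate layouts round-trip; role/well validation at read time", {
  lay <- data.frame(well = c("A1", "B2", "H12"),
                    sample_id = c("s1", "s1", "background"),
                    role = c("test", "test", "background"),
                    replicate_index = c(1L, 2L, 1L),
                    stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_plate_layout(lay, path)
  expect_equal(read_plate_layout(path), lay)

  bad <- lay; bad$role[2] <- "blank"
  write_plate_layout(bad, path)
  expect_error(read_plate_layout(path), "unknown role 'blank'")
  bad <- lay; bad$well[2] <- "A1"
  write_plate_layout(bad, path)
  expect_error(read_plate_layout(path), "duplicate well")
  # a layout without background wells reads fine; quantification rejects it
  no_bg <- lay[lay$role != "background", ]
  write_plate_layout(no_bg, path)
  readback <- read_plate_layout(path)
  expect_identical(nrow(readback), 2L)
  mfis <- data.frame(well = c("A1", "B2"), region = 1L,
                     mfi = c(100, 120), n_events = 100L, low_count = FALSE)
  expect_error(background_correct(mfis, readback), "no background wells")
})

test_that("probe tables validate ids, lengths and parent consistency", {
  probes <- capture_probes()
  expect_identical(nrow(probes), 8L)
  path <- withr::local_tempfile(fileext = ".tsv")
  bad <- probes; bad$id[2] <- bad$id[1]
  utils::write.table(bad, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_probe_table(path), "duplicate probe_id")
  bad <- probes; bad$length_nt[1] <- 22L
  utils::write.table(bad, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_probe_table(path), "does not match sequence length")
  bad <- probes; bad$mismatch_count[1] <- 1L
  utils::write.table(bad, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_probe_table(path), "mismatch_count must be 0 iff")
})

test_that("Ct tables enforce the (0, 45) cycle window", {
  ct <- data.frame(sample = "RD", assay = "miR-23a", replicate = 1:3,
                   ct = c(24.1, 24.3, 24.2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_ct_table(ct, path)
  expect_equal(read_ct_table(path), ct)
  bad <- ct; bad$ct[2] <- 50
  write_ct_table(bad, path)
  expect_error(read_ct_table(path), "outside \\(0, 45\\) at line 3")
})

test_that("assay configurations round-trip through key = value text", {
  cfg <- assay_config(seed = 11, event_cv = 0.1,
                      eff_1mm = c("miR-27a" = 0.6, "miR-199a" = 0.5),
                      eff_2mm = c("miR-27a" = 0.3, "miR-199a" = 0.2))
  path <- withr::local_tempfile(fileext = ".txt")
  write_assay_config(cfg, path)
  expect_equal(read_assay_config(path), cfg)
  writeLines(c("seed = 1", "event_cvv = 0.2"), path)
  expect_error(read_assay_config(path), "unknown config key: event_cvv")
})

test_that("results writer emits 6-significant-digit TSV", {
  tbl <- data.frame(sample = "RD", value = 0.123456789, n = 3L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results(tbl, path)
  back <- utils::read.delim(path)
  expect_equal(back$value, 0.123457)
  expect_identical(back$n, 3L)
})

test_that("a whole simulated plate round-trips through its files", {
  pl <- simulate_calibration(default_config(), dilution_design(n_points = 6),
                             n_replicates = 2)
  prefix <- file.path(withr::local_tempdir(), "plate")
  paths <- write_plate(pl, prefix)
  ev <- read_bead_events(paths["events"])
  expect_equal(ev, pl$events[, c("well", "region", "event", "fluorescence")],
               ignore_attr = TRUE)
  lay <- read_plate_layout(paths["layout"])
  expect_equal(lay,
               pl$layout[, c("well", "sample_id", "role", "replicate_index")],
               ignore_attr = TRUE)
  expect_equal(read_assay_config(paths["config"]), pl$config)
})
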