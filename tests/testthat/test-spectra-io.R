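test_that("peak-list TSV round-trips losslessly", {
  fx <- makeFixture("isomer-pair")
  path <- withr::local_tempfile(fileext = ".tsv")
  writePeakList(fx$spectra, path)
  back <- readSpectra(path)
  expect_identical(scanIds(back), scanIds(fx$spectra))
  for (s in scanIds(back)) {
    expect_equal(back[[s]]@mz, fx$spectra[[s]]@mz, tolerance = 1e-6)
    expect_equal(back[[s]]@intensity, fx$spectra[[s]]@intensity,
                 tolerance = 1e-6)
    expect_identical(back[[s]]@precursorCharge,
                     fx$spectra[[s]]@precursorCharge)
  }
})

test_that("hand-written peak lists and edge cases parse correctly", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", ">s1\t500.25\t8", "200.1\t10", "300.2\t20"),
             path)
  got <- readSpectra(path)
  expect_length(got, 1L)
  expect_identical(nrow(peaksOf(got[["s1"]])), 2L)
  expect_identical(got[["s1"]]@precursorCharge, 8L)

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("# nothing", empty)
  expect_warning(none <- readSpectra(empty), "no spectra")
  expect_length(none, 0L)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("200.1\t10"), bad)
  expect_error(readSpectra(bad), "scan header")
})

test_that("unsorted peaks are sorted with a warning", {
  expect_warning(sp <- msSpectrum("x", 500, 8L, c(300, 200), c(1, 2)),
                 "not sorted")
  expect_identical(sp@mz, c(200, 300))
  expect_identical(sp@intensity, c(2, 1))
})

test_that("mzML spectra read back through mzR match the source peaks", {
  fx <- makeFixture("isomer-pair")
  sp <- as.list(fx$spectra)[1:2]
  hdr <- data.frame(
    seqNum = 1:2, acquisitionNum = 1:2, msLevel = 2L, polarity = 1L,
    peaksCount = vapply(sp, function(x) nrow(peaksOf(x)), integer(1)),
    totIonCurrent = vapply(sp, function(x) sum(x@intensity), numeric(1)),
    retentionTime = c(10, 20), basePeakMZ = 0, basePeakIntensity = 0,
    collisionEnergy = 0, ionisationEnergy = 0, lowMZ = 0, highMZ = 0,
    precursorScanNum = 0L,
    precursorMZ = vapply(sp, function(x) x@precursorMz, numeric(1)),
    precursorCharge = 8L, precursorIntensity = 100, mergedScan = 0L,
    mergedResultScanNum = 0L, mergedResultStartScanNum = 0L,
    mergedResultEndScanNum = 0L, injectionTime = 0,
    filterString = NA_character_, spectrumId = paste0("scan=", 1:2),
    centroided = TRUE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_,
    isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_)
  path <- withr::local_tempfile(fileext = ".mzML")
  mzR::writeMSData(lapply(sp, function(x) as.matrix(peaksOf(x))), path,
                   header = hdr)
  got <- readSpectra(path, "mzml")
  expect_length(got, 2L)
  expect_equal(got[[1L]]@mz, sp[[1L]]@mz, tolerance = 1e-6)
  expect_identical(got[[1L]]@precursorCharge, 8L)
})

test_that("PSM tables parse placements and collect rejects", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "scan_id,variant,mods,pep,delta_mod_score",
    "s1,H3.1,K4(Trimethyl),0.01,20",
    "s2,H3.1,K14me1; K23ac,0.02,15",
    "s3,H3.1,R2(Acetyl),0.01,20",
    "s4,H3.3,,0.04,12",
    "s5,H3.1,K4(Trimethyl),1.5,20"
  ), path)
  psms <- readPsmTable(path)
  expect_identical(nrow(psms), 3L)
  expect_identical(psms$key[psms$scan_id == "s1"], "H3K4me3")
  expect_identical(psms$key[psms$scan_id == "s2"], "H3K14me1/K23ac")
  expect_identical(psms$key[psms$scan_id == "s4"], "H3unmod")
  rejects <- attr(psms, "rejects")
  expect_identical(nrow(rejects), 2L)
  expect_identical(nrow(psms) + nrow(rejects), 5L)
  expect_match(rejects$reason[1L], "not allowed")

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("scan_id,variant,mods,pep,delta_mod_score", empty)
  expect_identical(nrow(readPsmTable(empty)), 0L)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("scan_id,variant,pep", "s1,H3.1,0.01"), bad)
  expect_error(readPsmTable(bad), "missing required column")
})

test_that("PSM tables written by the simulator read back identically", {
  fx <- makeFixture("isomer-pair")
  path <- withr::local_tempfile(fileext = ".csv")
  writePsmTable(fx$psms, path)
  back <- readPsmTable(path)
  expect_identical(back$key, fx$psms$key)
  expect_equal(back$pep, fx$psms$pep, tolerance = 1e-12)
  expect_identical(nrow(attr(back, "rejects")), 0L)
})

test_that("quant tables are written key-sorted and round-trip", {
  res <- data.frame(
    proteoform = c("H3K9me1", "H3K14me1"), variant = "H3.1",
    contrast = "B_vs_A", n_scans = c(5L, 4L), n_scans_used = c(5L, 4L),
    mean_log2_a = c(1.5, 2.25), mean_log2_b = c(1.0, 2.0),
    log2fc = c(0.5, 0.25), p_value = c(0.01, 0.2), n_a = 10L, n_b = 10L,
    testable = TRUE, coverage_pass = TRUE)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeQuantTable(res, path)
  back <- utils::read.delim(path)
  expect_identical(back$proteoform, c("H3K14me1", "H3K9me1"))
  expect_equal(back$log2fc, c(0.25, 0.5), tolerance = 1e-6)
  expect_equal(back$p_value, c(0.2, 0.01), tolerance = 1e-6)

  hdrOnly <- withr::local_tempfile(fileext = ".tsv")
  writeQuantTable(res[0, ], hdrOnly)
  expect_identical(nrow(utils::read.delim(hdrOnly)), 0L)
})

test_that("run configuration round-trips through YAML", {
  cfg <- runConfig(conditions = rep(c("ctrl", "drug"), 3L),
                   fragmentTolPpm = 12, weightByFraction = TRUE,
                   seed = 99L)
  path <- withr::local_tempfile(fileext = ".yaml")
  writeRunConfig(cfg, path)
  back <- readRunConfig(path)
  expect_equal(back@channels, cfg@channels)
  expect_identical(back@fragmentTolPpm, 12)
  expect_true(back@weightByFraction)
  expect_identical(back@seed, 99L)
  expect_identical(configConditions(back), c("ctrl", "drug"))
})
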