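noLossCfg <- runConfig(neutralLosses = character())

test_that("ion-set enumeration covers series x index x charge", {
  psm <- data.frame(variant = "H3.1", key = "H3unmod")
  ions <- generateIonSets(psm, noLossCfg, precursorCharge = 8L)
  expect_identical(nrow(ions), 5L * 35L * 2L)
  expect_identical(anyDuplicated(ions[, c("series", "index", "charge",
                                          "loss")]), 0L)
  ## neutral losses multiply the enumeration
  cfg2 <- runConfig(neutralLosses = c("H2O", "NH3"))
  expect_identical(nrow(generateIonSets(psm, cfg2, 8L)), 5L * 35L * 2L * 3L)
  ## no eligible fragment charge below the precursor
  expect_identical(nrow(generateIonSets(psm, noLossCfg,
                                        precursorCharge = 1L)), 0L)
})

test_that("positional isomers differ only between their placements", {
  c1 <- fragmentIonTable(proteoform("H3.1", 9L, "me1"), "c", 1L)
  c2 <- fragmentIonTable(proteoform("H3.1", 14L, "me1"), "c", 1L)
  differs <- abs(c1$mz - c2$mz) > 1e-9
  expect_identical(c1$index[differs], 9:13)
})

test_that("peak matching respects the inclusive ppm boundary", {
  ## integer-valued m/z makes the ppm arithmetic float-exact
  ions <- data.frame(proteoform = "P", variant = "H3.1", series = "c",
                     index = 1L, charge = 1L, loss = "none", mz = 1e6)
  at15 <- msSpectrum("s", 500, 8L, 1000015, 100)
  ann <- matchPeaks(at15, ions, noLossCfg)
  expect_identical(nrow(ann), 1L)
  expect_identical(ann$ppm, 15)

  beyond <- msSpectrum("s", 500, 8L, 1000015.1, 100)
  expect_identical(nrow(matchPeaks(beyond, ions, noLossCfg)), 0L)

  exact <- msSpectrum("s", 500, 8L, 1e6, 100)
  expect_identical(matchPeaks(exact, ions, noLossCfg)$ppm, 0)
})

test_that("the closest peak wins, ties broken by intensity", {
  ions <- data.frame(proteoform = "P", variant = "H3.1", series = "c",
                     index = 1L, charge = 1L, loss = "none", mz = 1e6)
  sp <- msSpectrum("s", 500, 8L, c(1000004, 1000007), c(5, 50))
  ann <- matchPeaks(sp, ions, noLossCfg)
  expect_identical(nrow(ann), 1L)
  expect_identical(ann$peak_mz, 1000004)

  tie <- msSpectrum("s", 500, 8L, c(999990, 1000010), c(5, 50))
  annTie <- matchPeaks(tie, ions, noLossCfg)
  expect_identical(annTie$peak_mz, 1000010)
})

test_that("reporter-region peaks are flagged and excluded from fragments", {
  ions <- data.frame(proteoform = "P", variant = "H3.1", series = "c",
                     index = 1L, charge = 1L, loss = "none", mz = 400)
  sp <- msSpectrum("s", 500, 8L, c(126.1277, 400), c(10, 20))
  ann <- matchPeaks(sp, ions, noLossCfg)
  expect_identical(nrow(ann), 2L)
  rep <- ann[ann$is_reporter, ]
  expect_identical(rep$peak_mz, 126.1277)
  expect_true(is.na(rep$proteoform))
  frag <- ann[!ann$is_reporter, ]
  expect_identical(frag$peak_mz, 400)
})

test_that("heavy-isotope confirmation requires the right spacing", {
  ions <- data.frame(proteoform = "P", variant = "H3.1", series = "c",
                     index = 1L, charge = 1L, loss = "none", mz = 400)
  withA1 <- msSpectrum("s", 500, 8L, c(400, 400 + 1.003355), c(100, 10))
  ann <- confirmHeavyIsotope(withA1, matchPeaks(withA1, ions, noLossCfg),
                             noLossCfg)
  expect_true(all(ann$isotope_confirmed))

  alone <- msSpectrum("s", 500, 8L, 400, 100)
  ann2 <- confirmHeavyIsotope(alone, matchPeaks(alone, ions, noLossCfg),
                              noLossCfg)
  expect_false(any(ann2$isotope_confirmed))

  ## companion at the charge-2 spacing does not confirm a charge-1 ion
  wrongZ <- msSpectrum("s", 500, 8L, c(400, 400 + 1.003355 / 2),
                       c(100, 10))
  ann3 <- confirmHeavyIsotope(wrongZ, matchPeaks(wrongZ, ions, noLossCfg),
                              noLossCfg)
  expect_false(any(ann3$isotope_confirmed))

  ## the 15N spacing is also accepted
  n15 <- msSpectrum("s", 500, 8L, c(400, 400 + 0.997035), c(100, 10))
  ann4 <- confirmHeavyIsotope(n15, matchPeaks(n15, ions, noLossCfg),
                              noLossCfg)
  expect_true(all(ann4$isotope_confirmed))
})

test_that("shared and unique ions are attributed correctly", {
  fx <- makeFixture("isomer-pair")
  s <- scanIds(fx$spectra)[1L]
  psms <- fx$psms[fx$psms$scan_id == s, ]
  ann <- annotateScan(fx$spectra[[s]], psms, fx$design$config)
  ## the fixture emits unique ions only, so every peak that survives
  ## heavy-isotope confirmation is attributed to exactly one isomer
  frag <- ann[!ann$is_reporter & ann$isotope_confirmed, ]
  expect_true(all(frag$attribution == "unique"))

  ## a full (non-unique-only) isomer pair shares the flanking c/z ions
  p1 <- proteoform("H3.1", 9L, "me1"); p2 <- proteoform("H3.1", 14L, "me1")
  ions <- rbind(fragmentIonTable(p1, c("c", "z"), 1L),
                fragmentIonTable(p2, c("c", "z"), 1L))
  mzs <- sort(unique(round(ions$mz, 6L)))
  sp <- msSpectrum("chim", 500, 8L, mzs, rep(10, length(mzs)))
  ann2 <- attributeAnnotations(matchPeaks(sp, ions, noLossCfg))
  c20 <- ann2[ann2$series == "c" & ann2$index == 20L, ]
  expect_true(all(c20$attribution == "shared"))
  expect_identical(sort(unique(c20$proteoform)),
                   c("H3K14me1", "H3K9me1"))
  c10 <- ann2[ann2$series == "c" & ann2$index == 10L, ]
  expect_true(all(c10$attribution == "unique"))
  expect_setequal(unique(c10$proteoform), c("H3K9me1", "H3K14me1"))
})

test_that("attribution is symmetric under PSM relabeling", {
  fx <- makeFixture("isomer-pair")
  s <- scanIds(fx$spectra)[1L]
  psms <- fx$psms[fx$psms$scan_id == s, ]
  annA <- annotateScan(fx$spectra[[s]], psms, fx$design$config)
  annB <- annotateScan(fx$spectra[[s]], psms[rev(seq_len(nrow(psms))), ],
                       fx$design$config)
  keyA <- annA[order(annA$peak_idx, annA$proteoform, annA$series,
                     annA$index, annA$charge), ]
  keyB <- annB[order(annB$peak_idx, annB$proteoform, annB$series,
                     annB$index, annB$charge), ]
  rownames(keyA) <- rownames(keyB) <- NULL
  expect_identical(keyA, keyB)
})

test_that("noise-free spectra of one proteoform annotate completely", {
  p <- proteoform("H3.1", c(4L, 14L), c("me3", "ac"))
  design <- simulationDesign(list(p), nScans = 2L,
                             seriesWeights = c(a = 0, b = 0, c = 1,
                                               y = 0, z = 1),
                             fragmentCharges = 1L, fragBaseSdlog = 0,
                             intensityCv = 0, dropoutRate = 0,
                             chaffPeaks = 0, reporterSdlog = 0, seed = 4L)
  sim <- simulateExperiment(design)
  s <- scanIds(sim$spectra)[1L]
  psms <- sim$psms[sim$psms$scan_id == s, ]
  ann <- annotateScan(sim$spectra[[s]], psms, design$config)
  frag <- ann[!ann$is_reporter & ann$loss == "none" &
              ann$series %in% c("c", "z") & ann$charge == 1L, ]
  ## every emitted c/z ion is matched and confirmed
  expect_identical(sort(unique(paste(frag$series, frag$index))),
                   sort(paste(rep(c("c", "z"), each = 35L), 1:35)))
  expect_true(all(frag$isotope_confirmed))
  q <- spectrumAbundance(ann, psms)
  expect_identical(unname(q$fractions), 1)
  expect_true(all(ann$attribution[!ann$is_reporter] == "unique"))
})
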