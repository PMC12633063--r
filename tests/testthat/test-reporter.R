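# Build a ReporterMatrix directly from a raw scans x channels matrix.
makeReporterMatrix <- function(raw, config, normalized = NULL) {
  ch <- config@channels
  colnames(raw) <- ch$channel
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(raw = raw),
    rowData = S4Vectors::DataFrame(scan_id = rownames(raw),
                                   row.names = rownames(raw)),
    colData = S4Vectors::DataFrame(channel = ch$channel,
                                   condition = ch$condition,
                                   replicate = ch$replicate,
                                   row.names = ch$channel))
  rm <- new("ReporterMatrix", se)
  if (!is.null(normalized)) {
    colnames(normalized) <- ch$channel
    SummarizedExperiment::assay(rm, "normalized") <- normalized
    SummarizedExperiment::assay(rm, "log2") <- log2(normalized)
  }
  rm
}

twoChannelCfg <- runConfig(conditions = c("A", "B"),
                           channelMz = c(`126` = 126.127726,
                                         `127` = 127.124761),
                           minReportersPerCondition = 1L)

test_that("reporter extraction takes the closest in-tolerance peak", {
  cfg <- runConfig()
  mzs <- unname(tmt6ReporterMz())
  full <- msSpectrum("s", 500, 8L, sort(mzs), 1:6)
  got <- extractReporters(full, cfg)
  expect_identical(sum(!is.na(got)), 6L)

  none <- msSpectrum("s", 500, 8L, c(200, 300), c(1, 1))
  expect_true(all(is.na(extractReporters(none, cfg))))

  ## peak midway between two channels is beyond tolerance of both
  mid <- msSpectrum("s", 500, 8L, mean(mzs[1:2]), 10)
  got2 <- extractReporters(mid, cfg)
  expect_true(all(is.na(got2)))
})

test_that("channel normalization equalizes channel means", {
  raw <- matrix(c(300, 100, 150, 50), nrow = 2L,
                dimnames = list(c("s1", "s2"), NULL))
  rm <- makeReporterMatrix(raw, twoChannelCfg)
  norm <- channelNormalize(rm)
  factors <- S4Vectors::metadata(norm)$channel_factors
  expect_equal(unname(factors), c(1, 2), tolerance = 1e-12)
  post <- colMeans(SummarizedExperiment::assay(norm, "normalized"))
  expect_equal(unname(post), c(200, 200), tolerance = 1e-12)

  ## idempotence
  again <- channelNormalize(norm)
  expect_equal(SummarizedExperiment::assay(again, "normalized"),
               SummarizedExperiment::assay(norm, "normalized"),
               tolerance = 1e-12)

  ## equal means are left untouched
  eq <- makeReporterMatrix(matrix(c(10, 30, 30, 10), nrow = 2L,
                                  dimnames = list(c("s1", "s2"), NULL)),
                           twoChannelCfg)
  expect_equal(unname(S4Vectors::metadata(
    channelNormalize(eq))$channel_factors), c(1, 1), tolerance = 1e-12)

  ## a channel with no usable signal is a hard error naming it
  bad <- makeReporterMatrix(matrix(c(10, 20, NA, NA), nrow = 2L,
                                   dimnames = list(c("s1", "s2"), NULL)),
                            twoChannelCfg)
  expect_error(channelNormalize(bad), "127")
})

test_that("condition coverage requires two reporters per condition", {
  cfg <- runConfig()  # 3 channels per condition, min 2
  ch <- cfg@channels$channel
  full <- setNames(rep(10, 6L), ch)
  expect_true(coverageFilter(full, cfg))

  one <- full; one[ch[1:2]] <- NA  # condition A down to 1 reporter
  expect_false(coverageFilter(one, cfg))

  exact2 <- full; exact2[ch[c(1, 4)]] <- NA  # exactly 2 per condition
  expect_true(coverageFilter(exact2, cfg))
})

test_that("group testing reproduces the hand-computed Welch contrast", {
  raw <- matrix(2^c(1, 2, 3, 2, 3, 4), nrow = 3L,
                dimnames = list(paste0("s", 1:3), NULL))
  rm <- makeReporterMatrix(raw, twoChannelCfg, normalized = raw)
  groups <- data.frame(scan_id = paste0("s", 1:3), variant = "H3.1",
                       key = "H3unmod", fraction = 1)
  res <- groupAndTest(rm, groups, contrasts = list(c("A", "B")),
                      config = twoChannelCfg)
  expect_identical(nrow(res), 1L)
  expect_equal(res$log2fc, -1, tolerance = 1e-12)
  ## frozen two-sample Welch t on pooled {1,2,3} vs {2,3,4}
  expect_equal(res$p_value, 0.287864135, tolerance = 1e-8)
  expect_identical(res$n_a, 3L)
  expect_true(res$testable)

  ## antisymmetry: reversing the contrast negates log2FC, keeps p
  rev <- groupAndTest(rm, groups, contrasts = list(c("B", "A")),
                      config = twoChannelCfg)
  expect_equal(rev$log2fc, -res$log2fc, tolerance = 1e-12)
  expect_equal(rev$p_value, res$p_value, tolerance = 1e-12)
})

test_that("identical pooled conditions give zero log2FC", {
  raw <- matrix(2^c(1, 2, 3, 1, 2, 3), nrow = 3L,
                dimnames = list(paste0("s", 1:3), NULL))
  rm <- makeReporterMatrix(raw, twoChannelCfg, normalized = raw)
  groups <- data.frame(scan_id = paste0("s", 1:3), variant = "H3.1",
                       key = "H3unmod", fraction = 1)
  res <- groupAndTest(rm, groups, contrasts = list(c("A", "B")),
                      config = twoChannelCfg)
  expect_equal(res$log2fc, 0, tolerance = 1e-12)
})

test_that("a condition with one pooled value is untestable but reported", {
  raw <- matrix(c(2, 4, 8, 16, NA, NA), nrow = 3L,
                dimnames = list(paste0("s", 1:3), NULL))
  rm <- makeReporterMatrix(raw, twoChannelCfg, normalized = raw)
  groups <- data.frame(scan_id = paste0("s", 1:3), variant = "H3.1",
                       key = "H3unmod", fraction = 1)
  res <- groupAndTest(rm, groups, contrasts = list(c("A", "B")),
                      config = twoChannelCfg)
  expect_false(res$testable)
  expect_true(is.na(res$p_value))
  expect_true(is.finite(res$log2fc))
})

test_that("noise-free symmetric fold changes are recovered exactly", {
  panel <- list(proteoform("H3.1", 9L, "me1"),
                proteoform("H3.1", 14L, "me1"))
  fc <- cbind(A = 2^(-c(1, -1) / 2), B = 2^(c(1, -1) / 2))
  design <- simulationDesign(
    panel, nScans = 8L, foldChange = fc,
    scanAssignment = as.list(rep(1:2, each = 4L)),
    seriesWeights = c(a = 0, b = 0, c = 1, y = 0, z = 1),
    fragmentCharges = 1L, fragBaseSdlog = 0, intensityCv = 0,
    dropoutRate = 0, chaffPeaks = 0, reporterSdlog = 0, seed = 6L)
  sim <- simulateExperiment(design)
  out <- runPipeline(sim$spectra, sim$psms, design$config)
  res <- merge(out$results, sim$truth$proteoforms,
               by = c("proteoform", "variant", "contrast"))
  expect_equal(res$log2fc, res$true_log2fc, tolerance = 1e-9)
})
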