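#' Extract TMT reporter intensities from a spectrum
#'
#' For each configured channel, takes the intensity of the closest peak
#' within the reporter ppm tolerance of the channel's m/z, or NA when no
#' peak is in tolerance. Missing reporters stay missing; nothing is imputed.
#'
#' @param spectrum An [MsSpectrum-class].
#' @param config A [RunConfig-class] carrying the channel table.
#' @return Named numeric vector, channel -> intensity (NA = missing).
#' @export
extractReporters <- function(spectrum, config = runConfig()) {
  ch <- config@channels
  mzs <- spectrum@mz
  out <- setNames(rep(NA_real_, nrow(ch)), ch$channel)
  if (!length(mzs)) return(out)
  for (i in seq_len(nrow(ch))) {
    near <- findInterval(ch$mz[i], mzs)
    cand <- unique(pmin(pmax(c(near, near + 1L), 1L), length(mzs)))
    d <- abs(ppmError(mzs[cand], ch$mz[i]))
    j <- which.min(d)
    if (d[j] <= config@reporterTolPpm)
      out[i] <- spectrum@intensity[cand[j]]
  }
  out
}

#' Build a ReporterMatrix over the scans of a run
#'
#' Rows are scans (all spectra carrying at least one kept PSM), columns the
#' TMT channels; the `"raw"` assay holds extracted intensities.
#'
#' @param spectra A [SpectrumSet-class].
#' @param scanIds Scans to include (row order).
#' @param config A [RunConfig-class].
#' @return A [ReporterMatrix-class].
#' @export
reporterMatrix <- function(spectra, scanIds, config = runConfig()) {
  raw <- t(vapply(scanIds,
                  function(s) extractReporters(spectra[[s]], config),
                  numeric(nrow(config@channels))))
  if (length(scanIds) == 1L) rownames(raw) <- scanIds
  ch <- config@channels
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(raw = raw),
    rowData = S4Vectors::DataFrame(scan_id = scanIds, row.names = scanIds),
    colData = S4Vectors::DataFrame(channel = ch$channel,
                                   condition = ch$condition,
                                   replicate = ch$replicate,
                                   row.names = ch$channel))
  new("ReporterMatrix", se)
}

#' Channel-normalize reporter intensities
#'
#' Scales every channel so that its mean intensity over all PSM-bearing
#' scans (missing entries ignored) equals the mean of the most intense
#' channel: each channel is multiplied by max(channel means) / (its mean).
#' Adds `"normalized"` and `"log2"` assays; the operation is idempotent.
#'
#' @param rm A [ReporterMatrix-class] with a `"raw"` assay.
#' @return The matrix with `"normalized"` and `"log2"` assays and the scale
#'   factors stored in `metadata(rm)$channel_factors`.
#' @export
channelNormalize <- function(rm) {
  raw <- SummarizedExperiment::assay(rm, "raw")
  means <- colMeans(raw, na.rm = TRUE)
  if (any(!is.finite(means) | means <= 0)) {
    bad <- colnames(raw)[!is.finite(means) | means <= 0]
    stop("channel(s) with no usable reporter signal: ",
         paste(bad, collapse = ", "))
  }
  factors <- max(means) / means
  normalized <- sweep(raw, 2L, factors, `*`)
  SummarizedExperiment::assay(rm, "normalized") <- normalized
  SummarizedExperiment::assay(rm, "log2") <- log2(normalized)
  S4Vectors::metadata(rm)$channel_factors <- factors
  rm
}

#' Condition-coverage filter for a scan
#'
#' A scan is used in quantification only when every treatment condition has
#' at least `minReportersPerCondition` (default 2) non-missing reporter
#' ions.
#'
#' @param reporters Named channel -> intensity vector (NA = missing), as
#'   from [extractReporters()], or one row of a [ReporterMatrix-class] raw
#'   assay.
#' @param config A [RunConfig-class].
#' @return `TRUE` when the scan passes.
#' @export
coverageFilter <- function(reporters, config = runConfig()) {
  ch <- config@channels
  present <- !is.na(reporters[ch$channel])
  counts <- tapply(present, ch$condition, sum)
  all(counts >= config@minReportersPerCondition)
}

#' Group scans by proteoform and test contrasts
#'
#' Pools, for each proteoform group and condition, the channel-normalized
#' log2 reporter signals of every coverage-passing scan attributed to the
#' group, then reports per contrast the difference of condition means as
#' the log2 fold change and a two-sided Welch t-test p-value on the pooled
#' per-scan, per-channel values. A condition with fewer than two pooled
#' values makes the contrast untestable (log2FC still reported, p NA).
#'
#' With `weightByFraction` set in the config, a chimeric scan's normalized
#' (linear) signal is multiplied by the scan's proteoform fraction before
#' the log2 transform; by default a scan contributes its full reporter
#' signal to every proteoform group it is assigned to.
#'
#' @param rm A normalized [ReporterMatrix-class] (see [channelNormalize()]).
#' @param scanGroups `data.frame` with columns `scan_id`, `variant`, `key`
#'   and `fraction` linking scans to proteoform groups.
#' @param contrasts List of `c(conditionA, conditionB)` pairs; default every
#'   non-reference condition against the first configured condition.
#' @param config A [RunConfig-class].
#' @return `data.frame`, one row per proteoform per contrast: `proteoform`,
#'   `variant`, `contrast` (`"A_vs_B"`), `n_scans`, `n_scans_used`,
#'   `mean_log2_a`, `mean_log2_b`, `log2fc`, `p_value`, `n_a`, `n_b`,
#'   `testable`, `coverage_pass`.
#' @export
groupAndTest <- function(rm, scanGroups, contrasts = NULL,
                         config = runConfig()) {
  conds <- configConditions(config)
  if (is.null(contrasts)) {
    contrasts <- lapply(setdiff(conds, conds[1L]),
                        function(x) c(x, conds[1L]))
  }
  norm <- SummarizedExperiment::assay(rm, "normalized")
  ch <- config@channels
  covPass <- vapply(rownames(norm), function(s)
    coverageFilter(SummarizedExperiment::assay(rm, "raw")[s, ], config),
    logical(1))
  groups <- split(scanGroups, paste(scanGroups$variant, scanGroups$key,
                                    sep = "|"))
  rows <- list()
  for (g in groups) {
    key <- g$key[1L]; variant <- g$variant[1L]
    inMat <- g$scan_id %in% rownames(norm)
    used <- g[inMat & covPass[g$scan_id], , drop = FALSE]
    ## pooled log2 values per condition
    pool <- lapply(conds, function(cond) {
      chans <- ch$channel[ch$condition == cond]
      if (!nrow(used)) return(numeric())
      vals <- norm[used$scan_id, chans, drop = FALSE]
      if (config@weightByFraction)
        vals <- vals * used$fraction
      v <- log2(as.numeric(vals))
      v[is.finite(v)]
    })
    names(pool) <- conds
    for (ct in contrasts) {
      a <- pool[[ct[1L]]]; b <- pool[[ct[2L]]]
      testable <- length(a) >= 2L && length(b) >= 2L
      log2fc <- mean(a) - mean(b)
      p <- NA_real_
      if (testable && (stats::var(a) > 0 || stats::var(b) > 0))
        p <- stats::t.test(a, b, alternative = "two.sided",
                           var.equal = FALSE)$p.value
      rows[[length(rows) + 1L]] <- data.frame(
        proteoform = key, variant = variant,
        contrast = paste(ct[1L], "vs", ct[2L], sep = "_"),
        n_scans = length(unique(g$scan_id)),
        n_scans_used = length(unique(used$scan_id)),
        mean_log2_a = mean(a), mean_log2_b = mean(b),
        log2fc = log2fc, p_value = p,
        n_a = length(a), n_b = length(b),
        testable = testable,
        coverage_pass = nrow(used) > 0L
      )
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(proteoform = character(), variant = character(),
                      contrast = character(), n_scans = integer(),
                      n_scans_used = integer(), mean_log2_a = numeric(),
                      mean_log2_b = numeric(), log2fc = numeric(),
                      p_value = numeric(), n_a = integer(), n_b = integer(),
                      testable = logical(), coverage_pass = logical()))
  out <- out[order(out$proteoform, out$variant, out$contrast), ]
  if (config@adjustP)
    out$p_value <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}
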