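#' TMT 6-plex reporter ion m/z table
#'
#' Reporter-ion m/z values for channels 126-131, derived from the reporter
#' cation elemental compositions (combinations of 13C and 15N coding) minus
#' one electron mass. These live in configuration, not in the matching code,
#' so alternative labeling chemistries can be supplied.
#'
#' @return Named numeric vector, channel name -> m/z.
#' @export
tmt6ReporterMz <- function() {
  comps <- list(
    `126` = c(C = 8, H = 16, N = 1),
    `127` = c(C = 8, H = 16, `15N` = 1),
    `128` = c(C = 6, `13C` = 2, H = 16, N = 1),
    `129` = c(C = 6, `13C` = 2, H = 16, `15N` = 1),
    `130` = c(C = 4, `13C` = 4, H = 16, N = 1),
    `131` = c(C = 4, `13C` = 4, H = 16, `15N` = 1)
  )
  vapply(comps, function(x) compositionMass(x) - .ELECTRON_MASS, numeric(1))
}

#' Construct a run configuration
#'
#' Bundles the tolerances, TMT channel layout, PSM filter thresholds and
#' matching options of a quantification run. Defaults follow the pipeline's
#' reference settings: 15 ppm fragment and 500 ppm precursor tolerance, PSMs
#' kept at posterior error probability <= 0.05 and delta-mod score >= 10,
#' and scans used when every condition has >= 2 observed reporters.
#'
#' @param conditions Character vector, one condition label per channel, in
#'   channel order (default two conditions over the six TMT channels).
#' @param channelMz Named numeric vector of reporter m/z values
#'   (default [tmt6ReporterMz()]).
#' @param replicates Integer vector of replicate numbers per channel
#'   (default numbered within condition).
#' @param fragmentTolPpm,precursorTolPpm,reporterTolPpm Tolerances in ppm.
#' @param pepMax,deltaMin PSM filter thresholds (both boundaries inclusive).
#' @param minReportersPerCondition Coverage threshold per condition.
#' @param alpha Reporting significance level.
#' @param maxFragmentCharge Cap on enumerated fragment charges.
#' @param neutralLosses Neutral losses enumerated alongside plain fragments.
#' @param maxPsmsPerScan Scans with more kept PSMs are dropped with warning.
#' @param reporterWindow m/z window flagged as reporter region and excluded
#'   from fragment matching.
#' @param isotopeSpacings Accepted heavy-isotope spacings in Da at charge 1
#'   (13C by default, with the 15N spacing also accepted).
#' @param weightByFraction Weight a chimeric scan's reporter signal by its
#'   proteoform fraction instead of contributing it fully to every group.
#' @param adjustP Benjamini-Hochberg adjust reported p-values.
#' @param seed Integer seed recorded in the run manifest.
#' @return A validated [RunConfig-class].
#' @export
runConfig <- function(conditions = rep(c("A", "B"), each = 3L),
                      channelMz = tmt6ReporterMz(),
                      replicates = NULL,
                      fragmentTolPpm = 15, precursorTolPpm = 500,
                      reporterTolPpm = 15,
                      pepMax = 0.05, deltaMin = 10,
                      minReportersPerCondition = 2L, alpha = 0.05,
                      maxFragmentCharge = 2L,
                      neutralLosses = c("H2O", "NH3"),
                      maxPsmsPerScan = 5L,
                      reporterWindow = c(125.5, 132.0),
                      isotopeSpacings = c(.C13_SPACING, .N15_SPACING),
                      weightByFraction = FALSE, adjustP = FALSE,
                      seed = 1L) {
  if (length(conditions) != length(channelMz))
    stop("conditions must map one label per channel")
  if (is.null(replicates))
    replicates <- stats::ave(seq_along(conditions), conditions,
                             FUN = seq_along)
  channels <- data.frame(
    channel = names(channelMz), mz = unname(channelMz),
    condition = as.character(conditions), replicate = as.integer(replicates),
    stringsAsFactors = FALSE
  )
  new("RunConfig", fragmentTolPpm = fragmentTolPpm,
      precursorTolPpm = precursorTolPpm, reporterTolPpm = reporterTolPpm,
      channels = channels, pepMax = pepMax, deltaMin = deltaMin,
      minReportersPerCondition = as.integer(minReportersPerCondition),
      alpha = alpha, maxFragmentCharge = as.integer(maxFragmentCharge),
      neutralLosses = neutralLosses,
      maxPsmsPerScan = as.integer(maxPsmsPerScan),
      reporterWindow = reporterWindow, isotopeSpacings = isotopeSpacings,
      weightByFraction = weightByFraction, adjustP = adjustP,
      seed = as.integer(seed))
}

## Neutral-loss compositions named in a config.
.configLosses <- function(config) {
  all <- list(H2O = .MOLECULE_COMPOSITION$H2O, NH3 = .MOLECULE_COMPOSITION$NH3)
  all[intersect(config@neutralLosses, names(all))]
}

#' Conditions present in a config, in channel order
#' @param config A [RunConfig-class].
#' @return Character vector of unique condition labels.
#' @export
configConditions <- function(config) unique(config@channels$condition)

#' Read / write a run configuration as YAML
#'
#' The YAML layout mirrors the constructor arguments; the channel table is a
#' list of `{channel, mz, condition, replicate}` records. Round-trips are
#' lossless.
#'
#' @param path File path.
#' @return `readRunConfig` returns a [RunConfig-class]; `writeRunConfig`
#'   returns `path` invisibly.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  ch <- do.call(rbind, lapply(y$channels, as.data.frame))
  runConfig(
    conditions = as.character(ch$condition),
    channelMz = setNames(as.numeric(ch$mz), as.character(ch$channel)),
    replicates = as.integer(ch$replicate),
    fragmentTolPpm = y$fragment_tol_ppm, precursorTolPpm = y$precursor_tol_ppm,
    reporterTolPpm = y$reporter_tol_ppm, pepMax = y$pep_max,
    deltaMin = y$delta_min,
    minReportersPerCondition = y$min_reporters_per_condition,
    alpha = y$alpha, maxFragmentCharge = y$max_fragment_charge,
    neutralLosses = as.character(y$neutral_losses %||% character()),
    maxPsmsPerScan = y$max_psms_per_scan,
    reporterWindow = as.numeric(y$reporter_window),
    isotopeSpacings = as.numeric(y$isotope_spacings),
    weightByFraction = isTRUE(y$weight_by_fraction),
    adjustP = isTRUE(y$adjust_p), seed = y$seed
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname readRunConfig
#' @param config A [RunConfig-class] to serialize.
#' @export
writeRunConfig <- function(config, path) {
  ch <- config@channels
  y <- list(
    fragment_tol_ppm = config@fragmentTolPpm,
    precursor_tol_ppm = config@precursorTolPpm,
    reporter_tol_ppm = config@reporterTolPpm,
    channels = lapply(seq_len(nrow(ch)), function(i) as.list(ch[i, ])),
    pep_max = config@pepMax, delta_min = config@deltaMin,
    min_reporters_per_condition = config@minReportersPerCondition,
    alpha = config@alpha, max_fragment_charge = config@maxFragmentCharge,
    neutral_losses = as.list(config@neutralLosses),
    max_psms_per_scan = config@maxPsmsPerScan,
    reporter_window = as.list(config@reporterWindow),
    isotope_spacings = as.list(config@isotopeSpacings),
    weight_by_fraction = config@weightByFraction,
    adjust_p = config@adjustP, seed = config@seed
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

setMethod("show", "RunConfig", function(object) {
  cat("RunConfig:", nrow(object@channels), "channels over",
      length(configConditions(object)), "conditions\n")
  cat("  fragment tol:", object@fragmentTolPpm, "ppm; precursor tol:",
      object@precursorTolPpm, "ppm\n")
  cat("  PSM filter: PEP <=", object@pepMax, ", delta >=", object@deltaMin,
      "\n")
})
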