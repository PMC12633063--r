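#' @import methods
#' @importFrom S4Vectors SimpleList DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<-
#'   assayNames colData rowData rowData<-
NULL

#' Proteoform: a histone H3 tail with positioned modifications
#'
#' A proteoform is one of the two sortase-released H3 N-terminal tail
#' peptides (H3.1 or H3.3, 36 residues) together with a set of positioned
#' variable modifications. Residue index `i` of the peptide corresponds to
#' histone residue `i`, so index 4 is H3K4. Fixed chemistry (TMT 6-plex on
#' His, the sortase-tag C-terminal correction) is implied, not stored.
#'
#' @slot variant `"H3.1"` or `"H3.3"`.
#' @slot positions Integer vector of 1-based modified positions, strictly
#'   increasing.
#' @slot mods Character vector of modification abbreviations (`me1`, `me2`,
#'   `me3`, `ac`, `ph`, `pr`), parallel to `positions`.
#' @seealso [proteoform()], [proteoformKey()], [parseProteoformKey()]
#' @export
setClass("Proteoform",
  representation(variant = "character", positions = "integer",
                 mods = "character"))

setValidity("Proteoform", function(object) {
  msgs <- character()
  if (length(object@variant) != 1L || !object@variant %in% names(.H3_TAIL))
    return(paste("variant must be one of:",
                 paste(names(.H3_TAIL), collapse = ", ")))
  if (length(object@positions) != length(object@mods))
    return("positions and mods must be parallel vectors")
  seqchars <- strsplit(.H3_TAIL[[object@variant]], "")[[1]]
  if (length(object@positions)) {
    if (any(object@positions < 1L | object@positions > length(seqchars)))
      return("placement positions out of sequence range")
    if (is.unsorted(object@positions, strictly = TRUE))
      msgs <- c(msgs, "placement positions must be strictly increasing")
    mods <- modificationTable()
    for (j in seq_along(object@positions)) {
      i <- match(object@mods[j], mods$abbrev)
      if (is.na(i)) {
        msgs <- c(msgs, paste0("unknown modification abbreviation: ",
                               object@mods[j]))
        next
      }
      if (isTRUE(mods$fixed[i])) {
        msgs <- c(msgs, paste0(mods$name[i], " is a fixed modification"))
        next
      }
      res <- seqchars[object@positions[j]]
      if (!grepl(res, mods$targets[i], fixed = TRUE))
        msgs <- c(msgs, paste0(mods$name[i], " not allowed on residue ", res,
                               object@positions[j]))
    }
    counts <- table(object@mods)
    caps <- mods$max_per_peptide[match(names(counts), mods$abbrev)]
    over <- !is.na(caps) & as.integer(counts) > caps
    if (any(over))
      msgs <- c(msgs, paste0("placement count exceeds max_per_peptide for: ",
                             paste(names(counts)[over], collapse = ", ")))
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' MsSpectrum: a centroided MS2 scan
#'
#' @slot scanId Opaque scan identifier (character).
#' @slot precursorMz,precursorCharge Precursor descriptors.
#' @slot mz,intensity Parallel peak vectors; `mz` strictly increasing,
#'   `intensity` non-negative.
#' @seealso [msSpectrum()], [readSpectra()]
#' @export
setClass("MsSpectrum",
  representation(scanId = "character", precursorMz = "numeric",
                 precursorCharge = "integer", mz = "numeric",
                 intensity = "numeric"))

setValidity("MsSpectrum", function(object) {
  if (length(object@scanId) != 1L)
    return("scanId must be a single string")
  if (length(object@mz) != length(object@intensity))
    return("mz and intensity must be parallel")
  if (length(object@mz) && is.unsorted(object@mz, strictly = TRUE))
    return("peaks must be sorted strictly increasing in m/z")
  if (any(object@intensity < 0))
    return("intensities must be >= 0")
  TRUE
})

#' SpectrumSet: an ordered collection of MsSpectrum objects
#'
#' A thin [S4Vectors::SimpleList] subclass keyed by scan id.
#' @export
setClass("SpectrumSet", contains = "SimpleList",
         prototype = prototype(elementType = "MsSpectrum"))

#' RunConfig: tolerances, channel layout and filter thresholds for a run
#'
#' @slot fragmentTolPpm Fragment-ion match tolerance (ppm, default 15).
#' @slot precursorTolPpm Precursor tolerance (ppm, default 500).
#' @slot reporterTolPpm Reporter-ion extraction tolerance (ppm).
#' @slot channels `data.frame` with columns `channel`, `mz`, `condition`,
#'   `replicate`: the TMT channel map.
#' @slot pepMax Maximum posterior error probability for a kept PSM (0.05).
#' @slot deltaMin Minimum delta-mod score for a kept PSM (10).
#' @slot minReportersPerCondition Coverage threshold (2).
#' @slot alpha Significance level for reporting (0.05).
#' @slot maxFragmentCharge Cap on enumerated fragment charges.
#' @slot neutralLosses Character subset of `c("H2O","NH3")`.
#' @slot maxPsmsPerScan Scans with more kept PSMs are excluded (5).
#' @slot reporterWindow Low/high m/z bounds of the reporter region.
#' @slot isotopeSpacings Accepted heavy-isotope spacings (Da at charge 1).
#' @slot weightByFraction Weight reporter signal by the scan's proteoform
#'   fraction before log transform.
#' @slot adjustP Apply Benjamini-Hochberg correction to reported p-values.
#' @slot seed Integer RNG seed recorded with the run.
#' @seealso [runConfig()]
#' @export
setClass("RunConfig",
  representation(fragmentTolPpm = "numeric", precursorTolPpm = "numeric",
                 reporterTolPpm = "numeric", channels = "data.frame",
                 pepMax = "numeric", deltaMin = "numeric",
                 minReportersPerCondition = "integer", alpha = "numeric",
                 maxFragmentCharge = "integer", neutralLosses = "character",
                 maxPsmsPerScan = "integer", reporterWindow = "numeric",
                 isotopeSpacings = "numeric", weightByFraction = "logical",
                 adjustP = "logical", seed = "integer"))

setValidity("RunConfig", function(object) {
  if (object@fragmentTolPpm <= 0 || object@precursorTolPpm <= 0 ||
      object@reporterTolPpm <= 0)
    return("tolerances must be > 0")
  ch <- object@channels
  need <- c("channel", "mz", "condition", "replicate")
  if (!all(need %in% names(ch)))
    return(paste("channels must have columns:", paste(need, collapse = ", ")))
  if (!nrow(ch) || any(!nzchar(ch$condition)))
    return("every channel must be mapped to a condition")
  if (length(object@reporterWindow) != 2L ||
      diff(object@reporterWindow) <= 0)
    return("reporterWindow must be c(low, high) with low < high")
  TRUE
})

#' ReporterMatrix: scan-by-channel reporter intensities
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding TMT
#' reporter-ion intensities with scans as rows and channels as columns.
#' The `"raw"` assay holds extracted intensities (NA = missing);
#' [channelNormalize()] adds `"normalized"` and `"log2"` assays. `colData`
#' carries the channel -> (condition, replicate) map and `rowData` per-scan
#' bookkeeping (coverage flag, number of PSMs).
#' @export
setClass("ReporterMatrix", contains = "SummarizedExperiment")

setValidity("ReporterMatrix", function(object) {
  if (!"raw" %in% SummarizedExperiment::assayNames(object))
    return("ReporterMatrix must carry a 'raw' assay")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("condition", "replicate") %in% names(cd)))
    return("colData must have 'condition' and 'replicate'")
  raw <- SummarizedExperiment::assay(object, "raw")
  if (any(raw[!is.na(raw)] < 0))
    return("raw reporter intensities must be >= 0 or NA")
  TRUE
})
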