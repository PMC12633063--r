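#' Theoretical ion sets for a scan's candidate proteoforms
#'
#' Enumerates a/b/c/y/z fragment ions (with the configured neutral losses)
#' for every candidate proteoform assigned to a scan, at fragment charges
#' 1 up to one below the precursor charge, capped by the config.
#'
#' @param psmsForScan PSM rows of one scan (columns `variant`, `key`).
#' @param config A [RunConfig-class].
#' @param precursorCharge Precursor charge of the scan.
#' @return `data.frame` of theoretical ions (see [fragmentIonTable()]).
#' @export
generateIonSets <- function(psmsForScan, config = runConfig(),
                            precursorCharge = 8L) {
  maxZ <- min(precursorCharge - 1L, config@maxFragmentCharge)
  if (maxZ < 1L)
    return(fragmentIonTable(proteoform(), charges = integer())[0, ])
  cand <- unique(psmsForScan[, c("variant", "key")])
  tabs <- lapply(seq_len(nrow(cand)), function(i)
    fragmentIonTable(parseProteoformKey(cand$key[i], cand$variant[i]),
                     charges = seq_len(maxZ),
                     losses = .configLosses(config)))
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  out
}

#' Match observed peaks to theoretical ions
#'
#' Assigns each theoretical ion to its closest observed peak within the
#' fragment ppm tolerance (ties broken toward the higher-intensity peak);
#' each observed peak then carries all ions assigned to it, so a peak is
#' annotated at most once. Peaks inside the reporter window are flagged
#' `is_reporter` and excluded from fragment matching.
#'
#' @param spectrum An [MsSpectrum-class].
#' @param ions Theoretical ion table from [generateIonSets()].
#' @param config A [RunConfig-class].
#' @return `data.frame` with one row per (peak, matched ion): columns
#'   `peak_idx`, `peak_mz`, `peak_intensity`, `is_reporter`, `proteoform`,
#'   `variant`, `series`, `index`, `charge`, `loss`, `mz_theo`, `ppm`.
#'   Reporter-region peaks appear once with NA ion fields.
#' @export
matchPeaks <- function(spectrum, ions, config = runConfig()) {
  mzs <- spectrum@mz
  ints <- spectrum@intensity
  inReporter <- mzs >= config@reporterWindow[1L] &
                mzs <= config@reporterWindow[2L]
  fragIdx <- which(!inReporter)
  empty <- data.frame(
    peak_idx = integer(), peak_mz = numeric(), peak_intensity = numeric(),
    is_reporter = logical(), proteoform = character(), variant = character(),
    series = character(), index = integer(), charge = integer(),
    loss = character(), mz_theo = numeric(), ppm = numeric()
  )
  repRows <- if (any(inReporter)) data.frame(
    peak_idx = which(inReporter), peak_mz = mzs[inReporter],
    peak_intensity = ints[inReporter], is_reporter = TRUE,
    proteoform = NA_character_, variant = NA_character_,
    series = NA_character_, index = NA_integer_, charge = NA_integer_,
    loss = NA_character_, mz_theo = NA_real_, ppm = NA_real_
  ) else empty
  if (!length(fragIdx) || is.null(ions) || !nrow(ions)) {
    out <- rbind(empty, repRows)
    rownames(out) <- NULL
    return(out)
  }
  pmz <- mzs[fragIdx]
  tol <- config@fragmentTolPpm
  lo <- findInterval(ions$mz, pmz)
  hi <- pmz[pmin(lo + 1L, length(pmz))]
  loMz <- pmz[pmax(lo, 1L)]
  ppmLo <- ifelse(lo >= 1L, ppmError(loMz, ions$mz), Inf)
  ppmHi <- ifelse(lo < length(pmz), ppmError(hi, ions$mz), Inf)
  okLo <- abs(ppmLo) <= tol
  okHi <- abs(ppmHi) <= tol
  ## closest-ppm peak wins; tie -> higher intensity
  intLo <- ints[fragIdx][pmax(lo, 1L)]
  intHi <- ints[fragIdx][pmin(lo + 1L, length(pmz))]
  pickHi <- okHi & (!okLo | abs(ppmHi) < abs(ppmLo) |
                    (abs(ppmHi) == abs(ppmLo) & intHi > intLo))
  pick <- ifelse(pickHi, lo + 1L, ifelse(okLo, lo, NA_integer_))
  matched <- which(!is.na(pick))
  if (!length(matched)) {
    out <- rbind(empty, repRows)
    rownames(out) <- NULL
    return(out)
  }
  pk <- pick[matched]
  out <- data.frame(
    peak_idx = fragIdx[pk], peak_mz = pmz[pk],
    peak_intensity = ints[fragIdx][pk], is_reporter = FALSE,
    proteoform = ions$proteoform[matched], variant = ions$variant[matched],
    series = ions$series[matched], index = ions$index[matched],
    charge = ions$charge[matched], loss = ions$loss[matched],
    mz_theo = ions$mz[matched],
    ppm = ppmError(pmz[pk], ions$mz[matched])
  )
  out <- rbind(out[order(out$peak_idx), ], repRows)
  rownames(out) <- NULL
  out
}

#' Confirm annotations by heavy-isotope peaks
#'
#' An annotated fragment peak is high confidence when the spectrum contains
#' a peak at the expected A+1 isotopologue position, i.e. the annotated m/z
#' plus an accepted heavy-isotope spacing (13C by default; the 15N spacing
#' is also accepted) divided by the matched ion's charge, within the
#' fragment ppm tolerance. Reporter peaks are never eligible.
#'
#' @param spectrum The [MsSpectrum-class] the annotations came from.
#' @param annotations Output of [matchPeaks()].
#' @param config A [RunConfig-class].
#' @return `annotations` with a logical `isotope_confirmed` column
#'   (constant within a peak; FALSE for reporter rows).
#' @export
confirmHeavyIsotope <- function(spectrum, annotations,
                                config = runConfig()) {
  mzs <- spectrum@mz
  tol <- config@fragmentTolPpm
  confirmed <- rep(FALSE, nrow(annotations))
  frag <- which(!annotations$is_reporter)
  if (length(frag)) {
    ## one lookup per distinct (peak m/z, charge, spacing)
    combos <- unique(data.frame(mz = annotations$peak_mz[frag],
                                charge = annotations$charge[frag]))
    hit <- logical(nrow(combos))
    for (sp in config@isotopeSpacings) {
      expect <- combos$mz + sp / combos$charge
      near <- findInterval(expect, mzs)
      dLo <- ifelse(near >= 1L,
                    abs(ppmError(mzs[pmax(near, 1L)], expect)), Inf)
      dHi <- ifelse(near < length(mzs),
                    abs(ppmError(mzs[pmin(near + 1L, length(mzs))], expect)),
                    Inf)
      hit <- hit | pmin(dLo, dHi) <= tol
    }
    key <- paste(annotations$peak_mz[frag], annotations$charge[frag])
    confirmed[frag] <- hit[match(key, paste(combos$mz, combos$charge))]
  }
  annotations$isotope_confirmed <- confirmed
  annotations
}

#' Attribute annotated peaks to proteoforms
#'
#' Classifies each annotated fragment peak as `unique` (every matched ion
#' belongs to one candidate proteoform) or `shared` (ions of several
#' candidates fall on the peak, as happens for fragments N-terminal or
#' C-terminal of all differing placements in co-isolated positional
#' isomers).
#'
#' @param annotations Output of [matchPeaks()] (optionally confirmed).
#' @return `annotations` with `attribution` (`"unique"`/`"shared"`) and
#'   `n_proteoforms` columns; NA for reporter rows.
#' @export
attributeAnnotations <- function(annotations) {
  annotations$attribution <- NA_character_
  annotations$n_proteoforms <- NA_integer_
  frag <- which(!annotations$is_reporter)
  if (length(frag)) {
    pf <- paste(annotations$variant[frag], annotations$proteoform[frag])
    nPf <- vapply(split(pf, annotations$peak_idx[frag]),
                  function(x) length(unique(x)), integer(1))
    n <- nPf[as.character(annotations$peak_idx[frag])]
    annotations$n_proteoforms[frag] <- unname(n)
    annotations$attribution[frag] <- ifelse(n == 1L, "unique", "shared")
  }
  annotations
}

#' Annotate one scan end to end
#'
#' Convenience composition of [generateIonSets()], [matchPeaks()],
#' [confirmHeavyIsotope()] and [attributeAnnotations()].
#'
#' @param spectrum An [MsSpectrum-class].
#' @param psmsForScan Kept PSM rows of this scan.
#' @param config A [RunConfig-class].
#' @param ions Optional precomputed ion table (cache for repeated
#'   proteoforms).
#' @return Fully annotated `data.frame`.
#' @export
annotateScan <- function(spectrum, psmsForScan, config = runConfig(),
                         ions = NULL) {
  if (is.null(ions))
    ions <- generateIonSets(psmsForScan, config, spectrum@precursorCharge)
  ann <- matchPeaks(spectrum, ions, config)
  ann <- confirmHeavyIsotope(spectrum, ann, config)
  attributeAnnotations(ann)
}
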