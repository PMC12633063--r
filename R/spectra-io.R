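#' Construct an MsSpectrum
#'
#' @param scanId Scan identifier (opaque string; joins to PSM tables are
#'   exact-match).
#' @param precursorMz,precursorCharge Precursor descriptors.
#' @param mz,intensity Parallel peak vectors. Unsorted peaks are sorted with
#'   a warning.
#' @return An [MsSpectrum-class].
#' @export
msSpectrum <- function(scanId, precursorMz, precursorCharge, mz, intensity) {
  if (length(mz) && is.unsorted(mz, strictly = TRUE)) {
    warning("peaks of scan ", scanId, " not sorted by m/z; sorting")
    o <- order(mz)
    mz <- mz[o]; intensity <- intensity[o]
  }
  new("MsSpectrum", scanId = as.character(scanId),
      precursorMz = as.numeric(precursorMz),
      precursorCharge = as.integer(precursorCharge),
      mz = as.numeric(mz), intensity = as.numeric(intensity))
}

#' @describeIn msSpectrum Peak table of a spectrum.
#' @param x An `MsSpectrum`.
#' @export
peaksOf <- function(x) data.frame(mz = x@mz, intensity = x@intensity)

#' @describeIn msSpectrum Scan identifier.
#' @export
scanId <- function(x) x@scanId

#' Construct a SpectrumSet
#' @param spectra List of [MsSpectrum-class] objects.
#' @return A [SpectrumSet-class] named by scan id.
#' @export
spectrumSet <- function(spectra = list()) {
  ids <- vapply(spectra, scanId, character(1))
  if (anyDuplicated(ids))
    stop("duplicate scan ids in spectrum set")
  new("SpectrumSet", S4Vectors::SimpleList(setNames(spectra, ids)))
}

#' @describeIn spectrumSet Scan ids of a set.
#' @param x A `SpectrumSet`.
#' @export
scanIds <- function(x) names(x)

setMethod("show", "MsSpectrum", function(object) {
  cat(sprintf("MsSpectrum %s: %d peaks, precursor %.4f m/z (%d+)\n",
              object@scanId, length(object@mz), object@precursorMz,
              object@precursorCharge))
})

setMethod("show", "SpectrumSet", function(object) {
  cat("SpectrumSet of", length(object), "MS2 spectra\n")
})

## ---- peak-list TSV dialect --------------------------------------------
## A plain-text centroid format so tests and the simulator need no XML:
##   # midtail peaklist v1
##   >scan_id<TAB>precursor_mz<TAB>precursor_charge
##   mz<TAB>intensity          (one row per peak)
## Scan header lines start with '>'; comment lines with '#'.

#' Read MS2 spectra
#'
#' Reads centroided MS2 spectra either from the package's plain peak-list
#' TSV dialect (scan header lines starting with `>` carrying
#' `scan_id<TAB>precursor_mz<TAB>precursor_charge`, followed by
#' `mz<TAB>intensity` rows) or from mzML via the `mzR` package.
#'
#' @param path Input file.
#' @param format `"peaklist"` or `"mzml"` (default guessed from extension).
#' @return A [SpectrumSet-class].
#' @export
readSpectra <- function(path, format = c("auto", "peaklist", "mzml")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzml"
              else "peaklist"
  switch(format,
         peaklist = .readPeakList(path),
         mzml = .readMzml(path))
}

.readPeakList <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    warning("no spectra in ", path)
    return(spectrumSet())
  }
  isHeader <- startsWith(lines, ">")
  if (!isHeader[1L])
    stop("malformed peak list: first record line is not a scan header")
  block <- cumsum(isHeader)
  spectra <- lapply(split(lines, block), function(chunk) {
    hdr <- strsplit(substring(chunk[1L], 2L), "\t", fixed = TRUE)[[1]]
    if (length(hdr) != 3L)
      stop("malformed scan header: ", chunk[1L])
    if (length(chunk) > 1L) {
      parts <- strsplit(chunk[-1L], "\t", fixed = TRUE)
      bad <- vapply(parts, length, integer(1)) != 2L
      if (any(bad))
        stop("malformed peak row(s) in scan ", hdr[1L])
      mz <- as.numeric(vapply(parts, `[[`, character(1), 1L))
      intensity <- as.numeric(vapply(parts, `[[`, character(1), 2L))
      if (anyNA(mz) || anyNA(intensity))
        stop("non-numeric peak in scan ", hdr[1L])
    } else {
      mz <- numeric(); intensity <- numeric()
    }
    msSpectrum(hdr[1L], as.numeric(hdr[2L]), as.integer(hdr[3L]),
               mz, intensity)
  })
  spectrumSet(unname(spectra))
}

.readMzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("reading mzML requires the 'mzR' package")
  ms <- mzR::openMSfile(path)
  on.exit(mzR::close(ms))
  hdr <- mzR::header(ms)
  keep <- which(hdr$msLevel == 2L)
  spectra <- lapply(keep, function(i) {
    pk <- mzR::peaks(ms, i)
    msSpectrum(as.character(hdr$acquisitionNum[i]),
               hdr$precursorMZ[i], as.integer(hdr$precursorCharge[i]),
               pk[, 1L], pk[, 2L])
  })
  spectrumSet(spectra)
}

#' Write spectra as a peak-list TSV
#'
#' @param spectra A [SpectrumSet-class].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writePeakList <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# midtail peaklist v1", con)
  for (sp in as.list(spectra)) {
    writeLines(sprintf(">%s\t%.6f\t%d", sp@scanId, sp@precursorMz,
                       sp@precursorCharge), con)
    if (length(sp@mz))
      writeLines(sprintf("%.6f\t%.6f", sp@mz, sp@intensity), con)
  }
  invisible(path)
}

#' Write a proteoform quantification table
#'
#' Serializes group-level results (one row per proteoform per contrast) as a
#' TSV with deterministic, key-sorted row order.
#'
#' @param results `data.frame` as returned by [groupAndTest()] /
#'   [runPipeline()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeQuantTable <- function(results, path) {
  cols <- c("proteoform", "variant", "contrast", "n_scans", "n_scans_used",
            "mean_log2_a", "mean_log2_b", "log2fc", "p_value", "n_a", "n_b",
            "testable", "coverage_pass")
  if (is.null(results) || !nrow(results)) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(cols)),
                                  cols))
  } else {
    out <- results[order(results$proteoform, results$variant,
                         results$contrast), cols, drop = FALSE]
  }
  dbl <- c("mean_log2_a", "mean_log2_b", "log2fc", "p_value")
  out[dbl] <- lapply(out[dbl], function(x)
    ifelse(is.na(x), "NA", sprintf("%.6f", x)))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
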