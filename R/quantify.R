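#' Per-spectrum proteoform abundance fractions
#'
#' Computes each candidate proteoform's share of a scan's confirmed,
#' annotated fragment-ion intensity. Intensity of peaks whose ions are
#' unique to one proteoform is credited in full; intensity of shared peaks
#' (chimeric spectra of co-isolated isomers) is divided equally among the
#' proteoforms whose ion sets contain the peak. Fractions are each
#' proteoform's credit over the summed credit, so they sum to 1 and total
#' credited intensity equals total confirmed annotated fragment intensity.
#'
#' Only isotope-confirmed, non-reporter annotations contribute. A scan with
#' zero confirmed annotated intensity is flagged unquantifiable
#' (`quantifiable = FALSE`, fractions NA) and is excluded downstream.
#'
#' @param annotations Fully annotated scan table from [annotateScan()].
#' @param psmsForScan Kept PSM rows of this scan (defines the candidate
#'   proteoform set; candidates without any confirmed intensity keep
#'   fraction 0).
#' @return A list with elements `scan_id`-free scan quant: `fractions`
#'   (named numeric over `variant|key`), `credits`, `total_intensity`,
#'   `n_psms`, `quantifiable`.
#' @export
spectrumAbundance <- function(annotations, psmsForScan) {
  cand <- unique(paste(psmsForScan$variant, psmsForScan$key, sep = "|"))
  credits <- setNames(numeric(length(cand)), cand)
  use <- !annotations$is_reporter & annotations$isotope_confirmed
  total <- 0
  if (any(use)) {
    ann <- annotations[use, , drop = FALSE]
    ann$pf <- paste(ann$variant, ann$proteoform, sep = "|")
    perPeak <- split(ann, ann$peak_idx)
    for (pk in perPeak) {
      pfs <- unique(pk$pf)
      pfs <- intersect(pfs, cand)
      if (!length(pfs)) next
      intensity <- pk$peak_intensity[1L]
      total <- total + intensity
      credits[pfs] <- credits[pfs] + intensity / length(pfs)
    }
  }
  quantifiable <- total > 0
  fractions <- if (quantifiable) credits / sum(credits)
               else setNames(rep(NA_real_, length(cand)), cand)
  list(fractions = fractions, credits = credits, total_intensity = total,
       n_psms = nrow(psmsForScan), quantifiable = quantifiable)
}
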