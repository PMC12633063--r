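## Lightweight polynomial checksum over a serialized object, for run
## manifests (fingerprinting only, not cryptographic).
.objectHash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  ## Horner scheme mod a prime below 2^26 keeps products inside exact
  ## double-precision integer range.
  h <- 0
  for (b in bytes)
    h <- (h * 31 + b) %% 67108859
  sprintf("%07x", h)
}

#' Run the full quantification pipeline
#'
#' Composes the pipeline stages on a spectrum set and PSM table:
#' confidence-filter PSMs, subdivide scans by kept-PSM count (dropping
#' scans above the candidate cap), annotate each scan's peaks against its
#' candidate proteoforms with heavy-isotope confirmation, apportion
#' fragment intensity into per-scan proteoform fractions, extract and
#' channel-normalize TMT reporters over all PSM-bearing scans, apply the
#' per-condition coverage filter, and group scans by proteoform to report
#' log2 fold changes with two-sided Welch t-tests. Deterministic given
#' inputs and config.
#'
#' @param spectra A [SpectrumSet-class].
#' @param psms PSM `data.frame` (see [readPsmTable()]).
#' @param config A [RunConfig-class].
#' @param contrasts Optional list of condition pairs (see [groupAndTest()]).
#' @return A list:
#'   * `results`: group-level `data.frame` from [groupAndTest()];
#'   * `scans`: per-scan quant table (`scan_id`, `proteoform`, `variant`,
#'     `fraction`, `credited`, `total_intensity`, `n_psms`,
#'     `quantifiable`);
#'   * `reporters`: the normalized [ReporterMatrix-class] (NULL when no
#'     scan survived filtering);
#'   * `manifest`: machine-readable run manifest (counts per stage, config
#'     hash, seed, package version).
#' @export
runPipeline <- function(spectra, psms, config = runConfig(),
                        contrasts = NULL) {
  flt <- filterPsms(psms, config)
  kept <- flt$kept
  kept <- kept[kept$scan_id %in% scanIds(spectra), , drop = FALSE]
  byCount <- subdivideByPsmCount(kept)
  over <- as.integer(names(byCount)) > config@maxPsmsPerScan
  if (any(over)) {
    dropScans <- unlist(byCount[over], use.names = FALSE)
    warning(length(dropScans), " scan(s) exceed ", config@maxPsmsPerScan,
            " candidate PSMs and were excluded")
    kept <- kept[!kept$scan_id %in% dropScans, , drop = FALSE]
    byCount <- byCount[!over]
  }
  scans <- unique(kept$scan_id)
  ## annotate + apportion per scan, caching ion tables per proteoform
  ionCache <- new.env(parent = emptyenv())
  scanRows <- vector("list", length(scans))
  for (i in seq_along(scans)) {
    s <- scans[i]
    sub <- kept[kept$scan_id == s, , drop = FALSE]
    cand <- unique(sub[, c("variant", "key")])
    ions <- do.call(rbind, lapply(seq_len(nrow(cand)), function(j) {
      ck <- paste(cand$variant[j], cand$key[j],
                  spectra[[s]]@precursorCharge)
      if (is.null(ionCache[[ck]]))
        ionCache[[ck]] <- generateIonSets(cand[j, , drop = FALSE], config,
                                          spectra[[s]]@precursorCharge)
      ionCache[[ck]]
    }))
    ann <- annotateScan(spectra[[s]], sub, config, ions = ions)
    q <- spectrumAbundance(ann, sub)
    pfs <- names(q$fractions)
    scanRows[[i]] <- data.frame(
      scan_id = s,
      variant = sub("\\|.*$", "", pfs),
      proteoform = sub("^[^|]*\\|", "", pfs),
      fraction = unname(q$fractions),
      credited = unname(q$credits),
      total_intensity = q$total_intensity,
      n_psms = q$n_psms,
      quantifiable = q$quantifiable
    )
  }
  scanQuant <- do.call(rbind, scanRows)
  if (is.null(scanQuant))
    scanQuant <- data.frame(scan_id = character(), variant = character(),
                            proteoform = character(), fraction = numeric(),
                            credited = numeric(),
                            total_intensity = numeric(),
                            n_psms = integer(), quantifiable = logical())
  quantScans <- unique(scanQuant$scan_id[scanQuant$quantifiable])
  rm <- NULL
  results <- data.frame(
    proteoform = character(), variant = character(), contrast = character(),
    n_scans = integer(), n_scans_used = integer(), mean_log2_a = numeric(),
    mean_log2_b = numeric(), log2fc = numeric(), p_value = numeric(),
    n_a = integer(), n_b = integer(), testable = logical(),
    coverage_pass = logical())
  nCovered <- 0L
  if (length(quantScans)) {
    rm <- reporterMatrix(spectra, quantScans, config)
    rm <- channelNormalize(rm)
    raw <- SummarizedExperiment::assay(rm, "raw")
    covPass <- vapply(rownames(raw),
                      function(s) coverageFilter(raw[s, ], config),
                      logical(1))
    SummarizedExperiment::rowData(rm)$coverage_pass <- covPass
    nCovered <- sum(covPass)
    groupsTab <- scanQuant[scanQuant$quantifiable,
                           c("scan_id", "variant", "proteoform",
                             "fraction")]
    names(groupsTab)[3L] <- "key"
    results <- groupAndTest(rm, groupsTab, contrasts, config)
  }
  manifest <- list(
    package = "midtail",
    version = as.character(utils::packageVersion("midtail")),
    config_hash = .objectHash(config),
    seed = config@seed,
    counts = list(
      spectra = length(spectra),
      psms_in = nrow(psms),
      psms_kept = nrow(kept),
      psms_rejected = nrow(psms) - nrow(kept),
      scans_with_kept_psm = length(scans),
      scans_quantifiable = length(quantScans),
      scans_coverage_pass = nCovered,
      groups_tested = if (nrow(results)) sum(results$testable) else 0L,
      groups_reported = if (nrow(results))
        length(unique(paste(results$variant, results$proteoform))) else 0L
    )
  )
  list(results = results, scans = scanQuant, reporters = rm,
       manifest = manifest)
}
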