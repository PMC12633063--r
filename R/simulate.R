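#' Design of a synthetic middle-down experiment
#'
#' Bundles the ground-truth structure of a simulated run: the proteoform
#' panel and abundances, per-condition linear fold changes, scan count and
#' co-isolation behaviour, fragment and reporter noise models and the RNG
#' seed. The generator emulates the acquisition the pipeline targets:
#' 8+ precursors in the 480-540 m/z selection window, c/z-dominant EThcD
#' fragments with isotope envelopes, up to 5 co-isolated positional isomers
#' per scan, and TMT 6-plex reporters mixed 1:1:1:1:1:1 before condition
#' fold changes.
#'
#' @param proteoforms List of [Proteoform-class] objects (the panel).
#' @param nScans Number of MS2 scans to emit.
#' @param config A [RunConfig-class] (channel/condition layout).
#' @param abundance Sampling weights over the panel.
#' @param foldChange Numeric matrix, proteoforms x conditions, of linear
#'   reporter fold changes (default all 1). Rows follow the panel order,
#'   columns the configured conditions.
#' @param chimeraProb Probability that a scan co-isolates several isobaric
#'   panel members.
#' @param maxCoisolates Cap on co-isolated proteoforms per scan (<= 5).
#' @param mixture Fixed mixing fractions for chimeric scans (default drawn
#'   from a flat Dirichlet).
#' @param scanAssignment Optional list, one integer vector of panel indices
#'   per scan, overriding random proteoform sampling.
#' @param seriesWeights Relative base intensity per ion series; EThcD
#'   spectra are c/z dominant.
#' @param fragmentCharges Fragment charges emitted.
#' @param fragBaseSdlog Log-normal spread of per-ion base intensities
#'   (0 = deterministic bases).
#' @param intensityCv Multiplicative coefficient of variation applied per
#'   emitted fragment peak.
#' @param dropoutRate Probability that an individual fragment ion is not
#'   observed.
#' @param uniqueOnly In chimeric scans, emit only ions unique to each
#'   co-isolate (isolates the intensity-apportionment estimator from the
#'   structural bias of equal shared-ion splitting).
#' @param isotopePeaks Isotopologue peaks emitted per fragment (>= 2 makes
#'   every fragment heavy-isotope confirmable).
#' @param chaffPeaks Expected number of uniform random noise peaks per scan.
#' @param reporterBase Base reporter intensity per channel.
#' @param reporterSdlog Log-normal sigma of reporter noise (natural log).
#' @param reporterDropout Probability a reporter ion is missing.
#' @param decoyRate Probability a scan gains a decoy PSM row that fails the
#'   confidence filters.
#' @param seed Integer seed fixing all randomness.
#' @return A validated `simulationDesign` list.
#' @export
simulationDesign <- function(proteoforms, nScans, config = runConfig(),
                             abundance = NULL, foldChange = NULL,
                             chimeraProb = 0, maxCoisolates = 2L,
                             mixture = NULL, scanAssignment = NULL,
                             seriesWeights = c(a = 0.2, b = 0.2, c = 1,
                                               y = 0.3, z = 1),
                             fragmentCharges = 1:2,
                             fragBaseSdlog = 0.3, intensityCv = 0.2,
                             dropoutRate = 0.05, uniqueOnly = FALSE,
                             isotopePeaks = 2L, chaffPeaks = 5,
                             reporterBase = 1e5, reporterSdlog = 0.3,
                             reporterDropout = 0, decoyRate = 0,
                             seed = 1L) {
  nP <- length(proteoforms)
  stopifnot(nP >= 1L, nScans >= 1L)
  if (is.null(abundance)) abundance <- rep(1, nP)
  if (any(abundance <= 0)) stop("abundances must be > 0")
  conds <- configConditions(config)
  if (is.null(foldChange))
    foldChange <- matrix(1, nP, length(conds),
                         dimnames = list(NULL, conds))
  if (!all(conds %in% colnames(foldChange)))
    stop("foldChange must have one column per condition")
  if (chimeraProb < 0 || chimeraProb > 1)
    stop("chimeraProb must be in [0, 1]")
  if (maxCoisolates > 5L)
    stop("maxCoisolates must be <= 5 (acquisition cap)")
  if (!is.null(scanAssignment) && length(scanAssignment) != nScans)
    stop("scanAssignment must have one entry per scan")
  structure(list(
    proteoforms = proteoforms, nScans = as.integer(nScans), config = config,
    abundance = abundance, foldChange = foldChange,
    chimeraProb = chimeraProb, maxCoisolates = as.integer(maxCoisolates),
    mixture = mixture, scanAssignment = scanAssignment,
    seriesWeights = seriesWeights, fragmentCharges = fragmentCharges,
    fragBaseSdlog = fragBaseSdlog, intensityCv = intensityCv,
    dropoutRate = dropoutRate, uniqueOnly = uniqueOnly,
    isotopePeaks = as.integer(isotopePeaks), chaffPeaks = chaffPeaks,
    reporterBase = reporterBase, reporterSdlog = reporterSdlog,
    reporterDropout = reporterDropout, decoyRate = decoyRate,
    seed = as.integer(seed)
  ), class = "simulationDesign")
}

## Precompute emission data for one panel member: ion table of the emitted
## series/charges with per-ion base weight and A+1 intensity ratio.
.pfEmissionData <- function(p, design) {
  w <- design$seriesWeights[design$seriesWeights > 0]
  tab <- fragmentIonTable(p, series = names(w),
                          charges = design$fragmentCharges)
  tab$weight <- unname(w[tab$series])
  nC <- .fragmentCarbons(p)
  tab$nC <- ifelse(tab$series %in% c("a", "b", "c"),
                   nC$nterm[tab$index],
                   nC$cterm[nchar(h3TailSequence(variantOf(p))) -
                            tab$index + 1L])
  list(p = p, key = proteoformKey(p), variant = variantOf(p),
       ions = tab, premz = precursorMz(p, 8L))
}

#' Simulate a ground-truth middle-down experiment
#'
#' Emits centroided MS2 spectra, a PSM table and a ground-truth record for
#' a [simulationDesign()]. Fragment peaks are the c/z-dominant theoretical
#' ion sets of each scan's true proteoform(s), scaled by mixing fraction
#' and the noise model and accompanied by binomial-carbon isotope
#' envelopes; reporter ions appear at the configured channel m/z with
#' intensity base x condition fold change x log-normal noise; PSM rows
#' carry passing confidence scores for true proteoforms plus optional decoy
#' rows that fail the filters. Fully deterministic under the design seed.
#'
#' @param design A [simulationDesign()].
#' @return `list(spectra = SpectrumSet, psms = data.frame, truth = list)`;
#'   `truth$scans` joins scan ids to true proteoforms and mixing fractions,
#'   `truth$proteoforms` records the designed log2 fold change per contrast.
#' @export
simulateExperiment <- function(design) {
  stopifnot(inherits(design, "simulationDesign"))
  set.seed(design$seed)
  config <- design$config
  nP <- length(design$proteoforms)
  pf <- lapply(design$proteoforms, .pfEmissionData, design = design)
  premzs <- vapply(pf, `[[`, numeric(1), "premz")
  outside <- premzs < 480 | premzs > 540
  if (any(outside))
    warning(sum(outside), " panel proteoform(s) fall outside the 480-540 ",
            "m/z selection window at charge 8; emitted anyway")
  ch <- config@channels
  cvSdlog <- if (design$intensityCv > 0)
    sqrt(log(1 + design$intensityCv^2)) else 0
  spectra <- vector("list", design$nScans)
  psmRows <- list(); truthRows <- list()
  for (s in seq_len(design$nScans)) {
    scan <- sprintf("scan%05d", s)
    ## which proteoforms are co-isolated
    if (!is.null(design$scanAssignment)) {
      idx <- design$scanAssignment[[s]]
    } else {
      k <- 1L
      if (design$chimeraProb > 0 && nP > 1L &&
          stats::runif(1) < design$chimeraProb)
        k <- sample(2:min(design$maxCoisolates, nP), 1L)
      idx <- sample.int(nP, k, prob = design$abundance)
    }
    k <- length(idx)
    frac <- if (k == 1L) 1
            else if (!is.null(design$mixture)) design$mixture[seq_len(k)] /
                   sum(design$mixture[seq_len(k)])
            else { g <- stats::rgamma(k, 1); g / sum(g) }
    ## fragment peaks
    mzAll <- numeric(); intAll <- numeric()
    for (j in seq_len(k)) {
      tab <- pf[[idx[j]]]$ions
      if (design$uniqueOnly && k > 1L) {
        others <- sort(unlist(lapply(idx[-j],
                                     function(i) pf[[i]]$ions$mz)))
        near <- findInterval(tab$mz, others)
        dLo <- ifelse(near >= 1L,
                      abs(tab$mz - others[pmax(near, 1L)]), Inf)
        dHi <- ifelse(near < length(others),
                      abs(others[pmin(near + 1L, length(others))] - tab$mz),
                      Inf)
        sep <- pmin(dLo, dHi) / tab$mz * 1e6
        tab <- tab[sep > 2 * config@fragmentTolPpm, , drop = FALSE]
      }
      n <- nrow(tab)
      if (!n) next
      base <- tab$weight * 1000
      if (design$fragBaseSdlog > 0)
        base <- base * stats::rlnorm(n, 0, design$fragBaseSdlog)
      intensity <- base * frac[j]
      if (cvSdlog > 0)
        intensity <- intensity * stats::rlnorm(n, 0, cvSdlog)
      if (design$dropoutRate > 0)
        intensity <- intensity *
          stats::rbinom(n, 1L, 1 - design$dropoutRate)
      keep <- intensity > 0
      if (!any(keep)) next
      tab <- tab[keep, , drop = FALSE]
      intensity <- intensity[keep]
      ## isotope envelope per fragment (binomial carbon model)
      for (iso in seq_len(design$isotopePeaks) - 1L) {
        ratio <- stats::dbinom(iso, tab$nC, .C13_ABUNDANCE) /
                 stats::dbinom(0L, tab$nC, .C13_ABUNDANCE)
        mzAll <- c(mzAll, tab$mz + iso * .C13_SPACING / tab$charge)
        intAll <- c(intAll, intensity * ratio)
      }
    }
    ## reporter ions
    condFc <- vapply(seq_len(nrow(ch)), function(i) {
      sum(frac * design$foldChange[idx, ch$condition[i]])
    }, numeric(1))
    repInt <- design$reporterBase * condFc
    if (design$reporterSdlog > 0)
      repInt <- repInt * stats::rlnorm(nrow(ch), 0, design$reporterSdlog)
    if (design$reporterDropout > 0)
      repInt <- repInt * stats::rbinom(nrow(ch), 1L,
                                       1 - design$reporterDropout)
    keepRep <- repInt > 0
    mzAll <- c(mzAll, ch$mz[keepRep])
    intAll <- c(intAll, repInt[keepRep])
    ## uniform chaff
    if (design$chaffPeaks > 0) {
      nChaff <- stats::rpois(1L, design$chaffPeaks)
      if (nChaff > 0) {
        mzAll <- c(mzAll, stats::runif(nChaff, 135, 1500))
        intAll <- c(intAll, stats::rlnorm(nChaff, log(50), 0.5))
      }
    }
    ## merge coincident peaks (shared isomer ions collapse to one centroid)
    mzr <- round(mzAll, 5L)
    agg <- rowsum(intAll, mzr)
    mzs <- as.numeric(rownames(agg))
    o <- order(mzs)
    spectra[[s]] <- msSpectrum(scan, pf[[idx[1L]]]$premz, 8L,
                               mzs[o], agg[o, 1L])
    ## PSM rows (true, then possibly a decoy failing the filters)
    for (j in seq_len(k)) {
      psmRows[[length(psmRows) + 1L]] <- data.frame(
        scan_id = scan, variant = pf[[idx[j]]]$variant,
        key = pf[[idx[j]]]$key,
        pep = stats::runif(1, 0, 0.05),
        delta_mod_score = stats::runif(1, 10, 40)
      )
      truthRows[[length(truthRows) + 1L]] <- data.frame(
        scan_id = scan, proteoform = pf[[idx[j]]]$key,
        variant = pf[[idx[j]]]$variant, fraction = frac[j]
      )
    }
    if (design$decoyRate > 0 && stats::runif(1) < design$decoyRate) {
      d <- sample.int(nP, 1L)
      failPep <- stats::runif(1) < 0.5
      psmRows[[length(psmRows) + 1L]] <- data.frame(
        scan_id = scan, variant = pf[[d]]$variant, key = pf[[d]]$key,
        pep = if (failPep) stats::runif(1, 0.0501, 0.4)
              else stats::runif(1, 0, 0.05),
        delta_mod_score = if (failPep) stats::runif(1, 10, 40)
                          else stats::runif(1, 0, 9.9)
      )
    }
  }
  psms <- do.call(rbind, psmRows)
  rownames(psms) <- NULL
  conds <- configConditions(config)
  contrasts <- lapply(setdiff(conds, conds[1L]),
                      function(x) c(x, conds[1L]))
  pfTruth <- do.call(rbind, lapply(contrasts, function(ct) {
    data.frame(
      proteoform = vapply(pf, `[[`, character(1), "key"),
      variant = vapply(pf, `[[`, character(1), "variant"),
      contrast = paste(ct[1L], "vs", ct[2L], sep = "_"),
      true_log2fc = log2(design$foldChange[, ct[1L]] /
                         design$foldChange[, ct[2L]])
    )
  }))
  list(spectra = spectrumSet(spectra), psms = psms,
       truth = list(scans = do.call(rbind, truthRows),
                    proteoforms = pfTruth),
       design = design)
}

#' Bundled reproducible fixtures
#'
#' Named, fully specified simulation designs used across the test suite and
#' documentation:
#'
#' * `"isomer-pair"`: 20 chimeric scans of the positional isomers H3K9me1
#'   and H3K14me1 co-isolated at a fixed 0.7/0.3 mixture, noise-free, c/z
#'   ions at charge 1, unique ions only (seed 1).
#' * `"isomer-pair-noisy"`: the same pair over 200 scans with fragment
#'   dropout 0.1 and intensity CV 0.2 (seed 1).
#' * `"null-experiment"`: 200 random proteoform groups, 5 scans each, no
#'   true fold change, reporter log-normal sigma 0.3 (seed 2).
#' * `"grid-recovery"`: true log2 fold changes on the grid
#'   \{-2, -1, 0, 1, 2\}, six proteoform groups per grid value plus 90 null
#'   groups, 10 scans per group, reporter sigma 0.3, fold changes split
#'   symmetrically across the two conditions (seed 3).
#'
#' @param name Fixture name.
#' @param seed Optional seed overriding the fixture default.
#' @return The simulated experiment (see [simulateExperiment()]).
#' @export
makeFixture <- function(name, seed = NULL) {
  czOnly <- c(a = 0, b = 0, c = 1, y = 0, z = 1)
  isomerPair <- list(proteoform("H3.1", 9L, "me1"),
                     proteoform("H3.1", 14L, "me1"))
  design <- switch(name,
    "isomer-pair" = simulationDesign(
      isomerPair, nScans = 20L, chimeraProb = 1, maxCoisolates = 2L,
      mixture = c(0.7, 0.3),
      scanAssignment = rep(list(1:2), 20L),
      seriesWeights = czOnly, fragmentCharges = 1L,
      fragBaseSdlog = 0, intensityCv = 0, dropoutRate = 0,
      uniqueOnly = TRUE, chaffPeaks = 0, reporterSdlog = 0,
      seed = seed %||% 1L),
    "isomer-pair-noisy" = simulationDesign(
      isomerPair, nScans = 200L, chimeraProb = 1, maxCoisolates = 2L,
      mixture = c(0.7, 0.3),
      scanAssignment = rep(list(1:2), 200L),
      seriesWeights = czOnly, fragmentCharges = 1L,
      fragBaseSdlog = 0, intensityCv = 0.2, dropoutRate = 0.1,
      uniqueOnly = TRUE, chaffPeaks = 0, reporterSdlog = 0,
      seed = seed %||% 1L),
    "null-experiment" = {
      s <- seed %||% 2L
      set.seed(s)
      panel <- randomProteoforms(200L)
      simulationDesign(
        panel, nScans = 1000L,
        scanAssignment = as.list(rep(seq_along(panel), each = 5L)),
        seriesWeights = czOnly, fragmentCharges = 1L,
        fragBaseSdlog = 0.3, intensityCv = 0.2, dropoutRate = 0.05,
        chaffPeaks = 0, reporterSdlog = 0.3, seed = s)
    },
    "grid-recovery" = {
      s <- seed %||% 3L
      set.seed(s)
      panel <- randomProteoforms(120L)
      grid <- rep(c(-2, -1, 0, 1, 2), each = 6L)
      l2fc <- c(grid, rep(0, 90L))
      fc <- cbind(A = 2^(-l2fc / 2), B = 2^(l2fc / 2))
      simulationDesign(
        panel, nScans = 1200L, foldChange = fc,
        scanAssignment = as.list(rep(seq_along(panel), each = 10L)),
        seriesWeights = czOnly, fragmentCharges = 1L,
        fragBaseSdlog = 0.3, intensityCv = 0.2, dropoutRate = 0.05,
        chaffPeaks = 0, reporterSdlog = 0.3, seed = s)
    },
    stop("unknown fixture name: ", name)
  )
  simulateExperiment(design)
}
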