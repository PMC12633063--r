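# Independent brute-force mass oracle.
#
# Uses a second residue-mass table of literal published monoisotopic values
# (not the package's composition-derived table) and plain summation, so
# agreement with the package is a genuine dual-route check.

ORACLE_RESIDUE <- c(
  G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
  V = 99.068414, T = 101.047679, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)

ORACLE_MOD_DELTA <- c(
  me1 = 14.015650, me2 = 28.031300, me3 = 42.046950,
  ac = 42.010565, ph = 79.966331, pr = 56.026215
)

ORACLE_WATER  <- 18.010565
ORACLE_PROTON <- 1.007276
ORACLE_NH3    <- 17.026549
ORACLE_CO     <- 27.994915
ORACLE_HATOM  <- 1.007825
ORACLE_TMT    <- 229.162932
ORACLE_CTERM  <- 76.1001

# Per-position residue masses (literal table + fixed mods + placements).
oracleResidueMasses <- function(p) {
  seqchars <- strsplit(h3TailSequence(variantOf(p)), "")[[1]]
  m <- unname(ORACLE_RESIDUE[seqchars])
  m[seqchars == "H"] <- m[seqchars == "H"] + ORACLE_TMT
  m[length(m)] <- m[length(m)] + ORACLE_CTERM
  pos <- placementPositions(p)
  if (length(pos))
    m[pos] <- m[pos] + unname(ORACLE_MOD_DELTA[placementMods(p)])
  m
}

oracleProteoformMass <- function(p) {
  sum(oracleResidueMasses(p)) + ORACLE_WATER
}

oracleFragmentMz <- function(p, series, index, charge = 1L) {
  m <- oracleResidueMasses(p)
  n <- length(m)
  neutral <- switch(series,
    a = sum(m[seq_len(index)]) - ORACLE_CO,
    b = sum(m[seq_len(index)]),
    c = sum(m[seq_len(index)]) + ORACLE_NH3,
    y = sum(m[seq(n - index + 1L, n)]) + ORACLE_WATER,
    z = sum(m[seq(n - index + 1L, n)]) + ORACLE_WATER - ORACLE_NH3 +
        ORACLE_HATOM
  )
  (neutral + charge * ORACLE_PROTON) / charge
}

# Draw reproducible random proteoforms without touching the global seed
# state of the calling test.
drawProteoforms <- function(n, seed) {
  withr::with_seed(seed, randomProteoforms(n))
}

# Minimal hand-built annotation table for spectrumAbundance tests.
makeAnnotations <- function(peakIntensity, proteoformsPerPeak,
                            confirmed = TRUE) {
  confirmed <- rep_len(confirmed, length(peakIntensity))
  rows <- lapply(seq_along(peakIntensity), function(i) {
    pfs <- proteoformsPerPeak[[i]]
    data.frame(
      peak_idx = i, peak_mz = 200 + i, peak_intensity = peakIntensity[i],
      is_reporter = FALSE, proteoform = pfs, variant = "H3.1",
      series = "c", index = seq_along(pfs), charge = 1L, loss = "none",
      mz_theo = 200 + i, ppm = 0,
      isotope_confirmed = confirmed[i]
    )
  })
  attributeAnnotations(do.call(rbind, rows))
}
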