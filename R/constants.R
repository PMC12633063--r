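# Physical constants and element/residue tables used throughout the package.
# All masses are monoisotopic, in Da.

## Monoisotopic atomic masses (CODATA/IUPAC). Heavy isotopes are distinct
## symbols so isotopically coded labels (TMT) can be expressed exactly.
.ELEMENT_MASS <- c(
  H     = 1.00782503207,
  C     = 12.0,
  N     = 14.0030740048,
  O     = 15.9949146196,
  S     = 31.97207100,
  P     = 30.97376163,
  `13C` = 13.0033548378,
  `15N` = 15.0001088982
)

.PROTON_MASS   <- 1.007276466   # mass of H+ (H atom minus electron)
.ELECTRON_MASS <- 0.00054857990
.C13_SPACING   <- 1.003355      # 13C - 12C, spacing of the A+1 isotopologue
.N15_SPACING   <- 0.997035      # 15N - 14N
.C13_ABUNDANCE <- 0.0107        # natural 13C fraction

## Elemental compositions of the 20 standard amino-acid residues
## (as incorporated in a peptide chain, i.e. minus water).
.RESIDUE_COMPOSITION <- list(
  G = c(C = 2, H = 3,  N = 1, O = 1),
  A = c(C = 3, H = 5,  N = 1, O = 1),
  S = c(C = 3, H = 5,  N = 1, O = 2),
  P = c(C = 5, H = 7,  N = 1, O = 1),
  V = c(C = 5, H = 9,  N = 1, O = 1),
  T = c(C = 4, H = 7,  N = 1, O = 2),
  C = c(C = 3, H = 5,  N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1),
  I = c(C = 6, H = 11, N = 1, O = 1),
  N = c(C = 4, H = 6,  N = 2, O = 2),
  D = c(C = 4, H = 5,  N = 1, O = 3),
  Q = c(C = 5, H = 8,  N = 2, O = 2),
  K = c(C = 6, H = 12, N = 2, O = 1),
  E = c(C = 5, H = 7,  N = 1, O = 3),
  M = c(C = 5, H = 9,  N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7,  N = 3, O = 1),
  F = c(C = 9, H = 9,  N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1),
  Y = c(C = 9, H = 9,  N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1)
)

## Small neutral molecules used in terminus and neutral-loss arithmetic.
.MOLECULE_COMPOSITION <- list(
  H2O = c(H = 2, O = 1),
  NH3 = c(N = 1, H = 3),
  CO  = c(C = 1, O = 1)
)

## Histone H3 N-terminal tail peptides released by sortase tagging.
## Residue i of the peptide is histone residue i (index 4 = H3K4).
.H3_TAIL <- c(
  H3.1 = "ARTKQTARKSTGGKAPRKQLATKAARKSAPATGGGH",
  H3.3 = "ARTKQTARKSTGGKAPRKQLATKAARKSAPSTGGGH"
)

## Sortase-tag C-terminal fixed correction: the searched sequence ends in His,
## but the ligated species carries Lys + 2,3-diaminopropionamide in its place.
## Stored as the literal search-engine mass; reproduced analytically as
## M(Lys residue) + M(2,3-diaminopropionamide) - M(H2O) - M(His residue).
.CTERM_FIXED_MASS <- 76.1001
## Net elemental composition of that substitution (C3 H12 N2), used only
## where a composition is needed (isotope envelopes).
.CTERM_FIXED_COMPOSITION <- c(C = 3, H = 12, N = 2)
.DIAMINOPROPIONAMIDE_COMPOSITION <- c(C = 3, H = 9, N = 3, O = 1)
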