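#' Monoisotopic mass of an elemental composition
#'
#' Computes the exact monoisotopic mass of a formula given as a named count
#' vector over the supported element symbols (`C`, `H`, `N`, `O`, `S`, `P`,
#' and the heavy isotopes `13C`, `15N`, which are distinct symbols so that
#' isotopically coded labels such as TMT can be expressed exactly).
#'
#' @param composition Named numeric vector of non-negative integer counts,
#'   e.g. `c(C = 2, H = 2, O = 1)` for an acetyl delta.
#' @return Mass in Da (a single non-negative number).
#' @examples
#' compositionMass(c(C = 1, H = 2))          # methyl delta, 14.015650
#' compositionMass(c(C = 2, H = 2, O = 1))   # acetyl delta, 42.010565
#' @export
compositionMass <- function(composition) {
  if (length(composition) == 0L)
    return(0)
  if (is.null(names(composition)) || any(!nzchar(names(composition))))
    stop("composition must be a named count vector")
  unknown <- setdiff(names(composition), names(.ELEMENT_MASS))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  if (any(composition < 0))
    stop("element counts must be >= 0")
  sum(composition * .ELEMENT_MASS[names(composition)])
}

## Add two compositions (named count vectors); `mult` scales the second.
.addComposition <- function(a, b, mult = 1) {
  if (length(b) == 0L) return(a)
  all <- union(names(a), names(b))
  out <- setNames(numeric(length(all)), all)
  out[names(a)] <- a
  out[names(b)] <- out[names(b)] + mult * b
  out[out != 0]
}

#' Monoisotopic residue mass table
#'
#' Masses of the 20 standard amino-acid residues (peptide-bonded, i.e. minus
#' water), each computed from its elemental composition.
#'
#' @return Named numeric vector of residue masses in Da.
#' @export
residueMassTable <- function() {
  vapply(.RESIDUE_COMPOSITION, compositionMass, numeric(1))
}

#' Modification table for histone H3 tail searches
#'
#' The variable and fixed modifications considered by the pipeline: mono-, di-
#' and trimethylation, acetylation, phosphorylation and propionylation of the
#' tail, plus the fixed TMT 6-plex label on His and the fixed sortase-tag
#' C-terminal correction. Each `delta_mass` is derived from the elemental
#' composition except the C-terminal correction, which is a literal search
#' mass (see [ctermCorrectionMass()]).
#'
#' @return A `data.frame` with columns `name`, `abbrev`, `delta_mass`,
#'   `targets` (allowed residue letters, collapsed), `max_per_peptide` and
#'   `fixed`. Compositions are in `attr(, "compositions")`.
#' @export
modificationTable <- function() {
  comps <- list(
    Methyl    = c(C = 1, H = 2),
    Dimethyl  = c(C = 2, H = 4),
    Trimethyl = c(C = 3, H = 6),
    Acetyl    = c(C = 2, H = 2, O = 1),
    Phospho   = c(H = 1, P = 1, O = 3),
    Propionyl = c(C = 3, H = 4, O = 1),
    TMT6plex  = c(C = 8, H = 20, N = 1, O = 2, `13C` = 4, `15N` = 1),
    CtermTag  = .CTERM_FIXED_COMPOSITION
  )
  tab <- data.frame(
    name            = names(comps),
    abbrev          = c("me1", "me2", "me3", "ac", "ph", "pr", "tmt", "ctag"),
    delta_mass      = vapply(comps, compositionMass, numeric(1)),
    targets         = c("KR", "KR", "K", "K", "ST", "K", "H", ""),
    max_per_peptide = c(3L, 3L, 3L, 5L, 2L, 1L, NA_integer_, NA_integer_),
    fixed           = c(rep(FALSE, 6L), TRUE, TRUE),
    row.names       = NULL
  )
  ## the C-terminal tag mass is the literal search-engine value
  tab$delta_mass[tab$name == "CtermTag"] <- .CTERM_FIXED_MASS
  attr(tab, "compositions") <- comps
  tab
}

#' Sortase-tag C-terminal mass correction
#'
#' The fixed C-terminal mass correction applied to every tail peptide,
#' accounting for the difference between the His-terminated search sequence
#' and the actual Lys + 2,3-diaminopropionamide terminus left by sortase
#' ligation. `analytic = TRUE` recomputes it from residue chemistry as
#' M(Lys residue) + M(2,3-diaminopropionamide) - M(H2O) - M(His residue);
#' the default returns the literal value used in the search (76.1001 Da).
#'
#' @param analytic Recompute from elemental compositions instead of returning
#'   the stored literal.
#' @return Mass in Da.
#' @export
ctermCorrectionMass <- function(analytic = FALSE) {
  if (!analytic)
    return(.CTERM_FIXED_MASS)
  compositionMass(.RESIDUE_COMPOSITION$K) +
    compositionMass(.DIAMINOPROPIONAMIDE_COMPOSITION) -
    compositionMass(.MOLECULE_COMPOSITION$H2O) -
    compositionMass(.RESIDUE_COMPOSITION$H)
}

#' Parts-per-million mass error
#'
#' @param observed,theoretical m/z values; `theoretical` must be > 0.
#' @return `1e6 * (observed - theoretical) / theoretical`.
#' @export
ppmError <- function(observed, theoretical) {
  if (any(theoretical <= 0))
    stop("theoretical m/z must be > 0")
  1e6 * (observed - theoretical) / theoretical
}

## ---- internal mass plumbing -------------------------------------------

## Look up a modification row by name (or abbrev) in a modification table.
.modRow <- function(name, mods = modificationTable()) {
  i <- match(name, mods$name)
  if (is.na(i)) i <- match(name, mods$abbrev)
  if (is.na(i)) stop("unknown modification: ", name)
  i
}

## Per-position residue masses of a proteoform, with variable placements and
## fixed mods (TMT on His; C-terminal tag folded into the last residue).
## Returns a numeric vector of length nchar(sequence).
.residueMassesOf <- function(p) {
  seqchars <- strsplit(h3TailSequence(variantOf(p)), "")[[1]]
  rmass <- residueMassTable()[seqchars]
  mods <- modificationTable()
  ## fixed TMT on every His
  rmass[seqchars == "H"] <- rmass[seqchars == "H"] +
    mods$delta_mass[mods$name == "TMT6plex"]
  ## fixed C-terminal correction on the last residue
  rmass[length(rmass)] <- rmass[length(rmass)] + .CTERM_FIXED_MASS
  ## variable placements
  pos <- placementPositions(p)
  if (length(pos)) {
    deltas <- mods$delta_mass[vapply(placementMods(p), .modRow, integer(1),
                                     mods = mods)]
    rmass[pos] <- rmass[pos] + deltas
  }
  unname(rmass)
}

## Per-position carbon (12C) counts, for isotope-envelope arithmetic.
.residueCarbonsOf <- function(p) {
  seqchars <- strsplit(h3TailSequence(variantOf(p)), "")[[1]]
  nc <- vapply(.RESIDUE_COMPOSITION[seqchars], function(x) unname(x["C"]),
               numeric(1))
  mods <- modificationTable()
  comps <- attr(mods, "compositions")
  cOf <- function(comp) if ("C" %in% names(comp)) unname(comp[["C"]]) else 0
  nc[seqchars == "H"] <- nc[seqchars == "H"] + cOf(comps$TMT6plex)
  nc[length(nc)] <- nc[length(nc)] + cOf(comps$CtermTag)
  pos <- placementPositions(p)
  if (length(pos)) {
    addC <- vapply(placementMods(p), function(m)
      cOf(comps[[mods$name[.modRow(m, mods)]]]), numeric(1))
    nc[pos] <- nc[pos] + addC
  }
  unname(nc)
}

#' Neutral monoisotopic mass of a proteoform
#'
#' Sum of residue masses plus water, all variable placements, the fixed TMT
#' 6-plex label on each His and the fixed sortase-tag C-terminal correction.
#'
#' @param p A [Proteoform-class] object.
#' @return Neutral mass in Da.
#' @export
proteoformMass <- function(p) {
  sum(.residueMassesOf(p)) + compositionMass(.MOLECULE_COMPOSITION$H2O)
}

#' Precursor m/z of a proteoform
#'
#' @param p A [Proteoform-class].
#' @param charge Positive integer charge state (the acquisition selected 8+).
#' @return m/z of the protonated species.
#' @export
precursorMz <- function(p, charge = 8L) {
  stopifnot(charge >= 1)
  (proteoformMass(p) + charge * .PROTON_MASS) / charge
}

## Series constants: neutral fragment mass relative to the plain residue sums.
## b = sum(residues 1..i); y = sum(residues i+1..n) + H2O; a = b - CO;
## c = b + NH3; z is the ETD radical species z-dot = y - NH3 + H.
.seriesOffset <- function(series) {
  H2O <- compositionMass(.MOLECULE_COMPOSITION$H2O)
  NH3 <- compositionMass(.MOLECULE_COMPOSITION$NH3)
  CO  <- compositionMass(.MOLECULE_COMPOSITION$CO)
  Hat <- .ELEMENT_MASS[["H"]]
  switch(series,
    a = -CO,
    b = 0,
    c = NH3,
    y = H2O,
    z = H2O - NH3 + Hat,
    stop("unsupported ion series: ", series)
  )
}

#' Fragment-ion m/z of a proteoform
#'
#' Theoretical m/z of an `a`, `b`, `c`, `y` or `z` backbone fragment of a
#' tail proteoform, including every placement and fixed modification that
#' falls inside the fragment. `z` ions are the charge-reduced radical species
#' (z-dot) produced by electron-transfer dissociation. An optional neutral
#' loss (given as an elemental composition) is subtracted from the neutral
#' fragment before protonation.
#'
#' @param p A [Proteoform-class].
#' @param series One of `"a"`, `"b"`, `"c"`, `"y"`, `"z"`.
#' @param index Fragment index, 1..(sequence length - 1). For N-terminal
#'   series this counts residues from the N-terminus; for C-terminal series
#'   from the C-terminus.
#' @param charge Positive integer charge.
#' @param neutralLoss Optional composition (e.g. `c(H = 2, O = 1)`) lost from
#'   the fragment.
#' @return m/z (may be vectorized over `index`).
#' @export
fragmentMz <- function(p, series, index, charge = 1L, neutralLoss = NULL) {
  series <- match.arg(series, c("a", "b", "c", "y", "z"))
  n <- nchar(h3TailSequence(variantOf(p)))
  if (any(index < 1L | index > n - 1L))
    stop("fragment index must be in 1..", n - 1L)
  if (charge < 1L)
    stop("charge must be >= 1")
  rmass <- .residueMassesOf(p)
  neutral <- if (series %in% c("a", "b", "c")) {
    cumsum(rmass)[index] + .seriesOffset(series)
  } else {
    rev(cumsum(rev(rmass)))[n - index + 1L] + .seriesOffset(series)
  }
  if (!is.null(neutralLoss))
    neutral <- neutral - compositionMass(neutralLoss)
  (neutral + charge * .PROTON_MASS) / charge
}

#' Isotope envelope of a proteoform or composition
#'
#' Approximate A+0..A+(k-1) isotopologue pattern from a binomial model over
#' the carbon count (natural 13C abundance 0.0107), with peaks spaced by the
#' 13C spacing divided by charge and intensities normalized to a maximum of 1.
#' Heavy atoms already present (e.g. the 13C/15N of a TMT label) are part of
#' the monoisotopic species and do not enter the binomial.
#'
#' @param x A [Proteoform-class] or a named elemental composition vector.
#' @param charge Positive integer charge.
#' @param nPeaks Number of isotopologue peaks (>= 1).
#' @return `data.frame` with columns `mz` and `intensity`.
#' @export
isotopeEnvelope <- function(x, charge = 1L, nPeaks = 3L) {
  stopifnot(nPeaks >= 1L, charge >= 1L)
  if (is(x, "Proteoform")) {
    mono <- proteoformMass(x)
    nC <- sum(.residueCarbonsOf(x))
  } else {
    mono <- compositionMass(x)
    nC <- if ("C" %in% names(x)) unname(x[["C"]]) else 0
  }
  k <- seq_len(nPeaks) - 1L
  intensity <- stats::dbinom(k, size = nC, prob = .C13_ABUNDANCE)
  intensity <- intensity / max(intensity)
  data.frame(
    mz = (mono + charge * .PROTON_MASS) / charge + k * .C13_SPACING / charge,
    intensity = intensity
  )
}

#' All theoretical fragment ions of a proteoform
#'
#' Enumerates backbone fragments for the requested series, charges and
#' neutral losses. This is the ion set against which observed peaks are
#' matched.
#'
#' @param p A [Proteoform-class].
#' @param series Character vector of series tokens.
#' @param charges Integer vector of fragment charges.
#' @param losses Named list of neutral-loss compositions; an empty name or
#'   `"none"` entry is added automatically for the unmodified fragment.
#' @return `data.frame` with columns `proteoform` (canonical key), `variant`,
#'   `series`, `index`, `charge`, `loss` and `mz`.
#' @export
fragmentIonTable <- function(p, series = c("a", "b", "c", "y", "z"),
                             charges = 1:2, losses = list()) {
  n <- nchar(h3TailSequence(variantOf(p))) - 1L
  lossNames <- c("none", names(losses))
  lossList <- c(list(none = NULL), losses)
  grid <- expand.grid(series = series, charge = charges, loss = lossNames,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    data.frame(
      series = grid$series[i],
      index = seq_len(n),
      charge = grid$charge[i],
      loss = grid$loss[i],
      mz = fragmentMz(p, grid$series[i], seq_len(n), grid$charge[i],
                      lossList[[grid$loss[i]]])
    )
  })
  out <- do.call(rbind, rows)
  out <- cbind(proteoform = proteoformKey(p), variant = variantOf(p), out)
  rownames(out) <- NULL
  out
}

## Cumulative carbon counts for fragments (used by the simulator to emit
## realistic A+1 companion peaks). Returns list(nterm=, cterm=) vectors.
.fragmentCarbons <- function(p) {
  nc <- .residueCarbonsOf(p)
  list(nterm = cumsum(nc), cterm = rev(cumsum(rev(nc))))
}
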