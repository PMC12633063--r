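#' Construct a Proteoform
#'
#' @param variant `"H3.1"` or `"H3.3"`.
#' @param positions Integer vector of modified residue positions (1-based;
#'   index 4 is H3K4). Need not be sorted; placements are canonicalized to
#'   position order.
#' @param mods Character vector of modification abbreviations parallel to
#'   `positions` (`me1`, `me2`, `me3`, `ac`, `ph`, `pr`).
#' @return A validated [Proteoform-class].
#' @examples
#' proteoform("H3.1", c(14, 23, 27), c("ac", "ac", "me2"))
#' @export
proteoform <- function(variant = "H3.1", positions = integer(),
                       mods = character()) {
  positions <- as.integer(positions)
  o <- order(positions)
  new("Proteoform", variant = variant, positions = positions[o],
      mods = as.character(mods)[o])
}

#' H3 tail sequence of a variant
#' @param variant `"H3.1"` or `"H3.3"`.
#' @return The 36-residue tail peptide sequence.
#' @export
h3TailSequence <- function(variant) {
  if (!variant %in% names(.H3_TAIL))
    stop("unknown variant: ", variant)
  unname(.H3_TAIL[[variant]])
}

#' @describeIn proteoform Sequence variant of a proteoform.
#' @param p A `Proteoform`.
#' @export
variantOf <- function(p) p@variant

#' @describeIn proteoform Modified positions (sorted, 1-based).
#' @export
placementPositions <- function(p) p@positions

#' @describeIn proteoform Modification abbreviations, parallel to positions.
#' @export
placementMods <- function(p) p@mods

#' Canonical proteoform key
#'
#' Formats a proteoform as the field's slash-joined shorthand, e.g.
#' `"H3K14ac/K23ac/K27me2"`; an unmodified tail is `"H3unmod"`. Tokens are
#' sorted by position and the leading `H3` appears once. The sequence
#' variant (H3.1 vs H3.3) is not part of the key and is carried separately.
#'
#' @param p A [Proteoform-class].
#' @return A single string.
#' @export
proteoformKey <- function(p) {
  if (!length(p@positions))
    return("H3unmod")
  seqchars <- strsplit(h3TailSequence(variantOf(p)), "")[[1]]
  tokens <- paste0(seqchars[p@positions], p@positions, p@mods)
  paste0("H3", paste(tokens, collapse = "/"))
}

#' Parse a proteoform key
#'
#' Inverse of [proteoformKey()]: accepts keys like `"H3K14ac/K23ac/K27me2"`
#' (tokens in any order) or `"H3unmod"` and returns the canonical
#' [Proteoform-class]. Parsing then formatting canonicalizes token order;
#' formatting then parsing is the identity.
#'
#' @param key Key string.
#' @param variant Sequence variant the key refers to.
#' @return A [Proteoform-class].
#' @export
parseProteoformKey <- function(key, variant = "H3.1") {
  stopifnot(is.character(key), length(key) == 1L)
  if (!startsWith(key, "H3"))
    stop("proteoform key must start with 'H3': ", key)
  body <- substring(key, 3L)
  if (identical(body, "unmod") || body == "")
    return(proteoform(variant))
  tokens <- strsplit(body, "/", fixed = TRUE)[[1]]
  m <- regmatches(tokens, regexec("^([A-Z])([0-9]+)([a-z0-9]+)$", tokens))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad))
    stop("malformed proteoform token(s): ", paste(tokens[bad], collapse = ", "))
  res <- vapply(m, `[[`, character(1), 2L)
  pos <- as.integer(vapply(m, `[[`, character(1), 3L))
  abb <- vapply(m, `[[`, character(1), 4L)
  mods <- modificationTable()
  unknown <- setdiff(abb, mods$abbrev[!mods$fixed])
  if (length(unknown))
    stop("unknown modification abbreviation(s): ",
         paste(unknown, collapse = ", "))
  seqchars <- strsplit(h3TailSequence(variant), "")[[1]]
  if (any(pos > length(seqchars)))
    stop("position out of range in key: ", key)
  wrong <- seqchars[pos] != res
  if (any(wrong))
    stop("residue letter does not match sequence at position ",
         paste(pos[wrong], collapse = ", "))
  if (anyDuplicated(pos))
    stop("duplicate placement position in key: ", key)
  proteoform(variant, pos, abb)
}

#' Random proteoforms for simulations
#'
#' Draws distinct proteoforms by sampling allowed placements uniformly while
#' respecting each modification's residue targets and per-peptide cap. Used
#' by the synthetic-data generator to build proteoform panels.
#'
#' @param n Number of distinct proteoforms.
#' @param maxMods Maximum placements per proteoform.
#' @param variant Sequence variant.
#' @return List of [Proteoform-class] objects with distinct keys.
#' @export
randomProteoforms <- function(n, maxMods = 4L, variant = "H3.1") {
  seqchars <- strsplit(h3TailSequence(variant), "")[[1]]
  mods <- modificationTable()
  mods <- mods[!mods$fixed, ]
  out <- list(); seen <- character()
  guard <- 0L
  while (length(out) < n) {
    guard <- guard + 1L
    if (guard > 50L * n)
      stop("could not draw ", n, " distinct proteoforms")
    k <- sample.int(maxMods, 1L)
    pos <- sort(sample(seq_along(seqchars), k))
    abb <- character(0)
    used <- table(factor(character(), levels = mods$abbrev))
    ok <- TRUE
    for (pp in pos) {
      cand <- mods$abbrev[grepl(seqchars[pp], mods$targets, fixed = TRUE) &
                          (is.na(mods$max_per_peptide) |
                           as.integer(used[mods$abbrev]) <
                             mods$max_per_peptide)]
      if (!length(cand)) { ok <- FALSE; break }
      a <- if (length(cand) == 1L) cand else sample(cand, 1L)
      abb <- c(abb, a)
      used[a] <- used[a] + 1L
    }
    if (!ok) next
    p <- tryCatch(proteoform(variant, pos, abb), error = function(e) NULL)
    if (is.null(p)) next
    key <- proteoformKey(p)
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- p
  }
  out
}

setMethod("show", "Proteoform", function(object) {
  cat("Proteoform:", proteoformKey(object),
      sprintf("(%s, %.4f Da)\n", variantOf(object), proteoformMass(object)))
})
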