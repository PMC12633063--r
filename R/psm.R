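## PSM tables are plain data.frames with columns
##   scan_id, variant, key, pep, delta_mod_score
## where `key` is the canonical proteoform key. On disk the table is a
## CSV/TSV in a minimal search-export schema (see readPsmTable); a column
## map adapts third-party exports without hard-coding their headers.

#' Read a PSM export table
#'
#' Reads a peptide-spectrum-match table (CSV or TSV by extension) with one
#' row per PSM. The expected logical columns are `scan_id`, `variant`
#' (sequence name, `H3.1`/`H3.3`), `mods` (placement string, semicolon- or
#' comma-separated tokens like `K4(Trimethyl)` or `K4me3`; empty =
#' unmodified), `pep` (posterior error probability) and `delta_mod_score`.
#' `columnMap` renames the file's actual headers onto these names so real
#' search-engine exports can be adapted in configuration.
#'
#' Rows that fail to parse or violate modification chemistry (wrong target
#' residue, exceeded per-peptide cap) are never silently dropped: they are
#' returned in `attr(, "rejects")` with a reason.
#'
#' @param path Input file.
#' @param columnMap Named character vector mapping logical -> actual column
#'   names.
#' @return `data.frame` of accepted PSMs with a `rejects` attribute.
#' @export
readPsmTable <- function(path, columnMap = NULL) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  need <- c("scan_id", "variant", "mods", "pep", "delta_mod_score")
  map <- setNames(need, need)
  if (!is.null(columnMap)) map[names(columnMap)] <- columnMap
  missing <- map[!map %in% names(raw)]
  if (length(missing))
    stop("PSM table is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (!nrow(raw)) {
    out <- data.frame(scan_id = character(), variant = character(),
                      key = character(), pep = numeric(),
                      delta_mod_score = numeric())
    attr(out, "rejects") <- data.frame(row = integer(), reason = character())
    return(out)
  }
  rows <- vector("list", nrow(raw))
  rejects <- list()
  for (i in seq_len(nrow(raw))) {
    parsed <- tryCatch({
      variant <- raw[[map["variant"]]][i]
      p <- .parseModString(raw[[map["mods"]]][i], variant)
      pep <- as.numeric(raw[[map["pep"]]][i])
      delta <- as.numeric(raw[[map["delta_mod_score"]]][i])
      if (is.na(pep) || pep < 0 || pep > 1)
        stop("pep must be a probability in [0, 1]")
      if (is.na(delta) || delta < 0)
        stop("delta_mod_score must be a non-negative number")
      data.frame(scan_id = raw[[map["scan_id"]]][i], variant = variant,
                 key = proteoformKey(p), pep = pep,
                 delta_mod_score = delta, stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(parsed, "error")) {
      rejects[[length(rejects) + 1L]] <-
        data.frame(row = i, reason = conditionMessage(parsed))
    } else {
      rows[[i]] <- parsed
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(scan_id = character(), variant = character(),
                      key = character(), pep = numeric(),
                      delta_mod_score = numeric())
  rownames(out) <- NULL
  attr(out, "rejects") <- if (length(rejects)) do.call(rbind, rejects)
                          else data.frame(row = integer(),
                                          reason = character())
  out
}

## Parse a placement string such as "K4(Trimethyl); K9(Acetyl)" or
## "K4me3, K9ac" into a validated Proteoform.
.parseModString <- function(s, variant) {
  s <- trimws(s %||% "")
  if (!nzchar(s) || identical(tolower(s), "unmod"))
    return(proteoform(variant))
  tokens <- trimws(strsplit(s, "[;,]")[[1]])
  tokens <- tokens[nzchar(tokens)]
  m <- regmatches(tokens,
                  regexec("^([A-Z])([0-9]+)\\(([A-Za-z0-9]+)\\)$|^([A-Z])([0-9]+)([a-z0-9]+)$",
                          tokens))
  mods <- modificationTable()
  pos <- integer(); abb <- character()
  for (j in seq_along(tokens)) {
    g <- m[[j]]
    if (!length(g))
      stop("malformed placement token: ", tokens[j])
    if (nzchar(g[2L])) { res <- g[2L]; p <- g[3L]; name <- g[4L] }
    else { res <- g[5L]; p <- g[6L]; name <- g[7L] }
    i <- .modRow(name, mods)
    if (mods$fixed[i])
      stop(mods$name[i], " is fixed and cannot be a variable placement")
    pos <- c(pos, as.integer(p))
    abb <- c(abb, mods$abbrev[i])
    seqchars <- strsplit(h3TailSequence(variant), "")[[1]]
    if (as.integer(p) > length(seqchars) ||
        seqchars[as.integer(p)] != res)
      stop("residue letter mismatch at position ", p)
  }
  proteoform(variant, pos, abb)  # validity enforces targets and caps
}

#' Write a PSM table
#'
#' Emits the package's minimal PSM CSV schema (used by the simulator).
#'
#' @param psms PSM `data.frame` (columns `scan_id`, `variant`, `key`, `pep`,
#'   `delta_mod_score`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writePsmTable <- function(psms, path) {
  out <- data.frame(
    scan_id = psms$scan_id, variant = psms$variant,
    mods = vapply(psms$key, function(k) {
      if (identical(k, "H3unmod")) "" else substring(k, 3L)
    }, character(1)),
    pep = psms$pep, delta_mod_score = psms$delta_mod_score
  )
  ## key body tokens double as placement tokens (K4me3 form)
  out$mods <- gsub("/", "; ", out$mods, fixed = TRUE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Filter PSMs on confidence scores
#'
#' Keeps high-confidence matches with posterior error probability at or
#' below `pepMax` and delta-mod score at or above `deltaMin`; both
#' boundaries are inclusive. Nothing is dropped: the complement is returned
#' alongside.
#'
#' @param psms PSM `data.frame`.
#' @param config A [RunConfig-class] (thresholds default 0.05 and 10).
#' @return `list(kept = , rejected = )`, partitioning the input rows.
#' @export
filterPsms <- function(psms, config = runConfig()) {
  keep <- psms$pep <= config@pepMax & psms$delta_mod_score >= config@deltaMin
  list(kept = psms[keep, , drop = FALSE],
       rejected = psms[!keep, , drop = FALSE])
}

#' Subdivide scans by kept-PSM count
#'
#' Partitions the distinct scans of a filtered PSM table by how many PSMs
#' each carries (single-PSM scans are quantified directly; multi-PSM scans
#' are chimeric and their shared fragment intensity is apportioned).
#'
#' @param kept Filtered PSM `data.frame`.
#' @return Named list, `"1"`, `"2"`, ... -> character vector of scan ids.
#' @export
subdivideByPsmCount <- function(kept) {
  if (!nrow(kept)) return(setNames(list(), character()))
  counts <- table(kept$scan_id)
  split(names(counts), as.integer(counts))
}
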