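#' Parse a molecular formula string into element counts
#'
#' Tokenizes a formula such as \code{"C9H6O2"} into element counts. Symbols
#' are read greedily, longest first, so \code{"Cl"} is chlorine rather than
#' carbon followed by an unknown symbol. Supported elements are those in
#' \code{\link{elementMasses}} (C, H, N, O, S, P, Cl) — the element set used
#' upstream in formula assignment of LC/MS features.
#'
#' @param text A single formula string, e.g. \code{"C9H6O2"}.
#' @return Named integer vector of element counts (order of first appearance;
#'   repeated symbols are summed).
#' @examples
#' parseFormula("C9H6O2")
#' parseFormula("C2H3Cl")
#' @export
parseFormula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("formula must be a single character string")
  }
  text <- gsub("\\s", "", text)
  if (!nzchar(text)) stop("empty formula string")
  tokens <- regmatches(text, gregexpr("[A-Z][a-z]*[0-9]*", text))[[1]]
  if (paste(tokens, collapse = "") != text) {
    stop("cannot parse formula '", text, "': unexpected characters")
  }
  counts <- integer(0)
  for (tok in tokens) {
    sym <- sub("[0-9]*$", "", tok)
    dig <- sub("^[A-Za-z]+", "", tok)
    if (!sym %in% names(elementMasses)) {
      stop("unknown element symbol '", sym, "' in formula '", text, "'")
    }
    n <- if (nzchar(dig)) as.integer(dig) else 1L
    if (is.na(n) || n <= 0L) {
      stop("zero or negative multiplicity for '", sym, "' in formula '", text, "'")
    }
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
  }
  counts
}

#' Format element counts in Hill notation
#'
#' Hill order: carbon first, hydrogen second, then the remaining elements
#' alphabetically; when no carbon is present, all elements are alphabetical.
#' A count of 1 is written without the digit. Zero counts are dropped.
#'
#' @param counts Named integer vector of element counts.
#' @return Canonical formula string.
#' @examples
#' hillFormat(c(C = 9, H = 6, O = 2))
#' hillFormat(c(H = 2, O = 1))
#' @export
hillFormat <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) == 0) stop("empty element-count map")
  syms <- names(counts)
  if (is.null(syms) || any(!nzchar(syms))) stop("counts must be a named vector")
  ord <- if ("C" %in% syms) {
    c(intersect(c("C", "H"), syms), sort(setdiff(syms, c("C", "H"))))
  } else {
    sort(syms)
  }
  paste0(ord, ifelse(counts[ord] == 1L, "", counts[ord]), collapse = "")
}

#' Canonicalize a formula string
#'
#' \code{parseFormula} followed by \code{hillFormat}: any formula string with
#' the same element counts maps to the same canonical Hill string, the key on
#' which formula matching operates.
#'
#' @inheritParams parseFormula
#' @return Canonical Hill-notation string.
#' @export
canonicalFormula <- function(text) hillFormat(parseFormula(text))

#' Monoisotopic mass of a formula
#'
#' @param x Formula string or named count vector.
#' @return Mass in Da, computed from \code{\link{elementMasses}}.
#' @examples
#' monoisotopicMass("C9H6O2")
#' @export
monoisotopicMass <- function(x) {
  counts <- if (is.character(x)) parseFormula(x) else x
  counts <- counts[counts > 0]
  sum(counts * elementMasses[names(counts)])
}

#' Match assigned formulas against a toxic-compound table
#'
#' Exact element-count matching: an assigned formula matches a table entry iff
#' their canonical Hill strings are equal. An assigned formula matching k
#' entries yields one match with k candidates — all isomers are retained,
#' since without structural information every formula match is tentative.
#' Mass-tolerance matching is deliberately not performed: the upstream
#' assignment stage already resolved mass to formula.
#'
#' @param assigned Data frame from \code{\link{readAssignedFormulas}} (needs a
#'   \code{canonical} column).
#' @param table Data frame from \code{\link{readToxicTable}} (needs
#'   \code{canonical} and \code{name} columns).
#' @param ionAdjust Optional ion-form adjustment for users feeding raw ion
#'   formulas rather than neutral ones: \code{"none"} (default; upstream
#'   assignment produces neutral formulas), \code{"deprotonated"} (inputs are
#'   [M-H]- ions: add one H before matching) or \code{"protonated"} (inputs
#'   are [M+H]+ ions: remove one H).
#' @return List with \code{matches} (list of \code{list(assigned = one-row
#'   data frame, candidates = data frame of table rows)}) and \code{unmatched}
#'   (data frame of assigned rows with no candidate). Every assigned row lands
#'   in exactly one of the two.
#' @export
matchFormulas <- function(assigned, table, ionAdjust = c("none", "deprotonated", "protonated")) {
  ionAdjust <- match.arg(ionAdjust)
  key <- assigned$canonical
  if (ionAdjust != "none" && nrow(assigned) > 0) {
    delta <- if (ionAdjust == "deprotonated") 1L else -1L
    key <- vapply(assigned$canonical, function(f) {
      counts <- parseFormula(f)
      counts["H"] <- (if ("H" %in% names(counts)) counts[["H"]] else 0L) + delta
      if (counts[["H"]] < 0L) return(NA_character_)
      hillFormat(counts)
    }, character(1), USE.NAMES = FALSE)
  }
  idx <- split(seq_len(nrow(table)), table$canonical)
  matches <- list()
  unmatched <- integer(0)
  for (i in seq_len(nrow(assigned))) {
    rows <- if (!is.na(key[i])) idx[[key[i]]] else NULL
    if (is.null(rows)) {
      unmatched <- c(unmatched, i)
    } else {
      matches[[length(matches) + 1L]] <- list(
        assigned = assigned[i, , drop = FALSE],
        candidates = table[rows, , drop = FALSE]
      )
    }
  }
  list(matches = matches, unmatched = assigned[unmatched, , drop = FALSE])
}
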