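#' Monoisotopic atomic masses
#'
#' Masses (Da) of the most abundant isotope of each element supported in
#' molecular formulas. A single embedded table is used by both the fixture
#' generators and the mass/formula consistency check so the two can never
#' disagree.
#'
#' @format Named numeric vector (element symbol -> mass in Da).
#' @export
elementMasses <- c(
  C  = 12.000000,
  H  = 1.0078250319,
  N  = 14.0030740052,
  O  = 15.9949146221,
  S  = 31.97207069,
  P  = 30.97376151,
  Cl = 34.96885271
)

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Normalize a compound name for matching
#'
#' Lower-cases, trims and collapses whitespace. With \code{stripStereo = TRUE}
#' also removes a leading stereo-descriptor prefix (\code{L-}, \code{D-},
#' \code{DL-}, \code{(+)-}, \code{(-)-}) so that e.g. "L-phenylalanine" and
#' "phenylalanine" compare equal, mirroring the renaming seen between
#' food-safety and chemical-record databases.
#'
#' @param name Character vector of compound names.
#' @param stripStereo Also strip stereo-descriptor prefixes.
#' @return Character vector of normalized keys.
#' @export
normalizeName <- function(name, stripStereo = FALSE) {
  x <- tolower(trimws(as.character(name)))
  x <- gsub("\\s+", " ", x)
  if (stripStereo) {
    x <- sub("^(dl-|l-|d-|\\(\\+\\)-|\\(-\\)-|\\(±\\)-|\\(−\\)-)", "", x)
  }
  x
}

# Both lookup keys for a name: as-is (normalized) and stereo-stripped.
nameKeys <- function(name) {
  unique(c(normalizeName(name), normalizeName(name, stripStereo = TRUE)))
}

#' @rdname severityRank
#' @export
toxFamilies <- function() {
  c("AcuteToxic", "SkinAndEyeIrritant", "EyeIrritant", "SkinIrritant",
    "PotentiallyToxic")
}

#' Severity ranking of toxicity categories
#'
#' The classifier's codomain is five severity-ordered category families.
#' \code{severityRank} maps a (family, GHS level) pair to a numeric rank on a
#' total order; larger is more severe. Within a family, GHS category 1 is the
#' most severe. The order is: Acute toxic 1 > ... > Acute toxic 5 >
#' Skin and eye irritant > Eye irritant > Skin irritant > Potentially toxic.
#'
#' @param family One of \code{toxFamilies()}.
#' @param level GHS category integer, or \code{NA} for families without one.
#' @return Numeric rank (vectorized over \code{family}/\code{level}).
#' @export
severityRank <- function(family, level = NA_integer_) {
  base <- c(AcuteToxic = 100, SkinAndEyeIrritant = 80, EyeIrritant = 70,
            SkinIrritant = 60, PotentiallyToxic = 10)
  n <- max(length(family), length(level))
  family <- rep_len(family, n)
  level <- rep_len(as.integer(level), n)
  bad <- !family %in% names(base)
  if (any(bad)) stop("unknown category family: ", paste(family[bad], collapse = ", "))
  ifelse(family == "PotentiallyToxic", base[family],
         base[family] - ifelse(is.na(level), 0L, level))
}

#' Display label for a classification
#'
#' Pure function of (family, level): e.g. \code{("AcuteToxic", 4)} gives
#' \code{"Acute toxic 4"} and \code{("PotentiallyToxic", NA)} gives
#' \code{"Potentially toxic"}.
#'
#' @inheritParams severityRank
#' @return Character label.
#' @export
toxLabel <- function(family, level = NA_integer_) {
  stem <- c(AcuteToxic = "Acute toxic", SkinAndEyeIrritant = "Skin and eye irritant",
            EyeIrritant = "Eye irritant", SkinIrritant = "Skin irritant",
            PotentiallyToxic = "Potentially toxic")
  if (!family %in% names(stem)) stop("unknown category family: ", family)
  if (family == "PotentiallyToxic" || is.na(level)) unname(stem[family])
  else paste(stem[family], level)
}

#' Parse a classification label back to (family, level)
#'
#' Inverse of \code{\link{toxLabel}}; also accepts the special local-table
#' class \code{"excluded"}.
#'
#' @param label Character label such as \code{"Acute toxic 4"}.
#' @return List with \code{family}, \code{level} (integer or \code{NA}) and
#'   \code{rank} (\code{-Inf} for \code{"excluded"}).
#' @export
parseToxLabel <- function(label) {
  label <- trimws(label)
  if (normalizeName(label) == "excluded") {
    return(list(family = "excluded", level = NA_integer_, rank = -Inf))
  }
  stems <- c(AcuteToxic = "acute toxic", SkinAndEyeIrritant = "skin and eye irritant",
             EyeIrritant = "eye irritant", SkinIrritant = "skin irritant",
             PotentiallyToxic = "potentially toxic")
  low <- normalizeName(label)
  hit <- names(stems)[vapply(stems, function(s) startsWith(low, s), logical(1))]
  # "eye irritant" must not swallow "skin and eye irritant": prefer longest stem
  if (length(hit) > 1) hit <- hit[which.max(nchar(stems[hit]))]
  if (length(hit) == 0) stop("unrecognized classification label: '", label, "'")
  rest <- trimws(substring(low, nchar(stems[hit]) + 1L))
  level <- if (nzchar(rest)) suppressWarnings(as.integer(rest)) else NA_integer_
  if (nzchar(rest) && is.na(level)) stop("unrecognized classification label: '", label, "'")
  list(family = hit, level = level, rank = severityRank(hit, level))
}

# deterministic seed derivation, kept under 2^31
deriveSeed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}
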