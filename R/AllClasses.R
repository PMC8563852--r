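#' @import methods
NULL

validSections <- function(sections, path = "sections") {
  if (!is.list(sections)) return(paste0(path, " must be a list"))
  for (i in seq_along(sections)) {
    s <- sections[[i]]
    here <- paste0(path, "[", i, "]")
    if (!is.list(s)) return(paste0(here, " must be a list"))
    if (is.null(s$heading) || !is.character(s$heading) || length(s$heading) != 1 ||
        is.na(s$heading) || !nzchar(s$heading)) {
      return(paste0(here, ": heading must be a non-empty string"))
    }
    if (!is.null(s$content) && !is.character(s$content)) {
      return(paste0(here, ": content must be a character vector"))
    }
    msg <- validSections(s$children %||% list(), paste0(here, "$children"))
    if (!isTRUE(msg)) return(msg)
  }
  TRUE
}

#' CompoundRecord: a hierarchical compound record
#'
#' A full record for a named compound as retrieved from a chemical-record
#' database (or a local JSON store emulating one): an integer compound
#' identifier (CID), the compound name, and a finite tree of sections, each
#' with a heading, content lines and child subsections. Toxicity screening
#' walks this tree looking for toxicity and food-safety headings.
#'
#' @slot cid Positive integer identifier.
#' @slot name Compound name.
#' @slot sections List of sections; each section is a list with elements
#'   \code{heading} (string), \code{content} (character vector) and
#'   \code{children} (list of sections).
#' @seealso \code{\link{scanRecord}}, \code{\link{loadFixtureStore}}
#' @exportClass CompoundRecord
setClass("CompoundRecord",
  representation(cid = "numeric", name = "character", sections = "list"),
  validity = function(object) {
    if (length(object@cid) != 1 || is.na(object@cid) || object@cid <= 0 ||
        object@cid != round(object@cid)) {
      return("cid must be a single positive integer")
    }
    if (length(object@name) != 1 || is.na(object@name) || !nzchar(object@name)) {
      return("name must be a non-empty string")
    }
    validSections(object@sections)
  }
)

#' Construct a CompoundRecord
#'
#' @param cid Positive integer identifier.
#' @param name Compound name.
#' @param sections List of sections (see \code{\linkS4class{CompoundRecord}});
#'   \code{\link{recordSection}} builds one.
#' @return A \code{CompoundRecord} object.
#' @export
compoundRecord <- function(cid, name, sections = list()) {
  new("CompoundRecord", cid = as.numeric(cid), name = name, sections = sections)
}

#' @describeIn compoundRecord Build one record section.
#' @param heading Section heading.
#' @param content Character vector of content lines.
#' @param children List of child sections.
#' @export
recordSection <- function(heading, content = character(0), children = list()) {
  list(heading = heading, content = as.character(content), children = children)
}

#' @rdname compoundRecord
#' @param object,x A \code{CompoundRecord}.
#' @export
setMethod("show", "CompoundRecord", function(object) {
  cat("CompoundRecord:", object@name, "(CID", object@cid, ")\n")
  cat("  top-level sections:",
      paste(vapply(object@sections, `[[`, character(1), "heading"), collapse = "; "),
      "\n")
})

#' @describeIn compoundRecord Accessor for the identifier.
#' @export
recordCid <- function(x) x@cid

#' @describeIn compoundRecord Accessor for the name.
#' @export
recordName <- function(x) x@name

#' @describeIn compoundRecord Accessor for the section tree.
#' @export
recordSections <- function(x) x@sections

#' ToxClassification: one acute-toxicity classification
#'
#' The outcome of classifying a compound's extracted hazard-statement codes
#' into one of five severity-ordered category families: \code{AcuteToxic}
#' (GHS categories 1-5), \code{SkinAndEyeIrritant}, \code{EyeIrritant},
#' \code{SkinIrritant} (irritant categories 1-2) and \code{PotentiallyToxic}
#' (toxicity fields present but no mapped hazard code).
#'
#' @slot family One of \code{toxFamilies()}.
#' @slot level GHS category integer, \code{NA} for \code{PotentiallyToxic}.
#' @slot evidence Hazard codes that produced the classification.
#' @slot label Display label, a pure function of (family, level), e.g.
#'   \code{"Acute toxic 4"}.
#' @seealso \code{\link{classifyCodes}}, \code{\link{severityRank}}
#' @exportClass ToxClassification
setClass("ToxClassification",
  representation(family = "character", level = "integer",
                 evidence = "character", label = "character"),
  validity = function(object) {
    if (!object@family %in% toxFamilies()) return("unknown category family")
    if (object@family == "PotentiallyToxic" && !is.na(object@level)) {
      return("PotentiallyToxic carries no GHS level")
    }
    if (object@family == "AcuteToxic" && (is.na(object@level) || !object@level %in% 1:5)) {
      return("AcuteToxic level must be 1-5")
    }
    if (object@family %in% c("SkinAndEyeIrritant", "EyeIrritant", "SkinIrritant") &&
        (is.na(object@level) || !object@level %in% 1:2)) {
      return("irritant level must be 1-2")
    }
    if (!identical(object@label, toxLabel(object@family, object@level))) {
      return("label must equal toxLabel(family, level)")
    }
    TRUE
  }
)

toxClassification <- function(family, level = NA_integer_, evidence = character(0)) {
  new("ToxClassification", family = family, level = as.integer(level),
      evidence = as.character(evidence), label = toxLabel(family, level))
}

#' @describeIn classifyCodes Display label accessor.
#' @param x A \code{ToxClassification}.
#' @export
classificationLabel <- function(x) x@label

#' @describeIn classifyCodes Severity rank accessor (larger = more severe).
#' @export
classificationRank <- function(x) severityRank(x@family, x@level)

#' @describeIn classifyCodes Family accessor.
#' @export
classificationFamily <- function(x) x@family

#' @describeIn classifyCodes GHS level accessor (\code{NA} when absent).
#' @export
classificationLevel <- function(x) x@level

#' @describeIn classifyCodes Evidence (hazard codes) accessor.
#' @export
classificationEvidence <- function(x) x@evidence

setMethod("show", "ToxClassification", function(object) {
  cat("ToxClassification:", object@label)
  if (length(object@evidence)) cat(" [", paste(object@evidence, collapse = ", "), "]")
  cat("\n")
})

#' RecordProvider: source of compound records
#'
#' Virtual parent of \code{\linkS4class{FixtureStore}} (local JSON store) and
#' \code{\linkS4class{LiveProvider}} (rate-limited HTTP client). Both answer
#' \code{\link{resolveName}} (name to CIDs) and \code{\link{fetchRecord}}
#' (CID to full record).
#'
#' @exportClass RecordProvider
setClass("RecordProvider", representation("VIRTUAL"))

#' FixtureStore: local JSON record store
#'
#' In-memory provider built from a directory of JSON record files with a
#' case-insensitive (and stereo-prefix-insensitive) name index. Pure:
#' repeated identical queries return identical results.
#'
#' @slot records Named list of \code{CompoundRecord}, keyed by CID.
#' @slot nameIndex Named list mapping normalized name keys to CID vectors
#'   (store order preserved).
#' @slot path Directory the store was loaded from ("" for in-memory stores).
#' @seealso \code{\link{loadFixtureStore}}
#' @exportClass FixtureStore
setClass("FixtureStore", contains = "RecordProvider",
  representation(records = "list", nameIndex = "list", path = "character"))

setMethod("show", "FixtureStore", function(object) {
  cat("FixtureStore:", length(object@records), "record(s),",
      length(object@nameIndex), "name key(s)\n")
})

#' LiveProvider: rate-limited HTTP record client
#'
#' Client for a live name-to-CID / CID-to-record HTTP service. Enforces a
#' minimum interval between consecutive requests (default 0.2 s, one fifth of
#' a second, so the public service is never overloaded) and retries transient
#' transport failures with backoff before surfacing an error. The clock,
#' sleep function and transport are injectable so the rate-limit contract is
#' testable without network or real waiting; live use is opt-in and never
#' exercised by the test suite.
#'
#' @slot baseUrl Service base URL.
#' @slot limiter Rate-limiter environment (see \code{\link{rateLimiter}}).
#' @slot transport Function(url) returning parsed JSON; may signal conditions
#'   of class \code{toxscreenNotFound} or \code{toxscreenTransport}.
#' @slot retries Number of retry attempts for transient failures.
#' @slot cacheDir Optional directory where fetched records are written as
#'   fixture-format JSON ("" disables caching).
#' @exportClass LiveProvider
setClass("LiveProvider", contains = "RecordProvider",
  representation(baseUrl = "character", limiter = "environment",
                 transport = "function", retries = "numeric",
                 cacheDir = "character"))

setMethod("show", "LiveProvider", function(object) {
  cat("LiveProvider:", object@baseUrl, "(min interval",
      object@limiter$minInterval, "s,", object@retries, "retries)\n")
})

#' ScreeningResult: full screening run output
#'
#' Result of \code{\link{runPipeline}}: per-sample partitions of matched
#' candidates into toxic / unchecked / unfound / locally-matched, the three
#' cross-sample merged reports, the formatted toxic report, and a run log of
#' per-stage counts.
#'
#' @slot samples Named list (per sample id) of lists with data frames
#'   \code{toxic}, \code{unchecked}, \code{unfound}, \code{safe} and the
#'   per-mode unmatched-formula tables.
#' @slot merged Named list of merged data frames: \code{toxic},
#'   \code{unfound}, \code{unchecked}.
#' @slot formatted The formatted merged toxic report data frame.
#' @slot log List of per-stage counts.
#' @slot outputRoot Directory all report files were written under.
#' @exportClass ScreeningResult
setClass("ScreeningResult",
  representation(samples = "list", merged = "list", formatted = "data.frame",
                 log = "list", outputRoot = "character"))

setMethod("show", "ScreeningResult", function(object) {
  cat("ScreeningResult:", length(object@samples), "sample(s) ->",
      nrow(object@merged$toxic), "toxic,",
      nrow(object@merged$unfound), "unfound,",
      nrow(object@merged$unchecked), "unchecked merged row(s)\n")
  cat("  outputs under:", object@outputRoot, "\n")
})

#' @describeIn runPipeline Per-sample partitions accessor.
#' @param x A \code{ScreeningResult}.
#' @export
sampleResults <- function(x) x@samples

#' @describeIn runPipeline Merged reports accessor (list with
#'   \code{toxic}, \code{unfound}, \code{unchecked}).
#' @export
mergedReports <- function(x) x@merged

#' @describeIn runPipeline Formatted merged toxic report accessor.
#' @export
formattedToxicReport <- function(x) x@formatted

#' @describeIn runPipeline Run-log accessor (per-stage counts).
#' @export
runLog <- function(x) x@log
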