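#' Default heading keywords for record scanning
#'
#' Section headings are matched by case-insensitive substring against these
#' keyword lists: \code{tox} collects toxicity-related sections (e.g. "GHS
#' Classification", "Toxicity Summary", "Safety and Hazards"), \code{food}
#' collects food-safety sections (e.g. "Food Additives and Ingredients").
#' Both lists are user-overridable in the run configuration.
#'
#' @return List with character vectors \code{tox} and \code{food}.
#' @export
defaultKeywords <- function() {
  list(tox = c("toxic", "ghs", "hazard", "safety"), food = c("food"))
}

#' Scan a compound record for toxicity and food-safety fields
#'
#' Depth-first traversal of the record's section tree collecting every
#' section whose heading contains (case-insensitively) one of the configured
#' toxicity or food-safety keywords. A record with no matching section
#' anywhere yields empty results and is routed downstream to the
#' \emph{unchecked} partition.
#'
#' @param record A \code{\linkS4class{CompoundRecord}}.
#' @param keywords Keyword configuration, see \code{\link{defaultKeywords}}.
#' @return List of class \code{RelevantFields} with \code{tox} and
#'   \code{food}: lists of \code{list(heading, content)} in traversal order.
#' @export
scanRecord <- function(record, keywords = defaultKeywords()) {
  tox <- list()
  food <- list()
  matchAny <- function(heading, keys) {
    h <- tolower(heading)
    any(vapply(keys, function(k) grepl(tolower(k), h, fixed = TRUE), logical(1)))
  }
  walk <- function(sections) {
    for (s in sections) {
      hit <- list(heading = s$heading, content = s$content)
      if (matchAny(s$heading, keywords$tox)) tox[[length(tox) + 1L]] <<- hit
      if (matchAny(s$heading, keywords$food)) food[[length(food) + 1L]] <<- hit
      walk(s$children %||% list())
    }
  }
  walk(record@sections)
  structure(list(tox = tox, food = food), class = "RelevantFields")
}

#' Extract GHS hazard-statement codes from scanned fields
#'
#' Collects every substring of the form \code{H} followed by exactly three
#' digits from the content of the toxicity sections. Food-safety sections are
#' carried as evidence only and never contribute codes.
#'
#' @param fields Result of \code{\link{scanRecord}}.
#' @return Sorted character vector (a set) of hazard codes, e.g.
#'   \code{c("H302")}.
#' @export
extractHazardCodes <- function(fields) {
  text <- unlist(lapply(fields$tox, `[[`, "content"))
  if (length(text) == 0) return(character(0))
  hits <- regmatches(text, gregexpr("H[0-9]{3}(?![0-9])", text, perl = TRUE))
  sort(unique(unlist(hits)))
}

# hazard-statement code -> (family, GHS category) map.
# Oral (H300-303), dermal (H310-313) and inhalation (H330-333) acute codes
# collapse to one AcuteToxic level per position, since the category labels
# carry no exposure route. H300/H310/H330 span GHS categories 1-2; the less
# extreme category (2) is reported.
hazardCodeMap <- function() {
  acute <- function(codes) {
    stats::setNames(lapply(2:5, function(l) list(family = "AcuteToxic", level = l)), codes)
  }
  c(acute(c("H300", "H301", "H302", "H303")),
    acute(c("H310", "H311", "H312", "H313")),
    acute(c("H330", "H331", "H332", "H333")),
    list(
      H315 = list(family = "SkinIrritant", level = 2L),
      H318 = list(family = "EyeIrritant", level = 1L),
      H319 = list(family = "EyeIrritant", level = 2L)
    ))
}

#' Classify hazard codes into one of five severity categories
#'
#' Maps each known hazard-statement code to a category family and GHS level,
#' then keeps the single highest-severity classification. The five families,
#' in decreasing severity, are Acute toxic (levels 1-5), Skin and eye
#' irritant, Eye irritant, Skin irritant, and Potentially toxic (assigned
#' when no mapped code is present, i.e. toxicity fields exist but carry no
#' hazard statement). When both a skin-irritation and an eye-irritation code
#' are present the combined Skin-and-eye family applies, at the more severe
#' of the two category levels. Unknown codes are ignored with a warning,
#' never fatal. Monotone: adding codes can only raise the severity.
#'
#' @param codes Character vector (set) of hazard codes, e.g.
#'   \code{c("H315", "H319")}.
#' @return A \code{\linkS4class{ToxClassification}}.
#' @examples
#' classificationLabel(classifyCodes("H302"))           # "Acute toxic 4"
#' classificationLabel(classifyCodes(c("H315","H319"))) # "Skin and eye irritant 2"
#' classificationLabel(classifyCodes(character(0)))     # "Potentially toxic"
#' @export
classifyCodes <- function(codes) {
  codes <- unique(as.character(codes))
  map <- hazardCodeMap()
  unknown <- setdiff(codes, names(map))
  if (length(unknown) > 0) {
    warning("ignoring unmapped hazard code(s): ", paste(sort(unknown), collapse = ", "))
  }
  codes <- intersect(codes, names(map))
  if (length(codes) == 0) return(toxClassification("PotentiallyToxic"))
  cand <- lapply(codes, function(code) {
    m <- map[[code]]
    list(family = m$family, level = m$level, evidence = code)
  })
  skin <- codes[vapply(codes, function(c) map[[c]]$family == "SkinIrritant", logical(1))]
  eye <- codes[vapply(codes, function(c) map[[c]]$family == "EyeIrritant", logical(1))]
  if (length(skin) > 0 && length(eye) > 0) {
    lvl <- min(vapply(c(skin, eye), function(c) map[[c]]$level, integer(1)))
    cand[[length(cand) + 1L]] <- list(family = "SkinAndEyeIrritant", level = lvl,
                                      evidence = c(skin, eye))
  }
  ranks <- vapply(cand, function(x) severityRank(x$family, x$level), numeric(1))
  best <- cand[[which.max(ranks)]]
  toxClassification(best$family, best$level, sort(unique(best$evidence)))
}

#' Resolve, fetch and classify one candidate compound
#'
#' Runs the record-retrieval and classification chain for one matched
#' candidate name: resolve the name to CIDs, fetch up to \code{cidCap}
#' records, scan each for toxicity/food-safety fields, and classify on the
#' extracted hazard codes, keeping the maximum severity over all fetched
#' records. Routing: no CID or no retrievable record gives \code{unfound};
#' records present but none carrying a relevant field gives \code{unchecked};
#' otherwise \code{classified}. A provider transport error routes the
#' candidate conservatively to \code{unfound} with an error note, never
#' aborting the run.
#'
#' @param name Candidate compound name (from the toxic table).
#' @param provider A \code{\linkS4class{RecordProvider}}.
#' @param keywords Scanning keywords, see \code{\link{defaultKeywords}}.
#' @param cidCap Maximum number of CIDs fetched per name (default 3).
#' @return List with \code{outcome} (\code{"classified"}, \code{"unchecked"}
#'   or \code{"unfound"}), \code{classification}
#'   (\code{\linkS4class{ToxClassification}} or \code{NULL}),
#'   \code{resolvedName} (record name when found, else the input name) and
#'   \code{note}.
#' @export
classifyCompound <- function(name, provider, keywords = defaultKeywords(),
                             cidCap = 3) {
  cids <- tryCatch(resolveName(provider, name),
                   toxscreenTransport = function(e) e)
  if (inherits(cids, "toxscreenTransport")) {
    return(list(outcome = "unfound", classification = NULL, resolvedName = name,
                note = paste0("provider error: ", conditionMessage(cids))))
  }
  if (length(cids) == 0) {
    return(list(outcome = "unfound", classification = NULL, resolvedName = name,
                note = "no matching record"))
  }
  cids <- utils::head(cids, cidCap)
  records <- list()
  notes <- character(0)
  for (cid in cids) {
    rec <- tryCatch(fetchRecord(provider, cid),
                    toxscreenNotFound = function(e) NULL,
                    toxscreenTransport = function(e) {
                      notes <<- c(notes, conditionMessage(e))
                      NULL
                    })
    if (!is.null(rec)) records[[length(records) + 1L]] <- rec
  }
  if (length(records) == 0) {
    return(list(outcome = "unfound", classification = NULL, resolvedName = name,
                note = paste(c("no retrievable record", notes), collapse = "; ")))
  }
  scans <- lapply(records, scanRecord, keywords = keywords)
  relevant <- vapply(scans, function(f) length(f$tox) + length(f$food) > 0, logical(1))
  if (!any(relevant)) {
    return(list(outcome = "unchecked", classification = NULL,
                resolvedName = records[[1]]@name,
                note = "record has no toxicity or food-safety fields"))
  }
  cls <- lapply(which(relevant), function(i) classifyCodes(extractHazardCodes(scans[[i]])))
  ranks <- vapply(cls, classificationRank, numeric(1))
  list(outcome = "classified", classification = cls[[which.max(ranks)]],
       resolvedName = records[[which(relevant)[which.max(ranks)]]]@name,
       note = "")
}

#' Format the merged toxic report
#'
#' Second formatting pass over the cross-sample merged toxic table: rows are
#' grouped by the five category families in decreasing severity (a
#' \code{category} column names the group), sorted within group by severity
#' rank then name, with all per-sample/per-mode presence columns carried
#' through. Deterministic: identical input gives byte-identical output.
#'
#' @param merged Merged toxic data frame (from \code{\link{mergeSamples}}).
#' @param path Optional CSV path; when non-empty the formatted table is
#'   written there.
#' @return The formatted data frame, invisibly when written, visibly
#'   otherwise.
#' @export
formatToxicReport <- function(merged, path = "") {
  familyStem <- c(AcuteToxic = "Acute toxic",
                  SkinAndEyeIrritant = "Skin and eye irritant",
                  EyeIrritant = "Eye irritant", SkinIrritant = "Skin irritant",
                  PotentiallyToxic = "Potentially toxic")
  if (nrow(merged) == 0) {
    out <- cbind(data.frame(category = character(0)), merged)
  } else {
    parsed <- lapply(merged$classification, parseToxLabel)
    fam <- vapply(parsed, `[[`, character(1), "family")
    rank <- vapply(parsed, `[[`, numeric(1), "rank")
    ord <- order(match(fam, names(familyStem)), -rank,
                 normalizeName(merged$name), merged$name)
    out <- cbind(data.frame(category = unname(familyStem[fam[ord]])),
                 merged[ord, , drop = FALSE])
    rownames(out) <- NULL
  }
  if (nzchar(path)) {
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
    return(invisible(out))
  }
  out
}
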