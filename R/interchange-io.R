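#' Default column mapping for assigned-formula tables
#'
#' Column names of the upstream formula-assignment CSV are not standardized;
#' these defaults follow the common naming of unambiguous-assignment output
#' (\code{formula}, \code{exp_mass}, \code{abundance}, \code{RT}) and can be
#' overridden per file.
#'
#' @return Named character vector with entries \code{formula}, \code{mass},
#'   \code{abundance}, \code{rt}.
#' @export
defaultColumnMap <- function() {
  c(formula = "formula", mass = "exp_mass", abundance = "abundance", rt = "RT")
}

featureColumns <- c("row m/z", "peak area", "row retention time")

readCsvChecked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

numericColumn <- function(df, col, path) {
  raw <- df[[col]]
  x <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(x) & !is.na(raw) & nzchar(trimws(as.character(raw))))
  if (length(bad) > 0) {
    stop("non-numeric value in column '", col, "' at row ", bad[1],
         " of ", path, ": '", raw[bad[1]], "'")
  }
  x
}

#' Read an upstream LC/MS feature table
#'
#' Reads the CSV interchange format exported by peak-picking software: one
#' row per deconvoluted feature with columns \code{row m/z}, \code{peak area}
#' and \code{row retention time}. The downstream formula-assignment stage
#' requires exactly that left-to-right column order, so \code{strictOrder =
#' TRUE} enforces it and rejects any other permutation.
#'
#' @param path CSV file with a header row.
#' @param strictOrder Require the three columns in the stated order.
#' @return Data frame with columns \code{mz}, \code{peakArea},
#'   \code{retentionTime}, one row per feature in file order.
#' @export
readFeatureTable <- function(path, strictOrder = FALSE) {
  df <- readCsvChecked(path)
  missing <- setdiff(featureColumns, names(df))
  if (length(missing) > 0) {
    stop("feature table ", path, " is missing required column(s): ",
         paste0("'", missing, "'", collapse = ", "))
  }
  if (strictOrder && !identical(names(df)[seq_len(3)], featureColumns)) {
    stop("column-order violation in ", path, ": expected '",
         paste(featureColumns, collapse = "', '"),
         "' left to right, found '",
         paste(utils::head(names(df), 3), collapse = "', '"), "'")
  }
  out <- data.frame(
    mz = numericColumn(df, "row m/z", path),
    peakArea = numericColumn(df, "peak area", path),
    retentionTime = numericColumn(df, "row retention time", path)
  )
  if (any(out$mz <= 0, na.rm = TRUE)) stop("feature table ", path, " has non-positive m/z")
  if (any(out$peakArea < 0, na.rm = TRUE)) stop("feature table ", path, " has negative peak area")
  if (any(out$retentionTime < 0, na.rm = TRUE)) stop("feature table ", path, " has negative retention time")
  out
}

#' Read an assigned-formula table
#'
#' Reads the CSV written by the molecular-formula assignment stage (one row
#' per monoisotopic feature with its assigned neutral formula), parses each
#' formula into element counts and stamps the electrospray ionization mode on
#' every record. The stated mass is checked against the monoisotopic mass
#' computed from the formula: rows disagreeing beyond \code{ppmTol} are
#' flagged (\code{massFlag = TRUE}) with a warning but never dropped, because
#' downstream matching is by formula, not mass.
#'
#' @param path CSV file with a header.
#' @param columnMap Named character vector mapping the roles \code{formula},
#'   \code{mass}, \code{abundance}, \code{rt} to column names in the file;
#'   see \code{\link{defaultColumnMap}}.
#' @param ionMode \code{"positive"} or \code{"negative"}.
#' @param ppmTol Mass/formula consistency tolerance in ppm (default 3, the
#'   usual assignment error bound).
#' @param ambiguous Logical flag stored on every record; the unambiguous
#'   assignment list is the default input, ambiguous lists are opt-in.
#' @return Data frame with columns \code{formula} (as read), \code{canonical}
#'   (Hill notation), \code{neutralMass}, \code{abundance},
#'   \code{retentionTime}, \code{ionMode}, \code{ambiguous}, \code{massFlag}.
#' @export
readAssignedFormulas <- function(path, columnMap = defaultColumnMap(),
                                 ionMode = c("negative", "positive"),
                                 ppmTol = 3, ambiguous = FALSE) {
  ionMode <- match.arg(ionMode)
  df <- readCsvChecked(path)
  need <- c("formula", "mass", "abundance", "rt")
  if (!all(need %in% names(columnMap))) {
    stop("columnMap must name the roles: ", paste(need, collapse = ", "))
  }
  missing <- setdiff(unname(columnMap[need]), names(df))
  if (length(missing) > 0) {
    stop("assigned-formula table ", path, " is missing column(s): ",
         paste0("'", missing, "'", collapse = ", "),
         " (override columnMap to match your file)")
  }
  n <- nrow(df)
  if (n == 0) {
    return(data.frame(formula = character(0), canonical = character(0),
                      neutralMass = numeric(0), abundance = numeric(0),
                      retentionTime = numeric(0), ionMode = character(0),
                      ambiguous = logical(0), massFlag = logical(0)))
  }
  formulas <- as.character(df[[columnMap[["formula"]]]])
  canonical <- character(n)
  computed <- numeric(n)
  for (i in seq_len(n)) {
    counts <- tryCatch(parseFormula(formulas[i]), error = function(e) {
      stop("row ", i, " of ", path, ": ", conditionMessage(e), call. = FALSE)
    })
    if (!all(c("C", "H") %in% names(counts))) {
      stop("row ", i, " of ", path, ": formula '", formulas[i],
           "' lacks carbon or hydrogen", call. = FALSE)
    }
    canonical[i] <- hillFormat(counts)
    computed[i] <- monoisotopicMass(counts)
  }
  mass <- numericColumn(df, columnMap[["mass"]], path)
  ppm <- (mass - computed) / computed * 1e6
  massFlag <- abs(ppm) > ppmTol
  if (any(massFlag)) {
    warning(sum(massFlag), " row(s) in ", path, " disagree with the ",
            "formula-computed monoisotopic mass beyond ", ppmTol,
            " ppm (flagged, not dropped)")
  }
  data.frame(
    formula = formulas,
    canonical = canonical,
    neutralMass = mass,
    abundance = numericColumn(df, columnMap[["abundance"]], path),
    retentionTime = numericColumn(df, columnMap[["rt"]], path),
    ionMode = rep(ionMode, n),
    ambiguous = rep(isTRUE(ambiguous), n),
    massFlag = massFlag
  )
}

#' Read a local toxic-compound table
#'
#' Reads the local table of candidate toxic compounds (an OpenFoodTox/TPPT
#' style extract) with columns \code{name}, \code{formula},
#' \code{monoisotopic_mass}, \code{source} and optional \code{safety_class}.
#' Formulas are parsed and canonicalized; rows whose formula fails to parse
#' are skipped with a warning (the skipped count is returned as attribute
#' \code{"skipped"}); duplicate (name, formula) rows keep the first.
#'
#' @param path CSV file.
#' @return Data frame with columns \code{name}, \code{formula},
#'   \code{canonical}, \code{monoisotopicMass}, \code{source},
#'   \code{safetyClass}.
#' @export
readToxicTable <- function(path) {
  df <- readCsvChecked(path)
  need <- c("name", "formula", "monoisotopic_mass", "source")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("toxic table ", path, " is missing required column(s): ",
         paste0("'", missing, "'", collapse = ", "))
  }
  n <- nrow(df)
  canonical <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    canonical[i] <- tryCatch(canonicalFormula(as.character(df$formula[i])),
                             error = function(e) NA_character_)
  }
  skipped <- sum(is.na(canonical))
  if (skipped > 0) {
    warning("skipped ", skipped, " toxic-table row(s) with unparsable formulas in ", path)
  }
  keep <- !is.na(canonical)
  out <- data.frame(
    name = as.character(df$name[keep]),
    formula = as.character(df$formula[keep]),
    canonical = canonical[keep],
    monoisotopicMass = numericColumn(df[keep, , drop = FALSE], "monoisotopic_mass", path),
    source = as.character(df$source[keep]),
    safetyClass = if ("safety_class" %in% names(df)) as.character(df$safety_class[keep]) else rep("", sum(keep))
  )
  if (any(!nzchar(out$name))) stop("toxic table ", path, " has empty compound names")
  if (any(out$monoisotopicMass <= 0)) stop("toxic table ", path, " has non-positive masses")
  dup <- duplicated(paste(normalizeName(out$name), out$canonical, sep = "\r"))
  out <- out[!dup, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

reportColumns <- function(kind) {
  switch(kind,
    toxic = c(name = "c", formula = "c", classification = "c", evidence = "c"),
    unfound = c(name = "c", formula = "c", note = "c"),
    unchecked = c(name = "c", formula = "c"),
    safe = c(name = "c", safetyClass = "c"),
    stop("unknown report kind: ", kind)
  )
}

emptyReport <- function(kind, presence = character(0)) {
  base <- names(reportColumns(kind))
  cols <- c(stats::setNames(rep(list(character(0)), length(base)), base),
            stats::setNames(rep(list(logical(0)), length(presence)), presence))
  as.data.frame(cols, check.names = FALSE)
}

sortReport <- function(records, kind) {
  if (nrow(records) == 0) return(records)
  ord <- if (kind == "toxic") {
    rank <- vapply(records$classification, function(l) parseToxLabel(l)$rank, numeric(1))
    order(-rank, normalizeName(records$name), records$name)
  } else {
    order(normalizeName(records$name), records$name)
  }
  out <- records[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a screening report CSV
#'
#' Writes one homogeneous report of classified (\code{toxic}), record-less
#' (\code{unfound}), record-without-toxicity-fields (\code{unchecked}) or
#' locally matched (\code{safe}) compounds. Column order is fixed per kind
#' and rows are sorted deterministically (toxic: severity rank descending,
#' then name; others: by name), so identical inputs give byte-identical
#' files. \code{\link{readReport}} inverts the write exactly.
#'
#' @param records Data frame with the kind's base columns (see Details) and
#'   optionally logical presence columns (e.g. \code{inPos}, \code{inNeg}).
#' @param path Output CSV path.
#' @param kind One of \code{"toxic"}, \code{"unfound"}, \code{"unchecked"},
#'   \code{"safe"}.
#' @return The sorted data frame, invisibly.
#' @export
writeReport <- function(records, path, kind = c("toxic", "unfound", "unchecked", "safe")) {
  kind <- match.arg(kind)
  base <- names(reportColumns(kind))
  missing <- setdiff(base, names(records))
  if (length(missing) > 0) {
    stop(kind, " report requires column(s): ", paste(missing, collapse = ", "))
  }
  presence <- setdiff(names(records), base)
  records <- records[, c(base, presence), drop = FALSE]
  records <- sortReport(records, kind)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  ok <- tryCatch({
    utils::write.csv(records, path, row.names = FALSE, quote = TRUE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write report to ", path, ": ", conditionMessage(ok))
  invisible(records)
}

#' Read back a screening report CSV
#'
#' @param path Report CSV written by \code{\link{writeReport}}.
#' @param kind Report kind (fixes the expected base columns and their types).
#' @return Data frame identical to the one \code{writeReport} returned.
#' @export
readReport <- function(path, kind = c("toxic", "unfound", "unchecked", "safe")) {
  kind <- match.arg(kind)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  base <- reportColumns(kind)
  missing <- setdiff(names(base), names(df))
  if (length(missing) > 0) {
    stop("report ", path, " is missing column(s): ", paste(missing, collapse = ", "))
  }
  for (col in names(base)) {
    df[[col]] <- as.character(df[[col]])
    df[[col]][is.na(df[[col]])] <- ""
  }
  for (col in setdiff(names(df), names(base))) df[[col]] <- as.logical(df[[col]])
  df
}
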