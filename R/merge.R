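#' Read a local table of previously resolved records
#'
#' The local table records compounds that earlier runs could not resolve in
#' the record database and that were then looked up by hand: columns
#' \code{name}, \code{safety_class} (one of the five classification labels,
#' with level where applicable, or \code{"excluded"}) and optional
#' \code{note}.
#'
#' @param path CSV file.
#' @return Data frame with columns \code{name}, \code{safetyClass},
#'   \code{note}.
#' @export
readLocalTable <- function(path) {
  df <- readCsvChecked(path)
  need <- c("name", "safety_class")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("local table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  out <- data.frame(
    name = as.character(df$name),
    safetyClass = as.character(df$safety_class),
    note = if ("note" %in% names(df)) as.character(df$note) else rep("", nrow(df))
  )
  if (any(!nzchar(out$name))) stop("local table ", path, " has empty names")
  for (cls in out$safetyClass) parseToxLabel(cls) # validates, errors on junk
  out
}

#' Match unfound compounds against the local record table
#'
#' Compounds with no retrievable database record are matched by normalized
#' name (case-insensitive, stereo-descriptor prefixes stripped) against the
#' local table. Matched names are returned with their recorded safety class;
#' the rest stay unfound, to be added to the local table after a manual
#' search. Partition: every input name lands in exactly one of the two
#' outputs.
#'
#' @param unfound Character vector of compound names.
#' @param table Data frame from \code{\link{readLocalTable}} (may have zero
#'   rows).
#' @return List with \code{found} (data frame \code{name},
#'   \code{safetyClass}) and \code{stillUnfound} (character vector).
#' @export
matchLocal <- function(unfound, table) {
  if (length(unfound) == 0) {
    return(list(found = data.frame(name = character(0), safetyClass = character(0)),
                stillUnfound = character(0)))
  }
  key <- normalizeName(table$name, stripStereo = TRUE)
  qkey <- normalizeName(unfound, stripStereo = TRUE)
  hit <- match(qkey, key)
  list(
    found = data.frame(name = unfound[!is.na(hit)],
                       safetyClass = table$safetyClass[hit[!is.na(hit)]]),
    stillUnfound = unfound[is.na(hit)]
  )
}

moreSevere <- function(a, b) {
  if (parseToxLabel(a)$rank >= parseToxLabel(b)$rank) a else b
}

#' Combine positive- and negative-mode rows into per-sample rows
#'
#' The same sample is run in both electrospray ionization polarities; this
#' unions the two per-mode result tables by normalized compound name. A
#' compound seen in both modes appears once with both mode flags set. When
#' the two modes disagree on a toxic classification the higher severity is
#' kept and a conflict warning is logged.
#'
#' @param pos,neg Data frames of the same report kind with at least a
#'   \code{name} column (toxic kind: also \code{classification},
#'   \code{evidence}).
#' @param kind Report kind, one of \code{"toxic"}, \code{"unfound"},
#'   \code{"unchecked"}, \code{"safe"}.
#' @return Data frame with the kind's base columns plus logical \code{inPos}
#'   and \code{inNeg}, sorted deterministically.
#' @export
combineModes <- function(pos, neg, kind = c("toxic", "unfound", "unchecked", "safe")) {
  kind <- match.arg(kind)
  base <- names(reportColumns(kind))
  pos <- if (is.null(pos)) emptyReport(kind) else pos
  neg <- if (is.null(neg)) emptyReport(kind) else neg
  rows <- list()
  addRow <- function(row, mode) {
    k <- normalizeName(row$name, stripStereo = TRUE)
    if (is.null(rows[[k]])) {
      entry <- as.list(row[base])
      entry$inPos <- mode == "pos"
      entry$inNeg <- mode == "neg"
      rows[[k]] <<- entry
    } else {
      entry <- rows[[k]]
      if (mode == "pos") entry$inPos <- TRUE else entry$inNeg <- TRUE
      if (kind == "toxic" && !identical(entry$classification, row$classification)) {
        kept <- moreSevere(entry$classification, row$classification)
        warning("classification conflict for '", row$name, "' across modes: '",
                entry$classification, "' vs '", row$classification,
                "'; keeping '", kept, "'")
        if (!identical(kept, entry$classification)) {
          entry$classification <- row$classification
          entry$evidence <- row$evidence
        }
      }
      rows[[k]] <<- entry
    }
  }
  for (i in seq_len(nrow(pos))) addRow(pos[i, , drop = FALSE], "pos")
  for (i in seq_len(nrow(neg))) addRow(neg[i, , drop = FALSE], "neg")
  if (length(rows) == 0) return(emptyReport(kind, presence = c("inPos", "inNeg")))
  out <- do.call(rbind, lapply(rows, function(e) as.data.frame(e, check.names = FALSE)))
  rownames(out) <- NULL
  sortReport(out, kind)
}

#' Merge per-sample reports across samples
#'
#' Union join keyed on the normalized compound name — the one column all
#' per-sample tables share — producing one merged report per kind with a
#' presence flag per sample and mode. Run once each for the toxic, unfound
#' and unchecked data. No sample's compounds are dropped under the default
#' union; an intersection (compounds present in every sample) is available
#' via \code{how = "intersection"}. Cross-sample classification conflicts
#' resolve to the higher severity with a warning. Commutative and
#' associative over samples up to row order, and idempotent on duplicated
#' samples.
#'
#' @param samples Named list (sample id -> data frame from
#'   \code{\link{combineModes}}, i.e. base columns plus \code{inPos}/
#'   \code{inNeg}).
#' @param kind Report kind.
#' @param how \code{"union"} (default) or \code{"intersection"}.
#' @return Merged data frame: base columns, then \code{<sample>_pos} /
#'   \code{<sample>_neg} logical columns for every sample in name order.
#' @export
mergeSamples <- function(samples, kind = c("toxic", "unfound", "unchecked", "safe"),
                         how = c("union", "intersection")) {
  kind <- match.arg(kind)
  how <- match.arg(how)
  if (length(samples) == 0) stop("at least one sample is required")
  if (is.null(names(samples)) || any(!nzchar(names(samples)))) {
    stop("samples must be a named list (sample ids)")
  }
  ids <- sort(names(samples))
  base <- names(reportColumns(kind))
  rows <- list()
  seenIn <- list()
  for (id in ids) {
    df <- samples[[id]]
    for (i in seq_len(nrow(df))) {
      row <- df[i, , drop = FALSE]
      k <- normalizeName(row$name, stripStereo = TRUE)
      seenIn[[k]] <- unique(c(seenIn[[k]], id))
      if (is.null(rows[[k]])) {
        entry <- as.list(row[base])
        for (s in ids) {
          entry[[paste0(s, "_pos")]] <- FALSE
          entry[[paste0(s, "_neg")]] <- FALSE
        }
        rows[[k]] <- entry
      }
      entry <- rows[[k]]
      entry[[paste0(id, "_pos")]] <- entry[[paste0(id, "_pos")]] || isTRUE(row$inPos)
      entry[[paste0(id, "_neg")]] <- entry[[paste0(id, "_neg")]] || isTRUE(row$inNeg)
      if (kind == "toxic" && !identical(entry$classification, row$classification)) {
        kept <- moreSevere(entry$classification, row$classification)
        warning("classification conflict for '", row$name, "' across samples: '",
                entry$classification, "' vs '", row$classification,
                "'; keeping '", kept, "'")
        if (!identical(kept, entry$classification)) {
          entry$classification <- row$classification
          entry$evidence <- row$evidence
        }
      }
      rows[[k]] <- entry
    }
  }
  if (how == "intersection") {
    keep <- vapply(names(rows), function(k) length(seenIn[[k]]) == length(unique(ids)),
                   logical(1))
    rows <- rows[keep]
  }
  presence <- as.vector(t(outer(ids, c("_pos", "_neg"), paste0)))
  if (length(rows) == 0) return(emptyReport(kind, presence = presence))
  out <- do.call(rbind, lapply(rows, function(e) as.data.frame(e, check.names = FALSE)))
  rownames(out) <- NULL
  sortReport(out, kind)
}
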