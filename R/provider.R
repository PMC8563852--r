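notFoundError <- function(msg) {
  stop(structure(class = c("toxscreenNotFound", "error", "condition"),
                 list(message = msg, call = NULL)))
}

transportError <- function(msg) {
  stop(structure(class = c("toxscreenTransport", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Minimum-interval rate limiter
#'
#' Environment-based limiter guaranteeing that consecutive acquisitions are
#' at least \code{minInterval} seconds apart (default 0.2 s — a fifth of a
#' second between requests, so a shared public record service is never
#' overloaded). The clock and sleep functions are injectable, so the spacing
#' contract can be verified with a fake clock and no real waiting.
#'
#' @param minInterval Minimum seconds between acquisitions.
#' @param clock Zero-argument function returning the current time in seconds.
#' @param wait Function(seconds) that blocks for that long.
#' @return A \code{RateLimiter} environment; pass to
#'   \code{\link{acquireRateLimit}}.
#' @examples
#' t <- 0
#' lim <- rateLimiter(clock = function() t, wait = function(s) t <<- t + s)
#' acquireRateLimit(lim); acquireRateLimit(lim)
#' diff(requestTimes(lim)) # >= 0.2
#' @export
rateLimiter <- function(minInterval = 0.2,
                        clock = function() proc.time()[["elapsed"]],
                        wait = Sys.sleep) {
  env <- new.env(parent = emptyenv())
  env$minInterval <- minInterval
  env$clock <- clock
  env$wait <- wait
  env$last <- -Inf
  env$stamps <- numeric(0)
  env
}

#' @describeIn rateLimiter Block until the minimum interval since the last
#'   acquisition has elapsed, then record the request timestamp.
#' @param limiter A \code{RateLimiter}.
#' @export
acquireRateLimit <- function(limiter) {
  now <- limiter$clock()
  gap <- now - limiter$last
  if (gap < limiter$minInterval) {
    limiter$wait(limiter$minInterval - gap)
    now <- limiter$clock()
  }
  limiter$last <- now
  limiter$stamps <- c(limiter$stamps, now)
  invisible(now)
}

#' @describeIn rateLimiter Timestamps of all acquisitions so far.
#' @export
requestTimes <- function(limiter) limiter$stamps

sectionsFromList <- function(x) {
  lapply(x, function(s) {
    recordSection(
      heading = as.character(s$heading %||% ""),
      content = as.character(unlist(s$content %||% character(0))),
      children = sectionsFromList(s$children %||% list())
    )
  })
}

sectionsToList <- function(sections) {
  lapply(sections, function(s) {
    list(heading = s$heading, content = as.list(s$content),
         children = sectionsToList(s$children %||% list()))
  })
}

#' Read one compound-record JSON file
#'
#' The fixture schema mirrors a hierarchical Record/Section layout:
#' \code{\{"cid": int, "name": str, "sections": [\{"heading", "content",
#' "children"\}, ...]\}}, so real downloaded records converted to this shape
#' drop in unchanged. Schema violations are reported naming the offending
#' node.
#'
#' @param path JSON file path.
#' @return A \code{\linkS4class{CompoundRecord}}.
#' @export
readRecordJson <- function(path) {
  x <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                error = function(e) stop("invalid JSON in ", path, ": ",
                                         conditionMessage(e), call. = FALSE))
  for (node in c("cid", "name", "sections")) {
    if (is.null(x[[node]])) {
      stop("record ", path, " violates the schema: missing node '", node, "'",
           call. = FALSE)
    }
  }
  rec <- tryCatch(
    compoundRecord(cid = x$cid, name = as.character(x$name),
                   sections = sectionsFromList(x$sections)),
    error = function(e) stop("record ", path, " violates the schema: ",
                             conditionMessage(e), call. = FALSE))
  rec
}

#' Write a compound record as fixture-format JSON
#'
#' @param record A \code{\linkS4class{CompoundRecord}}.
#' @param path Output JSON path.
#' @export
writeRecordJson <- function(record, path) {
  jsonlite::write_json(
    list(cid = record@cid, name = record@name,
         sections = sectionsToList(record@sections)),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

buildStore <- function(records, path = "") {
  byCid <- list()
  nameIndex <- list()
  for (rec in records) {
    key <- as.character(rec@cid)
    byCid[[key]] <- rec
    for (k in nameKeys(rec@name)) {
      have <- nameIndex[[k]] %||% numeric(0)
      if (!rec@cid %in% have) nameIndex[[k]] <- c(have, rec@cid)
    }
  }
  new("FixtureStore", records = byCid, nameIndex = nameIndex, path = path)
}

#' Load a local JSON record store
#'
#' Reads every \code{*.json} file in a directory as a compound record and
#' builds an in-memory provider with a case-insensitive, stereo-prefix-aware
#' name index. Files are loaded in sorted name order, so CID order under a
#' shared name is deterministic. If any file violates the record schema the
#' load fails listing all offending files. Two records sharing a name are
#' both retained under that name.
#'
#' @param path Directory of JSON record files.
#' @return A \code{\linkS4class{FixtureStore}}.
#' @export
loadFixtureStore <- function(path) {
  if (!dir.exists(path)) stop("record store directory not found: ", path)
  files <- sort(list.files(path, pattern = "\\.json$", full.names = TRUE))
  records <- list()
  bad <- character(0)
  for (f in files) {
    rec <- tryCatch(readRecordJson(f), error = function(e) {
      bad <<- c(bad, paste0(basename(f), " (", conditionMessage(e), ")"))
      NULL
    })
    if (!is.null(rec)) records[[length(records) + 1L]] <- rec
  }
  if (length(bad) > 0) {
    stop("schema-invalid record file(s) in ", path, ":\n  ",
         paste(bad, collapse = "\n  "))
  }
  buildStore(records, path = path)
}

#' @describeIn loadFixtureStore Build a store directly from records in
#'   memory (used by tests and generators).
#' @param records List of \code{CompoundRecord} objects.
#' @export
fixtureStore <- function(records) buildStore(records)

#' @rdname resolveName
#' @export
setMethod("resolveName", "FixtureStore", function(provider, name, ...) {
  if (!nzchar(trimws(name))) stop("compound name must be non-empty")
  for (k in nameKeys(name)) {
    hit <- provider@nameIndex[[k]]
    if (!is.null(hit)) return(hit)
  }
  numeric(0)
})

#' @rdname fetchRecord
#' @export
setMethod("fetchRecord", "FixtureStore", function(provider, cid, ...) {
  if (cid <= 0) stop("cid must be positive")
  rec <- provider@records[[as.character(cid)]]
  if (is.null(rec)) notFoundError(paste0("no record for CID ", cid))
  rec
})

defaultTransport <- function(url) {
  res <- tryCatch(jsonlite::fromJSON(url, simplifyVector = FALSE),
                  error = function(e) e)
  if (inherits(res, "error")) {
    msg <- conditionMessage(res)
    if (grepl("404", msg)) notFoundError(paste0("HTTP 404 for ", url))
    transportError(msg)
  }
  res
}

#' Construct a live HTTP record provider
#'
#' @param baseUrl Base URL of a PUG-REST style service exposing
#'   \code{/compound/name/<name>/cids/JSON} and a per-CID full-record view.
#' @param minInterval Minimum seconds between requests (default 0.2).
#' @param retries Retry attempts for transient transport failures (default 3,
#'   with linearly growing backoff through the limiter's wait function).
#' @param transport Function(url) returning parsed JSON; injectable for
#'   testing. The default uses \code{jsonlite::fromJSON} over HTTP.
#' @param clock,wait Injected into the rate limiter (see
#'   \code{\link{rateLimiter}}).
#' @param cacheDir Optional directory; fetched records are written there in
#'   fixture JSON format and re-read on later fetches, easing load on the
#'   remote service.
#' @return A \code{\linkS4class{LiveProvider}}.
#' @export
liveProvider <- function(baseUrl = "https://pubchem.ncbi.nlm.nih.gov/rest",
                         minInterval = 0.2, retries = 3,
                         transport = defaultTransport,
                         clock = function() proc.time()[["elapsed"]],
                         wait = Sys.sleep, cacheDir = "") {
  new("LiveProvider", baseUrl = baseUrl,
      limiter = rateLimiter(minInterval, clock, wait),
      transport = transport, retries = retries, cacheDir = cacheDir)
}

withRetries <- function(provider, thunk) {
  attempt <- 0
  repeat {
    acquireRateLimit(provider@limiter)
    res <- tryCatch(thunk(), toxscreenTransport = function(e) e)
    if (!inherits(res, "toxscreenTransport")) return(res)
    attempt <- attempt + 1
    if (attempt > provider@retries) {
      transportError(paste0("transport failed after ", provider@retries,
                            " retries: ", conditionMessage(res)))
    }
    provider@limiter$wait(provider@limiter$minInterval * attempt)
  }
}

#' @rdname resolveName
#' @export
setMethod("resolveName", "LiveProvider", function(provider, name, ...) {
  if (!nzchar(trimws(name))) stop("compound name must be non-empty")
  url <- paste0(provider@baseUrl, "/pug/compound/name/",
                utils::URLencode(name, reserved = TRUE), "/cids/JSON")
  res <- tryCatch(withRetries(provider, function() provider@transport(url)),
                  toxscreenNotFound = function(e) NULL)
  if (is.null(res)) return(numeric(0))
  cids <- unlist(res$IdentifierList$CID %||% list())
  as.numeric(cids)
})

#' @rdname fetchRecord
#' @export
setMethod("fetchRecord", "LiveProvider", function(provider, cid, ...) {
  if (cid <= 0) stop("cid must be positive")
  if (nzchar(provider@cacheDir)) {
    cached <- file.path(provider@cacheDir, paste0("cid_", cid, ".json"))
    if (file.exists(cached)) return(readRecordJson(cached))
  }
  url <- paste0(provider@baseUrl, "/pug_view/data/compound/", cid, "/JSON")
  res <- withRetries(provider, function() provider@transport(url))
  rec <- parseLiveRecord(res, cid)
  if (nzchar(provider@cacheDir)) {
    dir.create(provider@cacheDir, recursive = TRUE, showWarnings = FALSE)
    writeRecordJson(rec, file.path(provider@cacheDir, paste0("cid_", cid, ".json")))
  }
  rec
})

# Accepts either the fixture schema or a PUG-View "Record" payload.
parseLiveRecord <- function(res, cid) {
  if (!is.null(res$cid) && !is.null(res$sections)) {
    return(compoundRecord(res$cid, as.character(res$name),
                          sectionsFromList(res$sections)))
  }
  rec <- res$Record
  if (is.null(rec)) notFoundError(paste0("no record payload for CID ", cid))
  fromView <- function(secs) {
    lapply(secs %||% list(), function(s) {
      content <- unlist(lapply(s$Information %||% list(), function(info) {
        vals <- info$Value$StringWithMarkup %||% list()
        vapply(vals, function(v) as.character(v$String %||% ""), character(1))
      }))
      recordSection(heading = as.character(s$TOCHeading %||% "?"),
                    content = content %||% character(0),
                    children = fromView(s$Section))
    })
  }
  compoundRecord(cid = rec$RecordNumber %||% cid,
                 name = as.character(rec$RecordTitle %||% paste0("CID ", cid)),
                 sections = fromView(rec$Section))
}
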