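#' Resolve a compound name to identifiers
#'
#' Queries a record provider with a compound name and returns the CID or list
#' of CIDs matching that compound, in provider order. An empty result means
#' \emph{not found} (routed downstream to local-table matching) and is never
#' conflated with a transport error, which is signalled as a condition of
#' class \code{toxscreenTransport}.
#'
#' @param provider A \code{\linkS4class{RecordProvider}}.
#' @param name Non-empty compound name; lookup is case-insensitive, with a
#'   stereo-prefix-stripped secondary key (so "L-phenylalanine" resolves
#'   records stored as "phenylalanine" and vice versa).
#' @param ... Passed to methods.
#' @return Numeric vector of CIDs (possibly empty).
#' @export
setGeneric("resolveName", function(provider, name, ...) standardGeneric("resolveName"))

#' Fetch a full compound record
#'
#' Retrieves the full hierarchical record for one CID. The live provider
#' waits so that consecutive requests are at least its minimum interval
#' (default 0.2 s) apart. An unknown CID signals a condition of class
#' \code{toxscreenNotFound}; transport failures (after retries) signal
#' \code{toxscreenTransport}.
#'
#' @param provider A \code{\linkS4class{RecordProvider}}.
#' @param cid Positive integer identifier.
#' @param ... Passed to methods.
#' @return A \code{\linkS4class{CompoundRecord}}.
#' @export
setGeneric("fetchRecord", function(provider, cid, ...) standardGeneric("fetchRecord"))
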