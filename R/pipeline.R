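#' Validate a run configuration
#'
#' Reads a YAML run configuration, checks mandatory keys, resolves paths and
#' applies documented defaults. Mandatory: \code{samples} (list of sample
#' directories, each holding per-mode assigned-formula CSVs),
#' \code{toxic_table}, \code{output}. Optional with defaults:
#' \code{provider} (\code{"fixture"}; \code{"fixture"} requires
#' \code{store}), \code{local_table}, \code{patterns} (\code{pos:
#' "*pos*.csv"}, \code{neg: "*neg*.csv"}), \code{column_map},
#' \code{keywords}, \code{ppm_tol} (3), \code{cid_cap} (3), \code{seed} (1).
#' A live provider is refused unless \code{allow_network: true} is set, so a
#' test run can never reach the network by accident.
#'
#' @param path YAML file, or a list already parsed.
#' @return Validated configuration list.
#' @export
validateConfig <- function(path) {
  cfg <- if (is.list(path)) path else {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path)
  }
  for (key in c("samples", "toxic_table", "output")) {
    if (is.null(cfg[[key]])) stop("config is missing mandatory key '", key, "'")
  }
  cfg$samples <- as.character(unlist(cfg$samples))
  if (length(cfg$samples) < 1) stop("config key 'samples' must list at least one sample directory")
  cfg$provider <- cfg$provider %||% "fixture"
  if (!cfg$provider %in% c("fixture", "live")) {
    stop("config key 'provider' must be 'fixture' or 'live'")
  }
  if (cfg$provider == "fixture" && is.null(cfg$store)) {
    stop("provider 'fixture' requires config key 'store' (record store directory)")
  }
  if (cfg$provider == "live" && !isTRUE(cfg$allow_network)) {
    stop("provider 'live' requires 'allow_network: true' in the config")
  }
  cfg$patterns <- utils::modifyList(list(pos = "*pos*.csv", neg = "*neg*.csv"),
                                    cfg$patterns %||% list())
  cm <- defaultColumnMap()
  for (role in names(cfg$column_map %||% list())) cm[[role]] <- cfg$column_map[[role]]
  cfg$column_map <- cm
  kw <- defaultKeywords()
  for (part in names(cfg$keywords %||% list())) kw[[part]] <- as.character(cfg$keywords[[part]])
  cfg$keywords <- kw
  cfg$ppm_tol <- cfg$ppm_tol %||% 3
  cfg$cid_cap <- cfg$cid_cap %||% 3
  cfg$seed <- cfg$seed %||% 1
  cfg$local_table <- cfg$local_table %||% ""
  missing <- cfg$samples[!dir.exists(cfg$samples)]
  if (length(missing) > 0) stop("sample directory not found: ", paste(missing, collapse = ", "))
  if (!file.exists(cfg$toxic_table)) stop("toxic table not found: ", cfg$toxic_table)
  if (nzchar(cfg$local_table) && !file.exists(cfg$local_table)) {
    stop("local table not found: ", cfg$local_table)
  }
  if (cfg$provider == "fixture" && !dir.exists(cfg$store)) {
    stop("record store directory not found: ", cfg$store)
  }
  cfg
}

modeFile <- function(dir, pattern) {
  rx <- utils::glob2rx(pattern)
  hits <- sort(list.files(dir, pattern = rx, full.names = TRUE))
  if (length(hits) == 0) return(NULL)
  hits[1]
}

screenMode <- function(path, mode, toxTable, provider, keywords, columnMap,
                       ppmTol, cidCap) {
  assigned <- readAssignedFormulas(path, columnMap = columnMap,
                                   ionMode = if (mode == "pos") "positive" else "negative",
                                   ppmTol = ppmTol)
  m <- matchFormulas(assigned, toxTable)
  toxic <- emptyReport("toxic")
  unchecked <- emptyReport("unchecked")
  unfound <- emptyReport("unfound")
  nCandidates <- 0L
  for (fm in m$matches) {
    cand <- fm$candidates
    for (i in seq_len(nrow(cand))) {
      nCandidates <- nCandidates + 1L
      res <- classifyCompound(cand$name[i], provider, keywords = keywords,
                              cidCap = cidCap)
      row <- switch(res$outcome,
        classified = data.frame(name = res$resolvedName,
                                formula = cand$canonical[i],
                                classification = classificationLabel(res$classification),
                                evidence = paste(classificationEvidence(res$classification),
                                                 collapse = ";")),
        unchecked = data.frame(name = res$resolvedName, formula = cand$canonical[i]),
        unfound = data.frame(name = res$resolvedName, formula = cand$canonical[i],
                             note = res$note))
      if (res$outcome == "classified") toxic <- rbind(toxic, row)
      else if (res$outcome == "unchecked") unchecked <- rbind(unchecked, row)
      else unfound <- rbind(unfound, row)
    }
  }
  list(assigned = assigned, matches = m$matches, unmatched = m$unmatched,
       toxic = sortReport(toxic, "toxic"),
       unchecked = sortReport(unchecked, "unchecked"),
       unfound = sortReport(unfound, "unfound"),
       nCandidates = nCandidates)
}

#' Run the full screening pipeline
#'
#' Drives the whole per-sample screening and cross-sample merging sequence:
#' for each sample directory, each ionization mode's assigned-formula table
#' is matched against the local toxic table, every matched candidate is
#' resolved/fetched/classified, the two modes are combined, and the
#' still-unfound names are matched against the local record table; then the
#' per-sample toxic, unfound and unchecked tables are each merged across
#' samples (three merge passes), and the merged toxic table gets a final
#' formatting pass. All reports are written under
#' \code{output/<sample-id>/} and \code{output/}. With the fixture provider
#' a run is a pure function of its inputs: reruns are byte-identical.
#'
#' @param config Path to a YAML configuration or a configuration list; see
#'   \code{\link{validateConfig}}.
#' @param provider Optional pre-built \code{\linkS4class{RecordProvider}}
#'   overriding the configured one (used by tests and the live mode).
#' @return A \code{\linkS4class{ScreeningResult}}.
#' @export
runPipeline <- function(config, provider = NULL) {
  cfg <- validateConfig(config)
  if (is.null(provider)) {
    provider <- if (cfg$provider == "fixture") loadFixtureStore(cfg$store)
                else liveProvider(cacheDir = file.path(cfg$output, "record_cache"))
  }
  toxTable <- readToxicTable(cfg$toxic_table)
  localTable <- if (nzchar(cfg$local_table)) readLocalTable(cfg$local_table)
                else data.frame(name = character(0), safetyClass = character(0),
                                note = character(0))
  outRoot <- cfg$output
  dir.create(outRoot, recursive = TRUE, showWarnings = FALSE)
  sampleIds <- sort(basename(normalizePath(cfg$samples, mustWork = TRUE)))
  sampleDirs <- stats::setNames(cfg$samples[order(basename(normalizePath(cfg$samples, mustWork = TRUE)))],
                                sampleIds)
  perSample <- list()
  log <- list(samples = list())
  for (id in sampleIds) {
    dir <- sampleDirs[[id]]
    sampleOut <- file.path(outRoot, id)
    dir.create(sampleOut, recursive = TRUE, showWarnings = FALSE)
    perMode <- list()
    counts <- list()
    for (mode in c("pos", "neg")) {
      f <- modeFile(dir, cfg$patterns[[mode]])
      if (is.null(f)) next
      sm <- screenMode(f, mode, toxTable, provider, cfg$keywords,
                       cfg$column_map, cfg$ppm_tol, cfg$cid_cap)
      perMode[[mode]] <- sm
      utils::write.csv(sm$unmatched, file.path(sampleOut, paste0("unmatched_", mode, ".csv")),
                       row.names = FALSE, quote = TRUE)
      counts[[mode]] <- list(featuresRead = nrow(sm$assigned),
                             matched = length(sm$matches),
                             candidates = sm$nCandidates,
                             unmatched = nrow(sm$unmatched))
    }
    if (length(perMode) == 0) {
      stop("sample '", id, "' has no file matching pattern '",
           cfg$patterns$pos, "' or '", cfg$patterns$neg, "' in ", dir)
    }
    toxic <- combineModes(perMode$pos$toxic, perMode$neg$toxic, "toxic")
    unchecked <- combineModes(perMode$pos$unchecked, perMode$neg$unchecked, "unchecked")
    unfoundAll <- combineModes(perMode$pos$unfound, perMode$neg$unfound, "unfound")
    lm <- matchLocal(unfoundAll$name, localTable)
    keep <- unfoundAll$name %in% lm$stillUnfound
    unfound <- unfoundAll[keep, , drop = FALSE]
    safeIdx <- match(lm$found$name, unfoundAll$name)
    safe <- if (nrow(lm$found) > 0) {
      data.frame(name = lm$found$name, safetyClass = lm$found$safetyClass,
                 inPos = unfoundAll$inPos[safeIdx], inNeg = unfoundAll$inNeg[safeIdx])
    } else emptyReport("safe", presence = c("inPos", "inNeg"))
    writeReport(toxic, file.path(sampleOut, "toxic.csv"), "toxic")
    writeReport(unchecked, file.path(sampleOut, "unchecked.csv"), "unchecked")
    writeReport(unfound, file.path(sampleOut, "unfound.csv"), "unfound")
    writeReport(safe, file.path(sampleOut, "safe.csv"), "safe")
    perSample[[id]] <- list(toxic = toxic, unchecked = unchecked,
                            unfound = unfound, safe = safe,
                            unmatched = lapply(perMode, `[[`, "unmatched"))
    counts$partitions <- list(
      toxic = nrow(toxic), unchecked = nrow(unchecked),
      stillUnfound = nrow(unfound), locallyMatched = nrow(safe))
    counts$classifiedPerFamily <- if (nrow(toxic) > 0) {
      fams <- vapply(toxic$classification, function(l) parseToxLabel(l)$family, character(1))
      as.list(table(factor(fams, levels = toxFamilies())))
    } else {
      as.list(stats::setNames(rep(0L, 5), toxFamilies()))
    }
    log$samples[[id]] <- counts
  }
  merged <- list(
    toxic = mergeSamples(lapply(perSample, `[[`, "toxic"), "toxic"),
    unfound = mergeSamples(lapply(perSample, `[[`, "unfound"), "unfound"),
    unchecked = mergeSamples(lapply(perSample, `[[`, "unchecked"), "unchecked")
  )
  for (kind in names(merged)) {
    writeReport(merged[[kind]], file.path(outRoot, paste0("merged_", kind, ".csv")), kind)
  }
  formatted <- formatToxicReport(merged$toxic,
                                 path = file.path(outRoot, "toxic_report.csv"))
  log$merged <- lapply(merged, nrow)
  writeRunLog(log, file.path(outRoot, "run_log.txt"))
  new("ScreeningResult", samples = perSample, merged = merged,
      formatted = formatted, log = log, outputRoot = outRoot)
}

writeRunLog <- function(log, path) {
  lines <- c("toxscreen run log")
  for (id in names(log$samples)) {
    s <- log$samples[[id]]
    lines <- c(lines, paste0("sample ", id, ":"))
    for (mode in intersect(c("pos", "neg"), names(s))) {
      m <- s[[mode]]
      lines <- c(lines, sprintf("  %s: features=%d matched=%d candidates=%d unmatched=%d",
                                mode, m$featuresRead, m$matched, m$candidates, m$unmatched))
    }
    p <- s$partitions
    lines <- c(lines, sprintf("  partitions: toxic=%d unchecked=%d unfound=%d local=%d",
                              p$toxic, p$unchecked, p$stillUnfound, p$locallyMatched))
    fam <- s$classifiedPerFamily
    lines <- c(lines, paste0("  per family: ",
                             paste(sprintf("%s=%d", names(fam), unlist(fam)), collapse = " ")))
  }
  lines <- c(lines, sprintf("merged: toxic=%d unfound=%d unchecked=%d",
                            log$merged$toxic, log$merged$unfound, log$merged$unchecked))
  writeLines(lines, path)
  invisible(path)
}
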