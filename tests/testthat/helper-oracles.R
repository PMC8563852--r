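# Independent oracles, kept deliberately separate from the implementations
# they check.

# Brute-force classification oracle: explicit per-code label table and an
# explicit severity order, most severe first.
oracleSeverityOrder <- c(
  paste("Acute toxic", 1:5),
  paste("Skin and eye irritant", 1:2),
  paste("Eye irritant", 1:2),
  paste("Skin irritant", 1:2),
  "Potentially toxic"
)

oracleCodeLabels <- c(
  H300 = "Acute toxic 2", H301 = "Acute toxic 3",
  H302 = "Acute toxic 4", H303 = "Acute toxic 5",
  H310 = "Acute toxic 2", H311 = "Acute toxic 3",
  H312 = "Acute toxic 4", H313 = "Acute toxic 5",
  H330 = "Acute toxic 2", H331 = "Acute toxic 3",
  H332 = "Acute toxic 4", H333 = "Acute toxic 5",
  H315 = "Skin irritant 2", H318 = "Eye irritant 1", H319 = "Eye irritant 2"
)

oracleClassify <- function(codes) {
  codes <- intersect(codes, names(oracleCodeLabels))
  labels <- unname(oracleCodeLabels[codes])
  skinLevels <- as.integer(sub(".* ", "", grep("^Skin irritant", labels, value = TRUE)))
  eyeLevels <- as.integer(sub(".* ", "", grep("^Eye irritant", labels, value = TRUE)))
  if (length(skinLevels) > 0 && length(eyeLevels) > 0) {
    labels <- c(labels, paste("Skin and eye irritant", min(c(skinLevels, eyeLevels))))
  }
  hit <- oracleSeverityOrder[oracleSeverityOrder %in% labels]
  if (length(hit) == 0) "Potentially toxic" else hit[1]
}

oracleRank <- function(label) {
  # position in the explicit order, 1 = most severe; smaller is more severe
  match(label, oracleSeverityOrder)
}

# O(n*m) pairwise matching oracle on element counts
bruteMatch <- function(assignedFormulas, tableFormulas) {
  lapply(seq_along(assignedFormulas), function(i) {
    ai <- toxscreen::parseFormula(assignedFormulas[i])
    which(vapply(tableFormulas, function(tf) {
      tc <- toxscreen::parseFormula(tf)
      length(ai) == length(tc) && all(sort(names(ai)) == sort(names(tc))) &&
        all(ai[sort(names(ai))] == tc[sort(names(tc))])
    }, logical(1)))
  })
}

# random formula string with shuffled element order and redundant splits
randomFormulaString <- function() {
  counts <- c(C = sample(1:30, 1), H = sample(1:40, 1),
              N = sample(0:4, 1), O = sample(0:12, 1),
              S = sample(0:1, 1), Cl = sample(0:2, 1))
  counts <- counts[counts > 0]
  syms <- sample(names(counts))
  paste0(syms, ifelse(counts[syms] == 1 & stats::runif(length(syms)) < 0.5,
                      "", counts[syms]), collapse = "")
}

mappedCodes <- names(oracleCodeLabels)

writeTempCsv <- function(df, dir = tempdir(), name = "tmp.csv") {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

simpleAssigned <- function(formulas) {
  data.frame(
    formula = formulas,
    canonical = vapply(formulas, toxscreen::canonicalFormula, character(1),
                       USE.NAMES = FALSE),
    neutralMass = vapply(formulas, toxscreen::monoisotopicMass, numeric(1),
                         USE.NAMES = FALSE),
    abundance = rep(1e5, length(formulas)),
    retentionTime = rep(1, length(formulas)),
    ionMode = rep("negative", length(formulas)),
    ambiguous = rep(FALSE, length(formulas)),
    massFlag = rep(FALSE, length(formulas))
  )
}

simpleToxTable <- function(names, formulas, source = "user") {
  data.frame(
    name = names,
    formula = formulas,
    canonical = vapply(formulas, toxscreen::canonicalFormula, character(1),
                       USE.NAMES = FALSE),
    monoisotopicMass = vapply(formulas, toxscreen::monoisotopicMass, numeric(1),
                              USE.NAMES = FALSE),
    source = rep(source, length(formulas)),
    safetyClass = rep("", length(formulas))
  )
}

fakeClockLimiter <- function(minInterval = 0.2, start = 0) {
  env <- new.env()
  env$t <- start
  lim <- toxscreen::rateLimiter(
    minInterval = minInterval,
    clock = function() env$t,
    wait = function(s) env$t <- env$t + s
  )
  list(limiter = lim, env = env)
}
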