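#' Specify a synthetic screening fixture
#'
#' Describes one synthetic study: a set of \emph{planted} compounds (known
#' name, formula, hazard codes, which ESI modes they appear in, and whether
#' their database record exists), a number of random background formulas
#' emulating the bulk of an unambiguous assignment list, and a number of
#' decoy entries padding the toxic table. All randomness is fixed by
#' \code{seed}; decoy and background formulas are generated so they never
#' collide, which makes planted-compound recovery exact by construction.
#'
#' @param planted List of planted-compound descriptions, each built by
#'   \code{\link{plantedCompound}}; names must be unique.
#' @param nBackground Number of random background formulas per sample.
#' @param nDecoys Number of random decoy entries in the toxic table.
#' @param seed Integer seed fixing all randomness.
#' @return A \code{FixtureSpec} list.
#' @export
fixtureSpec <- function(planted = list(), nBackground = 50, nDecoys = 10, seed = 1) {
  nm <- vapply(planted, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("planted compound names must be unique")
  structure(list(planted = planted, nBackground = as.integer(nBackground),
                 nDecoys = as.integer(nDecoys), seed = as.integer(seed)),
            class = "FixtureSpec")
}

#' @describeIn fixtureSpec Describe one planted compound.
#' @param name Compound name (as it appears in the toxic table).
#' @param formula Molecular formula string.
#' @param codes Hazard-statement codes embedded in the record's GHS section
#'   (may be empty: the record then carries a code-free toxicity section and
#'   classifies as Potentially toxic).
#' @param modes ESI modes the compound's formula appears in
#'   (\code{c("pos","neg")}, subset).
#' @param recordName Name the database record is stored under (defaults to
#'   \code{name}; set differently to exercise stereo-prefix normalization).
#' @param recordAbsent No record file is generated: the pipeline must route
#'   the compound to \emph{unfound}.
#' @param unchecked The record carries only physical-property sections, so
#'   the pipeline must route the compound to \emph{unchecked}.
#' @param foodSection Also embed a food-safety section.
#' @export
plantedCompound <- function(name, formula, codes = character(0),
                            modes = c("pos", "neg"), recordName = name,
                            recordAbsent = FALSE, unchecked = FALSE,
                            foodSection = FALSE) {
  stopifnot(all(modes %in% c("pos", "neg")), length(modes) >= 1)
  list(name = name, formula = formula, canonical = canonicalFormula(formula),
       codes = as.character(codes), modes = modes, recordName = recordName,
       recordAbsent = isTRUE(recordAbsent), unchecked = isTRUE(unchecked),
       foodSection = isTRUE(foodSection))
}

randomChnoFormula <- function() {
  cN <- sample(5:30, 1)
  # keep H within the chemically plausible H/C window used upstream (0.3-3.0)
  hN <- sample(max(1L, ceiling(0.3 * cN)):floor(3 * cN), 1)
  nN <- sample(0:3, 1)
  oN <- sample(1:10, 1)
  counts <- c(C = cN, H = hN, N = nN, O = oN)
  hillFormat(counts[counts > 0])
}

# Background and decoy formulas are drawn from one seeded stream so that
# gen_sample and gen_toxic_table stay mutually consistent: decoys are
# regenerated until they collide with neither background nor planted
# formulas, hence zero false positives by construction.
fixtureFormulas <- function(spec) {
  plantedCanon <- vapply(spec$planted, `[[`, character(1), "canonical")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
            suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(deriveSeed(spec$seed, 101))
  background <- character(0)
  while (length(background) < spec$nBackground) {
    f <- randomChnoFormula()
    if (!f %in% c(background, plantedCanon)) background <- c(background, f)
  }
  decoys <- character(0)
  while (length(decoys) < spec$nDecoys) {
    f <- randomChnoFormula()
    if (!f %in% c(background, plantedCanon, decoys)) decoys <- c(decoys, f)
  }
  list(background = background, decoys = decoys)
}

#' Generate a synthetic toxic-compound table
#'
#' Writes a toxic-table CSV containing every planted compound plus
#' \code{nDecoys} random CHNO formulas guaranteed not to collide with the
#' sample's background formulas. Deterministic under the spec's seed.
#'
#' @param spec A \code{\link{fixtureSpec}}.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
genToxicTable <- function(spec, path) {
  ff <- fixtureFormulas(spec)
  nP <- length(spec$planted)
  planted <- data.frame(
    name = vapply(spec$planted, `[[`, character(1), "name"),
    formula = vapply(spec$planted, `[[`, character(1), "canonical"),
    monoisotopic_mass = vapply(spec$planted, function(p) monoisotopicMass(p$canonical), numeric(1)),
    source = rep("user", nP),
    safety_class = rep("", nP)
  )
  decoys <- if (spec$nDecoys > 0) data.frame(
    name = paste0("decoy-", seq_along(ff$decoys)),
    formula = ff$decoys,
    monoisotopic_mass = vapply(ff$decoys, monoisotopicMass, numeric(1), USE.NAMES = FALSE),
    source = "user",
    safety_class = ""
  ) else NULL
  out <- rbind(planted, decoys)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Generate a synthetic assigned-formula sample
#'
#' Emulates the unambiguous output of the upstream formula-assignment stage
#' for one ESI mode: random background CHNO formulas (H/C ratio within
#' 0.3-3.0) plus the planted formulas whose \code{modes} include this mode.
#' Masses are computed from element counts (never sampled), so every row
#' passes the reader's mass/formula consistency check; abundances are
#' log-uniform and retention times uniform on [0, 70] minutes, the span of a
#' typical 70-minute LC gradient. Deterministic under the spec's seed.
#'
#' @param spec A \code{\link{fixtureSpec}}.
#' @param mode \code{"pos"} or \code{"neg"}.
#' @param path Output CSV path (columns follow
#'   \code{\link{defaultColumnMap}}).
#' @return The path, invisibly.
#' @export
genSample <- function(spec, mode = c("pos", "neg"), path) {
  mode <- match.arg(mode)
  ff <- fixtureFormulas(spec)
  plantedHere <- Filter(function(p) mode %in% p$modes, spec$planted)
  formulas <- unique(c(vapply(plantedHere, `[[`, character(1), "canonical"),
                       ff$background))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
            suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(deriveSeed(spec$seed, if (mode == "pos") 211 else 212))
  n <- length(formulas)
  out <- data.frame(
    formula = formulas,
    exp_mass = vapply(formulas, monoisotopicMass, numeric(1), USE.NAMES = FALSE),
    abundance = 10^stats::runif(n, 4, 8),
    RT = stats::runif(n, 0, 70)
  )
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

physicalSections <- function() {
  list(
    recordSection("Chemical and Physical Properties", children = list(
      recordSection("Melting Point", "160.5 C"),
      recordSection("Solubility", "soluble in ethanol")
    ))
  )
}

plantedRecord <- function(p, cid) {
  sections <- physicalSections()
  if (!p$unchecked) {
    ghs <- if (length(p$codes) > 0) {
      phrases <- c(H300 = "Fatal if swallowed", H301 = "Toxic if swallowed",
                   H302 = "Harmful if swallowed", H303 = "May be harmful if swallowed",
                   H310 = "Fatal in contact with skin", H311 = "Toxic in contact with skin",
                   H312 = "Harmful in contact with skin",
                   H313 = "May be harmful in contact with skin",
                   H315 = "Causes skin irritation", H318 = "Causes serious eye damage",
                   H319 = "Causes serious eye irritation",
                   H330 = "Fatal if inhaled", H331 = "Toxic if inhaled",
                   H332 = "Harmful if inhaled", H333 = "May be harmful if inhaled")
      recordSection("GHS Classification",
                    sprintf("%s (100%%): %s [Warning]", p$codes,
                            ifelse(p$codes %in% names(phrases), phrases[p$codes],
                                   "Hazard statement")))
    } else {
      recordSection("Toxicity Summary",
                    "Evaluated for dietary exposure; no harmonized hazard statement reported.")
    }
    safety <- recordSection("Safety and Hazards", children = list(ghs))
    sections <- c(sections, list(safety))
  }
  if (p$foodSection) {
    sections <- c(sections, list(
      recordSection("Food Additives and Ingredients",
                    "Listed in food-additive evaluations.")))
  }
  compoundRecord(cid = cid, name = p$recordName, sections = sections)
}

#' Generate a JSON record store for a fixture
#'
#' Writes one schema-valid JSON record per planted compound (unless flagged
#' \code{recordAbsent}, exercising the unfound path), embedding its hazard
#' codes inside a "GHS Classification" section nested under "Safety and
#' Hazards", alongside distractor physical-property sections. CIDs are
#' assigned deterministically in planted order.
#'
#' @param spec A \code{\link{fixtureSpec}}.
#' @param outDir Output directory for the JSON files.
#' @return The directory, invisibly.
#' @export
genRecordStore <- function(spec, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(spec$planted)) {
    p <- spec$planted[[i]]
    if (p$recordAbsent) next
    rec <- plantedRecord(p, cid = 10000 + i)
    writeRecordJson(rec, file.path(outDir, sprintf("record_%04d.json", i)))
  }
  invisible(outDir)
}

#' The bundled eight-compound validation fixture
#'
#' The worked example: the eight compounds recovered when the screening
#' method was validated against a proprietary-software workflow on red maple
#' leaf concentrate, with their standard harmonized GHS hazard statements.
#' Running the pipeline on this fixture classifies coumarin and
#' 4-methoxybenzaldehyde as "Acute toxic 4" (H302), 3-methoxybenzaldehyde,
#' citric acid and naringin as "Skin and eye irritant 2" (H315 + H319),
#' phenylalanine as "Eye irritant 2" (H319), and glutamic and aspartic acid
#' as "Potentially toxic" (toxicity fields, no hazard code). The three amino
#' acids are planted under their stereo-prefixed names (L-glutamic acid,
#' L-phenylalanine, L-aspartic acid) while their records are stored without
#' the prefix, exercising name normalization; 3- and 4-methoxybenzaldehyde
#' share the formula C8H8O2, exercising isomer retention.
#'
#' @param dir Directory to build the fixture in (created if needed).
#' @return List with paths: \code{toxicTable}, \code{store}, \code{sampleDir}
#'   (holding \code{sample_pos.csv} and \code{sample_neg.csv}), \code{spec}.
#' @export
validationFixture <- function(dir) {
  planted <- list(
    plantedCompound("3-methoxybenzaldehyde", "C8H8O2", c("H315", "H319")),
    plantedCompound("4-methoxybenzaldehyde", "C8H8O2", "H302"),
    plantedCompound("coumarin", "C9H6O2", "H302"),
    plantedCompound("L-glutamic acid", "C5H9NO4", character(0),
                    recordName = "glutamic acid"),
    plantedCompound("L-phenylalanine", "C9H11NO2", "H319",
                    recordName = "phenylalanine"),
    plantedCompound("citric acid", "C6H8O7", c("H315", "H319"), foodSection = TRUE),
    plantedCompound("L-aspartic acid", "C4H7NO4", character(0),
                    recordName = "aspartic acid"),
    plantedCompound("naringin", "C27H32O14", c("H315", "H319"))
  )
  spec <- fixtureSpec(planted, nBackground = 20, nDecoys = 5, seed = 42)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  toxicTable <- file.path(dir, "toxic_table.csv")
  store <- file.path(dir, "store")
  sampleDir <- file.path(dir, "leafA")
  genToxicTable(spec, toxicTable)
  genRecordStore(spec, store)
  genSample(spec, "pos", file.path(sampleDir, "sample_pos.csv"))
  genSample(spec, "neg", file.path(sampleDir, "sample_neg.csv"))
  list(toxicTable = toxicTable, store = store, sampleDir = sampleDir, spec = spec)
}
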