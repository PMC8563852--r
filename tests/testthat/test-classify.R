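recordWith <- function(name, sections) compoundRecord(1, name, sections)

test_that("scanRecord collects toxicity and food-safety sections depth-first", {
  rec <- recordWith("coumarin", list(
    recordSection("Names and Identifiers", "stuff"),
    recordSection("Safety and Hazards", children = list(
      recordSection("GHS Classification", "H302 (100%): Harmful if swallowed"))),
    recordSection("Food Additives and Ingredients", "flavouring")
  ))
  fields <- scanRecord(rec)
  headings <- vapply(fields$tox, `[[`, character(1), "heading")
  expect_true("GHS Classification" %in% headings)
  expect_true("Safety and Hazards" %in% headings)
  expect_length(fields$food, 1)
  expect_equal(fields$food[[1]]$heading, "Food Additives and Ingredients")
})

test_that("a record with only physical-property sections yields empty fields", {
  rec <- recordWith("blandine", list(
    recordSection("Melting Point", "12 C"),
    recordSection("Solubility", "miscible")))
  fields <- scanRecord(rec)
  expect_length(fields$tox, 0)
  expect_length(fields$food, 0)
})

test_that("extractHazardCodes finds H-codes in toxicity content only", {
  rec <- recordWith("x", list(
    recordSection("GHS Classification",
                  c("H302 (100%): Harmful if swallowed", "H315 ... H319")),
    recordSection("Food Additives", "H999 should not be read from food sections")))
  codes <- extractHazardCodes(scanRecord(rec))
  expect_equal(codes, c("H302", "H315", "H319"))
  expect_equal(extractHazardCodes(scanRecord(recordWith("y", list()))), character(0))
})

test_that("classifyCodes reproduces the category labels of the worked validation set", {
  expect_equal(classificationLabel(classifyCodes("H302")), "Acute toxic 4")
  expect_equal(classificationLabel(classifyCodes(c("H315", "H319"))),
               "Skin and eye irritant 2")
  expect_equal(classificationLabel(classifyCodes("H319")), "Eye irritant 2")
  expect_equal(classificationLabel(classifyCodes("H315")), "Skin irritant 2")
  expect_equal(classificationLabel(classifyCodes(character(0))), "Potentially toxic")
  expect_equal(classificationLabel(classifyCodes(c("H301", "H315", "H319"))),
               "Acute toxic 3")
  expect_equal(classificationLabel(classifyCodes("H318")), "Eye irritant 1")
  # dermal and inhalation routes collapse to the same levels
  expect_equal(classificationLabel(classifyCodes("H310")), "Acute toxic 2")
  expect_equal(classificationLabel(classifyCodes("H332")), "Acute toxic 4")
})

test_that("unknown hazard codes warn and are ignored, never fatal", {
  expect_warning(cls <- classifyCodes(c("H302", "H777")), "H777")
  expect_equal(classificationLabel(cls), "Acute toxic 4")
  expect_warning(cls2 <- classifyCodes("H777"), "H777")
  expect_equal(classificationLabel(cls2), "Potentially toxic")
})

test_that("classifyCodes equals the brute-force oracle on exhaustive code subsets", {
  # exhaustive over all subsets of a 12-code slice of the mapped set
  codes12 <- c("H300", "H301", "H302", "H303", "H311", "H312",
               "H315", "H318", "H319", "H330", "H332", "H333")
  for (mask in 0:(2^12 - 1)) {
    subset <- codes12[bitwAnd(mask, 2^(0:11)) > 0]
    got <- classificationLabel(classifyCodes(subset))
    expect_identical(got, oracleClassify(subset),
                     label = paste("codes:", paste(subset, collapse = "+")))
  }
})

test_that("classification is monotone: adding codes never lowers severity", {
  set.seed(19)
  for (i in 1:200) {
    a <- sample(mappedCodes, sample(0:6, 1))
    extra <- sample(mappedCodes, sample(0:4, 1))
    b <- union(a, extra)
    ra <- classificationRank(classifyCodes(a))
    rb <- classificationRank(classifyCodes(b))
    expect_gte(rb, ra)
  }
})

test_that("the classifier codomain has exactly five families", {
  expect_length(toxFamilies(), 5)
  seen <- unique(vapply(0:(2^12 - 1), function(mask) {
    codes12 <- c("H300", "H301", "H302", "H303", "H311", "H312",
                 "H315", "H318", "H319", "H330", "H332", "H333")
    classificationFamily(classifyCodes(codes12[bitwAnd(mask, 2^(0:11)) > 0]))
  }, character(1)))
  expect_setequal(seen, toxFamilies())
})

test_that("classifyCompound routes candidates to classified/unchecked/unfound", {
  store <- fixtureStore(list(
    compoundRecord(1, "coumarin", list(
      recordSection("GHS Classification", "H302 (100%): Harmful if swallowed"))),
    compoundRecord(2, "blandine", list(recordSection("Melting Point", "3 C")))
  ))
  got <- classifyCompound("coumarin", store)
  expect_equal(got$outcome, "classified")
  expect_equal(classificationLabel(got$classification), "Acute toxic 4")
  expect_equal(got$resolvedName, "coumarin")
  expect_equal(classifyCompound("blandine", store)$outcome, "unchecked")
  expect_equal(classifyCompound("absentine", store)$outcome, "unfound")
})

test_that("classifyCompound keeps the maximum severity over multiple records per name", {
  store <- fixtureStore(list(
    compoundRecord(1, "dualine", list(recordSection("Toxicity Summary", "mild"))),
    compoundRecord(2, "dualine", list(recordSection("GHS Classification", "H301")))
  ))
  got <- classifyCompound("dualine", store)
  expect_equal(classificationLabel(got$classification), "Acute toxic 3")
})

test_that("provider transport errors route conservatively to unfound with a note", {
  dead <- function(url) stop(structure(class = c("toxscreenTransport", "error", "condition"),
                                       list(message = "down", call = NULL)))
  lp <- liveProvider(baseUrl = "http://stub", transport = dead, retries = 0)
  lp@limiter <- fakeClockLimiter()$limiter
  got <- classifyCompound("coumarin", lp)
  expect_equal(got$outcome, "unfound")
  expect_match(got$note, "provider error")
})

test_that("formatToxicReport groups by family in severity order, deterministically", {
  merged <- data.frame(
    name = c("gentle", "acute2", "acute1", "eye"),
    formula = c("C1H4", "C2H4", "C2H6", "C3H6"),
    classification = c("Potentially toxic", "Acute toxic 4", "Acute toxic 2",
                       "Eye irritant 2"),
    evidence = c("", "H302", "H300", "H319"),
    S1_pos = c(TRUE, TRUE, FALSE, TRUE), S1_neg = c(FALSE, TRUE, TRUE, FALSE))
  out <- formatToxicReport(merged)
  expect_equal(out$category, c("Acute toxic", "Acute toxic", "Eye irritant",
                               "Potentially toxic"))
  expect_equal(out$name, c("acute1", "acute2", "eye", "gentle"))
  # deterministic: same input twice, byte-identical file
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  formatToxicReport(merged, p1); formatToxicReport(merged, p2)
  expect_identical(readLines(p1), readLines(p2))
  # empty merged table keeps the header
  pe <- tempfile(fileext = ".csv")
  formatToxicReport(merged[0, ], pe)
  expect_length(readLines(pe), 1)
})
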