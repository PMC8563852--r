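toxRow <- function(name, label, evidence = "", pos = TRUE, neg = FALSE) {
  data.frame(name = name, formula = "C2H4O", classification = label,
             evidence = evidence, inPos = pos, inNeg = neg)
}

test_that("matchLocal partitions unfound names with normalized matching", {
  table <- data.frame(name = c("widgetine", "Gadgetol"),
                      safetyClass = c("Potentially toxic", "excluded"),
                      note = c("", "solvent artifact"))
  got <- matchLocal(c("widgetine", "L-widgetine", "GADGETOL", "novelin"), table)
  expect_equal(nrow(got$found), 3)
  expect_equal(got$stillUnfound, "novelin")
  expect_equal(got$found$safetyClass[got$found$name == "L-widgetine"],
               "Potentially toxic")
  # partition identity
  expect_equal(nrow(got$found) + length(got$stillUnfound), 4)
  # empty table: everything stays unfound
  none <- matchLocal("novelin", table[0, ])
  expect_equal(none$stillUnfound, "novelin")
  expect_equal(nrow(none$found), 0)
})

test_that("matchLocal partition identity holds on randomized inputs", {
  set.seed(23)
  pool <- paste0("cpd", 1:40)
  for (i in 1:100) {
    tableNames <- sample(pool, sample(0:15, 1))
    queries <- sample(c(pool, toupper(pool)), sample(1:20, 1))
    table <- data.frame(name = tableNames,
                        safetyClass = rep("Potentially toxic", length(tableNames)),
                        note = rep("", length(tableNames)))
    got <- matchLocal(queries, table)
    expect_equal(nrow(got$found) + length(got$stillUnfound), length(queries))
    expect_length(intersect(got$found$name, got$stillUnfound), 0)
  }
})

test_that("combineModes unions the two polarities with correct mode flags", {
  pos <- rbind(toxRow("A", "Acute toxic 4", "H302"),
               toxRow("B", "Eye irritant 2", "H319"))
  neg <- rbind(toxRow("B", "Eye irritant 2", "H319", pos = FALSE, neg = TRUE),
               toxRow("C", "Potentially toxic", "", pos = FALSE, neg = TRUE))
  out <- combineModes(pos[, setdiff(names(pos), c("inPos", "inNeg"))],
                      neg[, setdiff(names(neg), c("inPos", "inNeg"))], "toxic")
  expect_setequal(out$name, c("A", "B", "C"))
  expect_true(out$inPos[out$name == "A"] && !out$inNeg[out$name == "A"])
  expect_true(out$inPos[out$name == "B"] && out$inNeg[out$name == "B"])
  expect_true(!out$inPos[out$name == "C"] && out$inNeg[out$name == "C"])
  # empty positive side
  out2 <- combineModes(NULL, data.frame(name = "X", formula = "C2H4",
                                        classification = "Acute toxic 5",
                                        evidence = "H303"), "toxic")
  expect_equal(out2$name, "X")
  expect_false(out2$inPos); expect_true(out2$inNeg)
})

test_that("cross-mode classification conflicts keep the higher severity with a warning", {
  pos <- data.frame(name = "dualine", formula = "C2H4O",
                    classification = "Acute toxic 4", evidence = "H302")
  neg <- data.frame(name = "dualine", formula = "C2H4O",
                    classification = "Potentially toxic", evidence = "")
  expect_warning(out <- combineModes(pos, neg, "toxic"), "conflict")
  expect_equal(out$classification, "Acute toxic 4")
  expect_true(out$inPos && out$inNeg)
  # and in the other direction
  expect_warning(out2 <- combineModes(neg, pos, "toxic"), "conflict")
  expect_equal(out2$classification, "Acute toxic 4")
})

test_that("combineModes never loses a compound", {
  set.seed(31)
  pool <- paste0("c", 1:30)
  for (i in 1:50) {
    p <- sample(pool, sample(0:10, 1))
    n <- sample(pool, sample(0:10, 1))
    pos <- data.frame(name = p, formula = rep("C2H4O", length(p)))
    neg <- data.frame(name = n, formula = rep("C2H4O", length(n)))
    out <- combineModes(pos, neg, "unchecked")
    expect_setequal(out$name, union(p, n))
  }
})

test_that("mergeSamples unions across samples with per-sample presence flags", {
  s1 <- combineModes(toxRow("A", "Acute toxic 4", "H302")[, -(5:6)],
                     toxRow("B", "Eye irritant 2", "H319")[, -(5:6)], "toxic")
  s2 <- combineModes(toxRow("B", "Eye irritant 2", "H319")[, -(5:6)],
                     toxRow("C", "Potentially toxic")[, -(5:6)], "toxic")
  m <- mergeSamples(list(S1 = s1, S2 = s2), "toxic")
  expect_setequal(m$name, c("A", "B", "C"))
  expect_true(m$S1_pos[m$name == "A"])
  expect_false(m$S2_pos[m$name == "A"] || m$S2_neg[m$name == "A"])
  expect_true(m$S1_neg[m$name == "B"] && m$S2_pos[m$name == "B"])
  expect_true(m$S2_neg[m$name == "C"])
  # single sample: identity up to presence columns
  one <- mergeSamples(list(S1 = s1), "toxic")
  expect_equal(one$name, s1$name)
  expect_equal(one$S1_pos, s1$inPos)
})

test_that("mergeSamples is commutative, associative and idempotent up to row order", {
  mk <- function(names) data.frame(name = names, formula = "C2H4O",
                                   inPos = TRUE, inNeg = FALSE)
  a <- mk(c("x", "y")); b <- mk(c("y", "z")); c3 <- mk("w")
  key <- function(m) m$name # rows are already deterministically sorted
  expect_equal(key(mergeSamples(list(A = a, B = b), "unchecked")),
               key(mergeSamples(list(B = b, A = a), "unchecked")))
  left <- mergeSamples(list(A = a, B = b, C = c3), "unchecked")
  right <- mergeSamples(list(C = c3, B = b, A = a), "unchecked")
  expect_equal(key(left), key(right))
  # idempotence: duplicating a sample's content adds no rows
  dup <- mergeSamples(list(A = a, Acopy = a), "unchecked")
  expect_equal(key(dup), sort(a$name))
})

test_that("intersection mode keeps only compounds present in every sample", {
  mk <- function(names) data.frame(name = names, formula = "C2H4O",
                                   inPos = TRUE, inNeg = FALSE)
  m <- mergeSamples(list(A = mk(c("x", "y")), B = mk(c("y", "z"))),
                    "unchecked", how = "intersection")
  expect_equal(m$name, "y")
})

test_that("local-table safety classes are validated on read", {
  good <- writeTempCsv(data.frame(name = c("a", "b"),
                                  safety_class = c("Acute toxic 4", "excluded")),
                       name = "local.csv")
  lt <- readLocalTable(good)
  expect_equal(nrow(lt), 2)
  bad <- writeTempCsv(data.frame(name = "a", safety_class = "Extremely bad"),
                      name = "local_bad.csv")
  expect_error(readLocalTable(bad), "unrecognized classification label")
})
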