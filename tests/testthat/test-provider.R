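storeOf <- function(...) fixtureStore(list(...))

coumarinRecord <- function(cid = 323) {
  compoundRecord(cid, "coumarin", list(
    recordSection("Chemical and Physical Properties", children = list(
      recordSection("Melting Point", "71 C"))),
    recordSection("Safety and Hazards", children = list(
      recordSection("GHS Classification", "H302 (100%): Harmful if swallowed")))
  ))
}

test_that("fixture store resolves names case-insensitively and in store order", {
  st <- storeOf(coumarinRecord(),
                compoundRecord(7, "naringin", list(recordSection("Toxicity", "x"))),
                compoundRecord(8, "naringin", list(recordSection("Toxicity", "y"))))
  expect_equal(resolveName(st, "coumarin"), 323)
  expect_equal(resolveName(st, "COUMARIN"), 323)
  expect_equal(resolveName(st, "zzz-nonexistent"), numeric(0))
  expect_equal(resolveName(st, "naringin"), c(7, 8)) # both retained, store order
  expect_error(resolveName(st, "  "), "non-empty")
})

test_that("stereo-prefix normalization bridges database naming conventions", {
  st <- storeOf(compoundRecord(17, "L-phenylalanine",
                               list(recordSection("Toxicity", "H319"))))
  expect_equal(resolveName(st, "phenylalanine"), 17)
  expect_equal(resolveName(st, "L-phenylalanine"), 17)
  st2 <- storeOf(compoundRecord(21, "glutamic acid",
                                list(recordSection("Toxicity", ""))))
  expect_equal(resolveName(st2, "L-glutamic acid"), 21)
  expect_equal(resolveName(st2, "DL-glutamic acid"), 21)
})

test_that("fetchRecord returns full records and distinguishes unknown CIDs", {
  st <- storeOf(coumarinRecord())
  rec <- fetchRecord(st, 323)
  expect_s4_class(rec, "CompoundRecord")
  expect_equal(recordName(rec), "coumarin")
  headings <- vapply(recordSections(rec), `[[`, character(1), "heading")
  expect_true("Safety and Hazards" %in% headings)
  expect_error(fetchRecord(st, 999), class = "toxscreenNotFound")
  expect_error(fetchRecord(st, -1), "positive")
})

test_that("the fixture provider is pure: repeated queries return identical results", {
  st <- storeOf(coumarinRecord())
  expect_identical(resolveName(st, "coumarin"), resolveName(st, "coumarin"))
  expect_identical(fetchRecord(st, 323), fetchRecord(st, 323))
})

test_that("loadFixtureStore validates the record schema and lists offending files", {
  dir <- tempfile("store")
  dir.create(dir)
  writeRecordJson(coumarinRecord(), file.path(dir, "coumarin.json"))
  st <- loadFixtureStore(dir)
  expect_equal(resolveName(st, "coumarin"), 323)
  # a file missing the sections node fails the load, naming the file
  writeLines('{"cid": 5, "name": "broken"}', file.path(dir, "broken.json"))
  expect_error(loadFixtureStore(dir), "broken.json")
  expect_error(loadFixtureStore(dir), "sections")
  # empty directory: provider resolving nothing
  empty <- tempfile("empty")
  dir.create(empty)
  st0 <- loadFixtureStore(empty)
  expect_equal(resolveName(st0, "anything"), numeric(0))
})

test_that("record JSON round-trips through write and read", {
  rec <- coumarinRecord()
  path <- tempfile(fileext = ".json")
  writeRecordJson(rec, path)
  back <- readRecordJson(path)
  expect_equal(recordCid(back), recordCid(rec))
  expect_equal(recordName(back), recordName(rec))
  expect_equal(recordSections(back), recordSections(rec))
})

test_that("consecutive rate-limited acquisitions are spaced by the minimum interval", {
  fc <- fakeClockLimiter(minInterval = 0.2)
  for (i in 1:10) acquireRateLimit(fc$limiter)
  stamps <- requestTimes(fc$limiter)
  expect_length(stamps, 10)
  expect_true(all(diff(stamps) >= 0.2 - 1e-12))
})

test_that("live provider spaces consecutive requests and separates not_found from errors", {
  fc <- fakeClockLimiter(minInterval = 0.2)
  calls <- new.env(); calls$urls <- character(0); calls$times <- numeric(0)
  transport <- function(url) {
    calls$urls <- c(calls$urls, url)
    calls$times <- c(calls$times, fc$env$t)
    if (grepl("name/missing", url)) {
      stop(structure(class = c("toxscreenNotFound", "error", "condition"),
                     list(message = "HTTP 404", call = NULL)))
    }
    list(IdentifierList = list(CID = list(323)))
  }
  lp <- liveProvider(baseUrl = "http://stub", transport = transport)
  lp@limiter <- fc$limiter
  expect_equal(resolveName(lp, "coumarin"), 323)
  expect_equal(resolveName(lp, "coumarin"), 323)
  expect_equal(resolveName(lp, "missing"), numeric(0)) # not_found -> empty, no error
  expect_true(all(diff(calls$times) >= 0.2 - 1e-12))
})

test_that("live provider retries transient failures with backoff, then surfaces an error", {
  fc <- fakeClockLimiter(minInterval = 0.2)
  attempts <- new.env(); attempts$n <- 0
  flaky <- function(url) {
    attempts$n <- attempts$n + 1
    if (attempts$n < 3) {
      stop(structure(class = c("toxscreenTransport", "error", "condition"),
                     list(message = "connection reset", call = NULL)))
    }
    list(IdentifierList = list(CID = list(9)))
  }
  lp <- liveProvider(baseUrl = "http://stub", transport = flaky, retries = 3)
  lp@limiter <- fc$limiter
  expect_equal(resolveName(lp, "x"), 9)
  expect_equal(attempts$n, 3)
  # permanent failure surfaces a transport error distinct from not_found
  dead <- function(url) stop(structure(class = c("toxscreenTransport", "error", "condition"),
                                       list(message = "down", call = NULL)))
  lp2 <- liveProvider(baseUrl = "http://stub", transport = dead, retries = 2)
  lp2@limiter <- fakeClockLimiter()$limiter
  expect_error(resolveName(lp2, "x"), class = "toxscreenTransport")
})

test_that("live provider caches fetched records as fixture JSON", {
  fc <- fakeClockLimiter()
  hits <- new.env(); hits$n <- 0
  transport <- function(url) {
    hits$n <- hits$n + 1
    list(cid = 323, name = "coumarin",
         sections = list(list(heading = "GHS Classification",
                              content = list("H302"), children = list())))
  }
  cache <- tempfile("cache")
  lp <- liveProvider(baseUrl = "http://stub", transport = transport, cacheDir = cache)
  lp@limiter <- fc$limiter
  r1 <- fetchRecord(lp, 323)
  r2 <- fetchRecord(lp, 323)
  expect_equal(hits$n, 1) # second fetch served from the on-disk cache
  expect_equal(recordName(r2), "coumarin")
})
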