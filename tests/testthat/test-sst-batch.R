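# Batch orchestration: query-set loading, per-run records, cross-run
# statistics, deficiency flags and table export.

fxDir <- file.path(tempdir(), "sst_batch_fixture")
if (!dir.exists(fxDir))
  fx <<- writeSstFixture(fxDir, seed = 1, variant = "default", nRuns = 3)

test_that("query sets load from JSON, xlsx and per-argument layouts", {
  qs <- loadQueryset(fx$queryFile)
  expect_equal(nrow(qs), 6)
  expect_true(all(grepl("^QUERY scansum", qs$query)))

  # duplicate names rejected, with the culprit named
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(data.frame(name = c("a", "a"),
                                  query = rep("QUERY scansum(MS1DATA) WHERE MS1MZ=100", 2)),
                       f, dataframe = "rows")
  expect_error(loadQueryset(f), "duplicate.*a")

  # unparseable queries reported with their position
  f2 <- tempfile(fileext = ".json")
  jsonlite::write_json(data.frame(name = c("ok", "broken"),
                                  query = c("QUERY scansum(MS1DATA) WHERE MS1MZ=100",
                                            "QUERY scansum(MS1DATA) WHERE NOPE=1")),
                       f2, dataframe = "rows")
  expect_error(loadQueryset(f2), "query 2.*broken")

  # empty set warns
  f3 <- tempfile(fileext = ".json")
  writeLines("[]", f3)
  expect_warning(empty <- loadQueryset(f3), "no queries")
  expect_equal(nrow(empty), 0)

  # per-argument layout composes MS1 scansum queries
  f4 <- tempfile(fileext = ".json")
  jsonlite::write_json(data.frame(name = "valeryl", mz = 249.1888,
                                  tolerance_ppm = 10, rt_min = 4.13,
                                  rt_max = 4.46),
                       f4, dataframe = "rows")
  qs4 <- loadQueryset(f4)
  q <- parseMassQL(qs4$query)
  expect_equal(queryConditions(q)$value, c(249.1888, 4.13, 4.46))

  skip_if_not_installed("readxl")
  f5 <- tempfile(fileext = ".xlsx")
  writeMinimalXlsx(loadQueryset(fx$queryFile), f5, sheetName = "queries")
  qs5 <- loadQueryset(f5)
  expect_equal(qs5$name, qs$name)
  expect_equal(qs5$query, qs$query)
})

test_that("a 3-run x 6-query batch yields 18 parameter-recovering records", {
  rec <- runBatch(loadConfig(fx$config))
  expect_equal(nrow(rec), 18)
  expect_equal(nrow(unique(rec[, c("run_id", "query_name")])), 18)
  expect_true(all(rec$found))
  truth <- fx$fixture
  interval <- truth$spec$ms1Interval
  apexByQuery <- setNames(truth$trueApexRt, truth$queries$name)
  for (i in seq_len(nrow(rec))) {
    expect_lte(abs(rec$apex_rt[i] - apexByQuery[[rec$query_name[i]]]),
               interval / 2 + 1e-9)
    expect_lt(abs(rec$area[i] - truth$trueArea) / truth$trueArea, 0.02)
    expect_lte(abs(rec$ppm_error[i]), 10)
  }
})

test_that("summary statistics use sample SD and guard RSD definition", {
  rec <- data.frame(
    run_id = rep(c("r1", "r2", "r3"), 2),
    run_index = rep(1:3, 2),
    query_name = rep(c("q1", "q2"), each = 3),
    found = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    apex_rt = c(4.2, 4.3, 4.4, 2.0, NA, NA),
    apex_intensity = 1, area = c(10, 10, 10, 5, NA, NA),
    observed_mz = 1, ppm_error = 0)
  s <- summarizeBatch(rec)
  q1 <- s[s$query_name == "q1", ]
  expect_equal(q1$rt_mean, 4.3)
  expect_equal(q1$rt_sd, 0.1)
  expect_equal(q1$rt_rsd, 0.1 / 4.3 * 100, tolerance = 1e-6) # 2.3256%
  expect_equal(q1$area_sd, 0)
  q2 <- s[s$query_name == "q2", ]
  expect_equal(q2$n_found, 1)
  expect_true(is.na(q2$rt_sd) && is.na(q2$rt_rsd)) # n-1 undefined

  # RSD invariant to rescaling all retention times
  rec2 <- rec; rec2$apex_rt <- rec2$apex_rt * 7
  expect_equal(summarizeBatch(rec2)$rt_rsd, s$rt_rsd, tolerance = 1e-9)

  # identical values give sd 0, RSD 0
  rec3 <- rec; rec3$apex_rt <- 2.0
  expect_equal(summarizeBatch(rec3)$rt_rsd[1], 0)
})

test_that("a corrupted file is logged and does not abort the batch", {
  d <- tempfile("corrupt")
  dir.create(d)
  file.copy(fx$runs, d)
  writeLines("this is not xml at all <<<", file.path(d, "broken.mzML"))
  cfg <- loadConfig(fx$config)
  cfg$mzml_directory <- d
  expect_warning(rec <- runBatch(cfg), "broken")
  expect_equal(nrow(rec), 18) # 3 readable runs x 6 queries
  errs <- attr(rec, "errors")
  expect_equal(nrow(errs), 1)
  expect_match(errs$path, "broken")
  unlink(d, recursive = TRUE)
})

test_that("removing a run leaves other records untouched", {
  d <- tempfile("subset")
  dir.create(d)
  file.copy(fx$runs, d)
  cfg <- loadConfig(fx$config)
  cfg$mzml_directory <- d
  full <- runBatch(cfg)
  unlink(file.path(d, basename(fx$runs[3])))
  part <- runBatch(cfg)
  expect_equal(nrow(part), 12)
  keep <- full$run_id %in% part$run_id
  expect_equal(part[, c("run_id", "query_name", "apex_rt", "area")],
               full[keep, c("run_id", "query_name", "apex_rt", "area")],
               ignore_attr = TRUE)
  unlink(d, recursive = TRUE)
})

test_that("a query for an absent analyte yields found=FALSE, NA fields", {
  cfg <- loadConfig(fx$config)
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(data.frame(name = "ghost",
                                  query = "QUERY scansum(MS1DATA) WHERE MS1MZ=777.7 AND TOLERANCEPPM=10"),
                       f, dataframe = "rows")
  cfg$query_file <- f
  rec <- runBatch(cfg)
  expect_equal(nrow(rec), 3)
  expect_false(any(rec$found))
  expect_true(all(is.na(rec$apex_rt)) && all(is.na(rec$area)))
})

test_that("deficiency flags catch missing analytes, shifts and inversions", {
  ref <- fx$fixture$reference
  rec <- runBatch(loadConfig(fx$config))
  expect_equal(nrow(flagDeviations(rec, ref)), 0) # clean batch

  # reversed elution order (wrong column/method scenario)
  dR <- tempfile("rev")
  fxR <- writeSstFixture(dR, seed = 3, variant = "reversed", nRuns = 1)
  recR <- runBatch(loadConfig(fxR$config))
  flR <- flagDeviations(recR, fxR$fixture$reference)
  eo <- flR[flR$flag == "ELUTION_ORDER", ]
  expect_equal(nrow(eo), 1)
  expect_match(eo$detail, "reversal")

  # +0.3 min shift on late eluters only (column lot drift scenario)
  dS <- tempfile("shift")
  fxS <- writeSstFixture(dS, seed = 4, variant = "shifted", nRuns = 1)
  recS <- runBatch(loadConfig(fxS$config))
  flS <- flagDeviations(recS, fxS$fixture$reference)
  shiftedNames <- fxS$fixture$reference$query_name[
    fxS$fixture$reference$expected_rt >= 5]
  expect_setequal(flS$query_name[flS$flag == "RT_SHIFT"], shiftedNames)
  expect_false("ELUTION_ORDER" %in% flS$flag)

  # missing analyte
  recM <- rec
  recM$found[recM$query_name == "oleoylcarnitine_d3"] <- FALSE
  flM <- flagDeviations(recM, ref)
  expect_equal(sum(flM$flag == "MISSING_ANALYTE"), 3)

  # reference lacking a query -> warning, query skipped
  expect_warning(flagDeviations(rec, ref[-1, ]), "no reference")
  unlink(c(dR, dS), recursive = TRUE)
})

test_that("export writes deterministic CSV and readxl-readable xlsx", {
  rec <- runBatch(loadConfig(fx$config))
  s <- summarizeBatch(rec)
  fl <- flagDeviations(rec, fx$fixture$reference)
  d1 <- tempfile("exp1"); d2 <- tempfile("exp2")
  exportResults(rec, s, fl, d1)
  exportResults(rec, s, fl, d2)
  for (nm in c("records", "summary", "flags")) {
    p1 <- file.path(d1, paste0(nm, ".csv"))
    p2 <- file.path(d2, paste0(nm, ".csv"))
    expect_true(file.exists(p1))
    expect_identical(readBin(p1, "raw", file.size(p1)),
                     readBin(p2, "raw", file.size(p2)))
  }
  # empty flags table exports header only
  flCsv <- read.csv(file.path(d1, "flags.csv"))
  expect_equal(nrow(flCsv), nrow(fl))
  recCsv <- read.csv(file.path(d1, "records.csv"))
  expect_equal(nrow(recCsv), 18)

  skip_if_not_installed("readxl")
  xl <- as.data.frame(readxl::read_excel(file.path(d1, "records.xlsx")))
  expect_equal(nrow(xl), 18)
  expect_equal(names(xl), names(rec))
  expect_equal(xl$area, rec$area, tolerance = 1e-12)
  unlink(c(d1, d2), recursive = TRUE)
})
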