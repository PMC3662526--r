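test_that("the DP-to-m/z series reproduces the eight published ions", {
  expect_identical(dpToMz(3:10),
                   c(503.3, 665.3, 827.3, 989.3, 1151.3, 1313.3, 1475.3,
                     1637.3))
  expect_error(dpToMz(2), "3..10")
  expect_error(dpToMz(11), "3..10")
})

test_that("m/z assignment inverts the series and rejects strays", {
  series <- dpSeries()
  expect_identical(mzToDp(dpToMz(3:10)), 3:10)
  expect_identical(mzToDp(827.5), 5L)
  expect_identical(mzToDp(900.0), NA_integer_)
  expect_identical(mzToDp(503.3), 3L)
  expect_identical(mzToDp(503.3 + 0.51), NA_integer_)
  expect_error(mzToDp(-1), "positive")
})

test_that("peak aggregation sums isomers and excludes labelled contaminants", {
  peaks <- data.frame(
    mz = c(503.3, 503.4, 503.2, 503.3, 503.3),
    intensity = c(10, 20, 30, 99, 44),
    label = c("1-kestose", "6-kestose", "6G-kestose", "raffinose",
              "loliose"))
  d <- aggregatePeaks(peaks)
  expect_equal(unname(dpValues(d)["DP3"]), 60)
  expect_equal(attr(d, "summary")$nExcluded, 2L)

  two <- data.frame(mz = c(665.3, 665.4), intensity = c(2, 1))
  expect_equal(unname(dpValues(aggregatePeaks(two))["DP4"]), 3)

  none <- aggregatePeaks(data.frame(mz = numeric(), intensity = numeric()))
  expect_true(all(dpValues(none) == 0))

  stray <- aggregatePeaks(data.frame(mz = 900.0, intensity = 5))
  expect_true(all(dpValues(stray) == 0))
  expect_equal(attr(stray, "summary")$nUnmatched, 1L)

  expect_warning(
    aggregatePeaks(data.frame(mz = 503.3, intensity = 1, label = "")),
    "unlabeled")
})

test_that("aggregation conserves the included intensity", {
  set.seed(7)
  mz <- c(sample(dpToMz(3:10), 30, replace = TRUE) + runif(30, -0.4, 0.4),
          runif(5, 2000, 3000))
  peaks <- data.frame(mz = mz, intensity = rexp(35), label = "x")
  d <- aggregatePeaks(peaks)
  included <- !is.na(mzToDp(peaks$mz))
  expect_equal(sum(dpValues(d)), sum(peaks$intensity[included]))
})

test_that("synthetic peak tables round-trip exactly at zero noise", {
  ss <- findSteadyState(applyScheme(fructanNetwork(), "e"))
  d <- dpDistribution(ss)
  pk <- synthesizePeakTable(d, noiseSd = 0, seed = 3)
  suppressWarnings(back <- aggregatePeaks(pk))
  expect_equal(dpValues(back), dpValues(d))
  # determinism
  expect_identical(pk, synthesizePeakTable(d, noiseSd = 0, seed = 3))
  expect_false(identical(pk, synthesizePeakTable(d, noiseSd = 0, seed = 4)))
})

test_that("synthetic tables honour the observed isomer multiplicities", {
  d <- dpDistribution(findSteadyState(fructanNetwork()))
  pk <- synthesizePeakTable(d, seed = 11)
  dp <- mzToDp(pk$mz)
  counts <- table(dp)
  # DP3 carries its three kestose isomers plus the two contaminants
  expect_equal(as.vector(counts[as.character(3:10)]),
               c(5L, 4L, 4L, 4L, 4L, 3L, 1L, 2L))
  expect_setequal(pk$label[dp == 3],
                  c("1-kestose", "6-kestose", "6G-kestose", "raffinose",
                    "loliose"))
  expect_equal(sum(dp == 9), 1L)
})

test_that("round-trip error grows from zero with the noise scale", {
  d <- dpDistribution(findSteadyState(fructanNetwork()), "sum")
  err <- vapply(c(0, 0.02, 0.5), function(sd) {
    pk <- synthesizePeakTable(d, noiseSd = sd, seed = 5)
    suppressWarnings(back <- aggregatePeaks(pk))
    compareDistributions(back, d)
  }, numeric(1))
  expect_lt(err[1], 1e-25)  # zero up to normalization round-off
  expect_lt(err[2], err[3])
})

test_that("peak tables read back with malformed rows skipped", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("mz\tintensity\tlabel",
               "503.3\t10\t1-kestose",
               "oops\t5\t",
               "665.3\t-2\t",
               "827.3\t7\t"), path)
  expect_message(pk <- readPeakTable(path), "2 malformed")
  expect_equal(nrow(pk), 2L)
  expect_equal(pk$mz, c(503.3, 827.3))

  allBad <- tempfile()
  writeLines(c("mz\tintensity", "x\ty"), allBad)
  expect_error(suppressMessages(readPeakTable(allBad)), "all peak-table")

  out <- tempfile(fileext = ".tsv")
  writePeakTable(pk, out)
  expect_equal(readPeakTable(out), pk)
})
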