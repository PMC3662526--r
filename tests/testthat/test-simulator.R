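test_that("integration stays non-negative and lands on the root's state", {
  for (s in c("a", "d", "e")) {
    net <- applyScheme(fructanNetwork(), s)
    traj <- simulateNetwork(net, tEnd = 1000)
    expect_true(all(traj@conc >= 0))
    expect_true(traj@converged)
    root <- steadyStateRoot(net)
    w <- setdiff(speciesIds(net), c("glc", "gf10"))
    big <- w[root[w] > 1e-9]
    expect_lt(max(abs(traj@steadyState[big] - root[big]) / root[big]), 0.01)
  }
})

test_that("a vanishing horizon returns the initial state", {
  net <- fructanNetwork()
  traj <- simulateNetwork(net, tEnd = 1e-9, nPoints = 2)
  expect_equal(unname(traj@conc[nrow(traj@conc), ]),
               unname(initialState(net)), tolerance = 1e-6)
})

test_that("kestose and higher polymers overshoot to a decreasing extent", {
  traj <- simulateNetwork(applyScheme(fructanNetwork(), "a"), tEnd = 1e4)
  om <- overshootMetrics(traj)
  rownames(om) <- om$id
  expect_gt(om["gf2", "overshootRatio"], 1.01)
  expect_gt(om["gf2", "overshootRatio"], om["gf3", "overshootRatio"])
  expect_gt(om["gf3", "overshootRatio"], om["gf4", "overshootRatio"])
  expect_lt(om["gf2", "peakTime"], om["gf3", "peakTime"])
  expect_equal(om["glc", "overshootRatio"], 1)

  short <- simulateNetwork(fructanNetwork(), tEnd = 0.1)
  expect_false(short@converged)
  expect_error(overshootMetrics(short), "converged")
})

test_that("steady states reproduce the published concentrations", {
  net <- fructanNetwork()
  for (s in names(printedSteadyStates)) {
    ss <- findSteadyState(applyScheme(net, s))
    expect_true(attr(ss, "converged"), label = paste("scheme", s))
    p <- printedSteadyStates[[s]]
    expect_true(all(abs(ss[names(p)] - p) <= lastDigitTol(p)),
                label = paste("scheme", s, "printed precision"))
  }
})

test_that("the acceptor-depletion gap of the fast reaction is reproduced", {
  ss <- findSteadyState(applyScheme(fructanNetwork(), "c"))
  expect_equal(unname(ss["gf4"]), 0.0025, tolerance = 0.05)
  expect_true(all(abs(ss[paste0("gf", 5:9)] - 0.0058) < 0.0001))
  expect_lt(ss["gf4"], min(ss[paste0("gf", 5:9)]))
})

test_that("integration and Newton root agree and are tolerance-stable", {
  net <- fructanNetwork()
  for (s in names(printedSteadyStates)) {
    scheme <- applyScheme(net, s)
    ssI <- findSteadyState(scheme)
    ssR <- steadyStateRoot(scheme)
    w <- setdiff(speciesIds(net), c("glc", "gf10"))
    big <- w[ssI[w] > 1e-9]
    expect_lt(max(abs(ssR[big] - ssI[big]) / ssI[big]), 0.001,
              label = paste("scheme", s, "root agreement"))
  }
  # tightening the tolerance tenfold moves nothing by more than 0.01 %
  a <- applyScheme(net, "a")
  s1 <- findSteadyState(a, tol = 1e-9)
  s2 <- findSteadyState(a, tol = 1e-10, tMax = 2e4)
  w <- setdiff(speciesIds(net), c("glc", "gf10"))
  expect_lt(max(abs(s2[w] - s1[w]) / pmax(s1[w], 1e-9)), 1e-4)
})

test_that("an inert network stays at its initial conditions", {
  net <- fructanNetwork()
  net@reactions$vmax[] <- 0
  ss <- steadyStateRoot(net)
  expect_equal(as.numeric(ss), unname(initialState(net)))
})

test_that("scheme e orders gf8 below gf9 below gf4 at the root", {
  root <- steadyStateRoot(applyScheme(fructanNetwork(), "e"))
  expect_lt(root["gf8"], root["gf9"])
  expect_lt(root["gf9"], root["gf4"])
})

test_that("chain equalization and the halving property hold in scheme a", {
  ss <- findSteadyState(applyScheme(fructanNetwork(), "a"))
  chain <- ss[paste0("gf", 3:9)]
  expect_lt(diff(range(chain)) / mean(chain), 0.001)
  expect_true(all(abs(chain - ss["gf2"] / 2) / (ss["gf2"] / 2) < 0.03))
})

test_that("DP distributions extract gf2..gf9 and normalize correctly", {
  ssA <- findSteadyState(applyScheme(fructanNetwork(), "a"))
  raw <- dpDistribution(ssA, "raw")
  v <- dpValues(raw)
  expect_identical(names(v), paste0("DP", 3:10))
  expect_lt(diff(range(v[2:8])) / mean(v[2:8]), 0.001)
  expect_equal(unname(mean(v[2:8]) / v["DP3"]), 0.5, tolerance = 0.03)

  sm <- dpDistribution(ssA, "sum")
  expect_equal(sum(dpValues(sm)), 1, tolerance = 1e-12)
  mx <- dpDistribution(ssA, "max")
  expect_equal(max(dpValues(mx)), 1)

  ssE <- findSteadyState(applyScheme(fructanNetwork(), "e"))
  vE <- dpValues(dpDistribution(ssE))
  expect_equal(which.min(vE), c(DP9 = 7L))  # gf8 is the minimum
  expect_gt(vE["DP10"], vE["DP9"])

  empty <- initialState(fructanNetwork())
  expect_error(dpDistribution(empty, "sum"), "all-zero")
})

test_that("trajectory, state and DP files round-trip", {
  net <- applyScheme(fructanNetwork(), "b")
  traj <- simulateNetwork(net, tEnd = 50, nPoints = 40)
  tf <- tempfile(fileext = ".tsv")
  writeTrajectory(traj, tf)
  df <- read.delim(tf, check.names = FALSE)
  expect_identical(names(df), c("time", speciesIds(net)))
  expect_equal(df$gf2, unname(traj@conc[, "gf2"]))

  ss <- findSteadyState(net)
  sf <- tempfile(fileext = ".tsv")
  writeState(ss, sf)
  expect_equal(readState(sf), setNames(as.numeric(ss), names(ss)))

  d <- dpDistribution(ss)
  dfp <- tempfile(fileext = ".tsv")
  writeDPDistribution(d, dfp)
  expect_equal(dpValues(readDPDistribution(dfp)), dpValues(d))
})
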