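test_that("canonical network has the full species and reaction complement", {
  net <- fructanNetwork()
  expect_identical(speciesIds(net),
                   c("glc", "fru", paste0("gf", 1:10), "f2", "f3"))
  expect_length(reactionIds(net), 22L)
  # 2 interconversion + sucrose + kestose + gf3 synthesis + 7 gf2-donor
  # + 7 gf3-donor + 3 fructose-polymer transfers
  expect_setequal(reactionIds(net), c(
    "v_glc_fru", "v_fru_glc", "v_glcfru_gf1", "v_11_02", "v_22_13",
    sprintf("v_2%d_1%d", 3:9, 4:10), "v_33_24",
    sprintf("v_3%d_2%d", 4:9, 5:10),
    "v_2f1_1f2", "v_2f2_1f3", "v_2f3_5"))
  expect_identical(validateNetwork(net), character(0))
  expect_true(validObject(net))
})

test_that("default parameters follow the published table", {
  net <- fructanNetwork()
  v <- velocities(net)
  K <- setNames(net@reactions$K, net@reactions$id)
  core <- c("v_glc_fru", "v_fru_glc", "v_glcfru_gf1", "v_11_02", "v_22_13",
            sprintf("v_2%d_1%d", 3:9, 4:10))
  off <- setdiff(names(v), core)
  expect_true(all(v[core] == 1))
  expect_true(all(v[off] == 0))
  expect_equal(unname(K[c("v_glc_fru", "v_fru_glc")]), c(0.1, 0.1))
  expect_true(all(K[setdiff(names(K), c("v_glc_fru", "v_fru_glc"))] == 0.01))
  st <- initialState(net)
  expect_equal(unname(st["glc"]), 0.1)
  expect_true(all(st[setdiff(names(st), "glc")] == 0))
  expect_identical(net@species$clamped, c(TRUE, rep(FALSE, 13)))
})

test_that("every reaction conserves hexose units", {
  net <- fructanNetwork()
  hx <- setNames(net@species$hexoseUnits, net@species$id)
  for (i in seq_len(nrow(net@reactions))) {
    subs <- net@reactions$substrates[[i]]
    prods <- net@reactions$products[[i]]
    expect_identical(sum(hx[names(subs)] * subs),
                     sum(hx[names(prods)] * prods),
                     info = net@reactions$id[i])
  }
})

test_that("scheme presets set exactly the documented velocities", {
  net <- fructanNetwork()
  a <- applyScheme(net, "a")
  expect_identical(velocities(a), velocities(net))
  expect_true(all(velocities(a)[c("v_33_24", sprintf("v_3%d_2%d", 4:9, 5:10),
                                  "v_2f1_1f2", "v_2f2_1f3", "v_2f3_5")] == 0))

  b <- applyScheme(net, "b")
  expect_true(all(velocities(b)[c("v_33_24",
                                  sprintf("v_3%d_2%d", 4:9, 5:10))] == 1))

  cc <- applyScheme(net, "c")
  expect_equal(unname(velocities(cc)["v_34_25"]), 10)

  d <- applyScheme(net, "d")
  expect_equal(unname(velocities(d)[c("v_22_13", "v_2f1_1f2", "v_2f2_1f3",
                                      "v_2f3_5")]), c(0, 1, 1, 1))

  e <- applyScheme(net, "e")
  expect_equal(
    unname(velocities(e)[c("v_22_13", "v_24_15", "v_25_16", "v_26_17",
                           "v_27_18", "v_28_19", "v_29_110")]),
    c(2, 2, 2, 2, 2, 10, 4))
  # presets only touch velocities, never topology or K
  for (s in list(a, b, cc, d, e)) {
    expect_identical(s@reactions$K, net@reactions$K)
    expect_identical(s@reactions$substrates, net@reactions$substrates)
  }
})

test_that("applyScheme is pure, idempotent and commutes on disjoint sets", {
  net <- fructanNetwork()
  before <- velocities(net)
  out <- applyScheme(net, "c")
  expect_identical(velocities(net), before)  # input unmodified
  expect_identical(velocities(applyScheme(out, "c")), velocities(out))
  expect_identical(applyScheme(net, c()), net)

  o1 <- c(v_22_13 = 3); o2 <- c(v_34_25 = 7)
  expect_identical(
    velocities(applyScheme(applyScheme(net, o1), o2)),
    velocities(applyScheme(applyScheme(net, o2), o1)))
})

test_that("applyScheme rejects unknown ids and negative velocities", {
  net <- fructanNetwork()
  expect_error(applyScheme(net, c(v_bogus_1 = 1)), "v_bogus_1")
  expect_error(applyScheme(net, c(v_22_13 = -1)), "non-negative")
  expect_error(applyScheme(net, "z"), "unknown scheme")
})

test_that("validateNetwork reports violations instead of raising", {
  net <- fructanNetwork()
  badK <- net
  badK@reactions$K[5] <- 0
  expect_length(validateNetwork(badK), 1L)
  expect_match(validateNetwork(badK), "non-positive K")

  # fabricated non-conserving reaction: 2 gf2 (3+3 units) -> gf1 + gf4 (2+5)
  badRx <- net
  badRx@reactions$products[[which(badRx@reactions$id == "v_22_13")]] <-
    c(gf1 = 1L, gf4 = 1L)
  expect_match(validateNetwork(badRx), "hexose-unit conservation")
})

test_that("network config files round-trip velocities, K and clamp", {
  net <- applyScheme(fructanNetwork(glcClamp = 0.2), "e")
  net@reactions$K[3] <- 0.05
  path <- tempfile(fileext = ".cfg")
  writeNetworkConfig(net, path)
  back <- readNetworkConfig(path)
  expect_identical(velocities(back), velocities(net))
  expect_identical(back@reactions$K, net@reactions$K)
  expect_identical(initialState(back), initialState(net))
  expect_error(readNetworkConfig(
    {p <- tempfile(); writeLines("v_nope = 1", p); p}), "v_nope")
})
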