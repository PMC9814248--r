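test_that("constant areas give flat percent-of-initial series", {
  fits <- list()
  for (tp in c(0, 1000, 2000)) {
    fits <- c(fits,
      makeFit("C1s", tp, c("C1s_285", "C1s_286"), c(2, 3)),
      makeFit("P2p", tp, c("P2p_32", "P2p_12"), c(2 / 3, 1 / 3)))
  }
  series <- normalizeSeries(fits)
  d <- seriesData(series$C1s)
  expect_equal(unique(d$percentOfInitial[d$component == "C1s_285"]), 40)
  expect_equal(unique(d$percentOfInitial[d$component == "C1s_286"]), 60)
  # non-gas percent sums to 100 at t0 (class invariant)
  d0 <- d[d$timepoint == 0 & !d$isGasPhase, ]
  expect_equal(sum(d0$percentOfInitial), 100, tolerance = 1e-9)
})

test_that("normalized areas are invariant to a common intensity rescale", {
  mk <- function(f) list(
    makeFit("C1s", 0, c("C1s_285", "C1s_286"), f * c(2, 3)),
    makeFit("C1s", 1000, c("C1s_285", "C1s_286"), c(2, 2.5)),
    makeFit("P2p", 0, c("P2p_32", "P2p_12"), f * c(2 / 3, 1 / 3)),
    makeFit("P2p", 1000, c("P2p_32", "P2p_12"), c(2 / 3, 1 / 3)))
  s1 <- normalizeSeries(mk(1))
  s2 <- normalizeSeries(mk(7.5))   # t0 intensities rescaled by 7.5
  expect_equal(seriesData(s1$C1s)$normalizedArea,
               seriesData(s2$C1s)$normalizedArea, tolerance = 1e-12)
})

test_that("an exponentially decaying component matches the closed form", {
  k <- 2e-5; tps <- seq(0, 7200, by = 1800)
  sc <- smallC1sScenario(timepoints = tps)
  gen <- generateSeries(sc, seed = 31)
  fits <- fitRegionSeries(gen$series, fixModelWidths(sc@regionModels$C1s))
  # reference region known exactly (the generator's constant P2p)
  p2p <- lapply(tps, function(tp)
    makeFit("P2p", tp, c("P2p_32", "P2p_12"), c(2 / 3, 1 / 3)))
  series <- normalizeSeries(c(fits, p2p))
  d <- seriesData(series$C1s)
  d6 <- d[d$component == "C1s_286", ]
  a0 <- 3.3; tot0 <- 2 + 3.3 + 1.7 + 1.2
  expected <- 100 * a0 * exp(-k * tps) / tot0
  relDev <- (d6$percentOfInitial - expected) / expected
  expect_lt(sqrt(mean(relDev^2)), 5e-3)       # series-level agreement
  expect_lt(max(abs(relDev)), 2e-2)           # no single point breaks away
})

test_that("missing reference timepoints are dropped with a warning", {
  fits <- list(
    makeFit("C1s", 0, "C1s_286", 3), makeFit("C1s", 100, "C1s_286", 2),
    makeFit("P2p", 0, c("P2p_32", "P2p_12"), c(2 / 3, 1 / 3)))
  expect_warning(series <- normalizeSeries(fits), "dropping")
  expect_equal(unique(seriesData(series$C1s)$timepoint), 0)
})

test_that("strand-break index handles identity, halving and error cases", {
  mkSeries <- function(endFrac) {
    fits <- list(
      makeFit("C1s", 0, c("C1s_285", "C1s_286"), c(2, 3)),
      makeFit("C1s", 100, c("C1s_285", "C1s_286"), c(2, 3 * endFrac)),
      makeFit("P2p", 0, c("P2p_32", "P2p_12"), c(2 / 3, 1 / 3)),
      makeFit("P2p", 100, c("P2p_32", "P2p_12"), c(2 / 3, 1 / 3)))
    normalizeSeries(fits)$C1s
  }
  expect_equal(strandBreakIndex(mkSeries(1))[["value"]], 0)
  expect_equal(strandBreakIndex(mkSeries(0.5))[["value"]], 0.5)
  expect_error(strandBreakIndex(mkSeries(1), component = "C1s_999"),
               "not present")
  # start area of zero -> undefined-index error
  zeroStart <- normalizeSeries(list(
    makeFit("C1s", 0, c("C1s_285", "C1s_286"), c(2, 0)),
    makeFit("C1s", 100, c("C1s_285", "C1s_286"), c(2, 1)),
    makeFit("P2p", 0, c("P2p_32", "P2p_12"), c(2 / 3, 1 / 3)),
    makeFit("P2p", 100, c("P2p_32", "P2p_12"), c(2 / 3, 1 / 3))))$C1s
  expect_error(strandBreakIndex(zeroStart), "undefined")
})

test_that("base-damage index sums non-gas nitrogen and reduces correctly", {
  fits <- list(
    makeFit("N1s", 0, c("N1s_399", "N1s_401", "N1s_405"),
            c(3, 2, 0.8), gas = c(FALSE, FALSE, TRUE)),
    makeFit("N1s", 100, c("N1s_399", "N1s_401", "N1s_405"),
            c(2.4, 1.6, 0.8), gas = c(FALSE, FALSE, TRUE)),
    makeFit("P2p", 0, c("P2p_32", "P2p_12"), c(2 / 3, 1 / 3)),
    makeFit("P2p", 100, c("P2p_32", "P2p_12"), c(2 / 3, 1 / 3)))
  series <- normalizeSeries(fits)
  bd <- baseDamageIndex(series$N1s)
  expect_equal(bd[["value"]], 0.2, tolerance = 1e-12)   # gas line excluded
  # single-component region: index equals that component's decrease
  fits2 <- list(
    makeFit("N1s", 0, "N1s_399", 3), makeFit("N1s", 100, "N1s_399", 2.1),
    makeFit("P2p", 0, c("P2p_32", "P2p_12"), c(2 / 3, 1 / 3)),
    makeFit("P2p", 100, c("P2p_32", "P2p_12"), c(2 / 3, 1 / 3)))
  expect_equal(baseDamageIndex(normalizeSeries(fits2)$N1s)[["value"]],
               0.3, tolerance = 1e-12)
  # constant series -> 0
  fits3 <- list(
    makeFit("N1s", 0, "N1s_399", 3), makeFit("N1s", 100, "N1s_399", 3),
    makeFit("P2p", 0, c("P2p_32", "P2p_12"), c(2 / 3, 1 / 3)),
    makeFit("P2p", 100, c("P2p_32", "P2p_12"), c(2 / 3, 1 / 3)))
  expect_equal(baseDamageIndex(normalizeSeries(fits3)$N1s)[["value"]], 0)
})

test_that("water per nucleotide follows the RSF-corrected O:P ratio", {
  p2p <- makeFit("P2p", 0, c("P2p_32", "P2p_12"), c(2 / 3, 1 / 3))
  rsf <- c(O1s = 2, P2p = 1)
  # zero water -> 0
  o0 <- makeFit("O1s", 0, c("O1s_531", "O1s_535"), c(5, 0),
                gas = c(FALSE, TRUE))
  expect_equal(waterPerNucleotide(o0, p2p, rsf)[["value"]], 0)
  # corrected O:P ratio exactly 5 -> 5.0
  o5 <- makeFit("O1s", 0, c("O1s_531", "O1s_535"), c(5, 5 * 2 * 1),
                gas = c(FALSE, TRUE))
  expect_equal(waterPerNucleotide(o5, p2p, rsf)[["value"]], 5.0)
  expect_error(waterPerNucleotide(o5, p2p, c(O1s = 2)), "configuration")
})

test_that("strand-break index strictly increases with the backbone decay rate", {
  rates <- c(0.5, 1, 2, 4, 8) * 1e-5
  idx <- vapply(rates, function(k) {
    models <- dnaRegionModels()
    sc <- damageScenario("mono", models["C1s"],
      initialAreas = c(C1s_285 = 2.0, C1s_286 = 3.3, C1s_288 = 1.7,
                       C1s_289 = 1.2),
      rates = c(C1s_286 = k), timepoints = c(0, 7200), atmosphere = "N2")
    gen <- generateSeries(sc, seed = 77)
    fits <- fitRegionSeries(gen$series, fixModelWidths(models$C1s))
    p2p <- lapply(c(0, 7200), function(tp)
      makeFit("P2p", tp, c("P2p_32", "P2p_12"), c(2 / 3, 1 / 3)))
    strandBreakIndex(normalizeSeries(c(fits, p2p))$C1s)[["value"]]
  }, numeric(1))
  expect_true(all(diff(idx) > 0))
})

test_that("damageReport assembles indices and end/start ratios", {
  fits <- list(
    makeFit("C1s", 0, "C1s_286", 3, sigmas = 0.03),
    makeFit("C1s", 100, "C1s_286", 2.4, sigmas = 0.03),
    makeFit("N1s", 0, "N1s_399", 3, sigmas = 0.03),
    makeFit("N1s", 100, "N1s_399", 2.7, sigmas = 0.03),
    makeFit("P2p", 0, c("P2p_32", "P2p_12"), c(2 / 3, 1 / 3)),
    makeFit("P2p", 100, c("P2p_32", "P2p_12"), c(2 / 3, 1 / 3)))
  series <- normalizeSeries(fits)
  rep <- damageReport(series, condition = list(gas = "N2"))
  expect_equal(rep@strandBreak[["value"]], 0.2, tolerance = 1e-12)
  expect_equal(rep@baseDamage[["value"]], 0.1, tolerance = 1e-12)
  expect_true(rep@strandBreak[["sigma"]] > 0)
  expect_true(all(c("region", "component", "ratio") %in%
                    names(rep@endStartRatios)))
})
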