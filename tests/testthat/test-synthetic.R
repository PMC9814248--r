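test_that("generation is bitwise deterministic in the seed", {
  sc <- smallC1sScenario()
  a <- generateSeries(sc, seed = 123)
  b <- generateSeries(sc, seed = 123)
  expect_identical(lapply(seq_len(length(a$series)),
                          function(i) intensity(a$series[[i]])),
                   lapply(seq_len(length(b$series)),
                          function(i) intensity(b$series[[i]])))
  expect_identical(a$truth@areas, b$truth@areas)
  c2 <- generateSeries(sc, seed = 124)
  expect_false(identical(intensity(a$series[[1]]), intensity(c2$series[[1]])))
})

test_that("zero rates without noise give identical timepoints", {
  models <- dnaRegionModels()
  sc <- damageScenario("flat", models["C1s"],
    initialAreas = c(C1s_285 = 2, C1s_286 = 3, C1s_288 = 1.5, C1s_289 = 1),
    rates = numeric(0), timepoints = c(0, 1000, 2000), atmosphere = "vacuum")
  gen <- generateSeries(sc, seed = 1, noise = FALSE)
  y <- lapply(seq_len(length(gen$series)),
              function(i) intensity(gen$series[[i]]))
  expect_identical(y[[1]], y[[2]])
  expect_identical(y[[2]], y[[3]])
})

test_that("first-order kinetics halve the area when k t equals log(2)", {
  tEnd <- 7200
  k <- log(2) / tEnd
  models <- dnaRegionModels()
  sc <- damageScenario("halving", models["C1s"],
    initialAreas = c(C1s_285 = 0, C1s_286 = 4, C1s_288 = 0, C1s_289 = 0),
    rates = c(C1s_286 = k), timepoints = c(0, tEnd), atmosphere = "vacuum")
  gen <- generateSeries(sc, seed = 1, noise = FALSE)
  tr <- gen$truth@areas
  a0 <- tr$area[tr$component == "C1s_286" & tr$timepoint == 0]
  a1 <- tr$area[tr$component == "C1s_286" & tr$timepoint == tEnd]
  expect_equal(a1, a0 / 2, tolerance = 1e-12)
})

test_that("the Poisson scale hits the requested peak signal-to-noise", {
  sc <- smallC1sScenario(snr = 80)
  gen <- generateSeries(sc, seed = 1, noise = FALSE)
  peakMax <- max(vapply(seq_len(length(gen$series)),
                        function(i) max(intensity(gen$series[[i]])),
                        numeric(1)))
  expect_equal(peakMax, 80^2, tolerance = 1e-9)
})

test_that("Poisson noise has variance equal to its mean", {
  models <- dnaRegionModels()
  sc <- damageScenario("tiny", models["C1s"],
    initialAreas = c(C1s_285 = 2, C1s_286 = 3, C1s_288 = 1.5, C1s_289 = 1),
    rates = numeric(0), timepoints = c(0, 10), atmosphere = "vacuum",
    gridStep = 0.5, snr = 60)
  base <- generateSeries(sc, seed = 1, noise = FALSE)
  lam <- intensity(base$series[[1]])
  draws <- matrix(0, 1000, length(lam))
  for (r in seq_len(1000))
    draws[r, ] <- intensity(generateSeries(sc, seed = r)$series[[1]])
  pick <- order(lam, decreasing = TRUE)[c(1, 5, 15)]
  for (j in pick) {
    expect_equal(mean(draws[, j]), lam[j], tolerance = 0.05)
    expect_equal(var(draws[, j]) / lam[j], 1, tolerance = 0.15)
  }
})

test_that("presets encode the programmed atmosphere contrasts exactly", {
  ps <- presetScenarios()
  expect_equal(ps$H2O@rates[["C1s_286"]] / ps$N2@rates[["C1s_286"]], 2)
  nRateH <- ps$H2O@rates[c("N1s_399", "N1s_401")]
  nRateN <- ps$N2@rates[c("N1s_399", "N1s_401")]
  expect_equal(unname(nRateH / nRateN), c(3, 3))
  # vacuum sits slightly below N2
  expect_lt(ps$vacuum@rates[["C1s_286"]], ps$N2@rates[["C1s_286"]])
  expect_lt(ps$vacuum@rates[["N1s_399"]], ps$N2@rates[["N1s_399"]])
  # the N2 scenario carries the gas-phase nitrogen line, H2O does not
  expect_true("N1s_405" %in% names(ps$N2@initialAreas))
  expect_false("N1s_405" %in%
                 componentLabels(ps$H2O@regionModels$N1s))
})

test_that("scenario validity rejects bad inputs", {
  models <- dnaRegionModels()
  expect_error(damageScenario("bad", models["C1s"],
    initialAreas = c(C1s_285 = -1, C1s_286 = 3, C1s_288 = 1, C1s_289 = 1),
    rates = numeric(0), timepoints = c(0, 10)), "initial areas")
  expect_error(damageScenario("bad", models["C1s"],
    initialAreas = c(C1s_285 = 1, C1s_286 = 3, C1s_288 = 1, C1s_289 = 1),
    rates = numeric(0), timepoints = c(10, 10)), "increasing")
})
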