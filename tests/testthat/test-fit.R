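test_that("noiseless four-component region is recovered to spec precision", {
  sc <- smallC1sScenario()
  gen <- generateSeries(sc, seed = 1, noise = FALSE)
  fit <- fitRegion(gen$series[[1]], sc@regionModels$C1s)
  expect_true(converged(fit))
  truth0 <- gen$truth@areas[gen$truth@areas$timepoint == 0, ]
  ca <- componentAreas(fit)
  i <- match(ca$label, truth0$component)
  relErr <- abs(ca$area / gen$truth@scale / truth0$area[i] - 1)
  expect_lt(max(relErr), 1e-3)
  ctr <- vapply(fit@model@components, function(p) p@center, numeric(1))
  expect_lt(max(abs(ctr - truth0$center[i])), 0.01)
})

test_that("stored curves reproduce the input counts exactly", {
  sc <- smallC1sScenario()
  gen <- generateSeries(sc, seed = 7)
  s <- gen$series[[1]]
  fit <- fitRegion(s, sc@regionModels$C1s)
  comp <- Reduce(`+`, lapply(fit@model@components, function(p)
    voigtProfile(bindingEnergy(s), p@center, p@area, p@gaussianFwhm,
                 p@lorentzianFwhm)))
  expect_equal(comp + backgroundCurve(fit) + residuals(fit), intensity(s),
               tolerance = 1e-12)
})

test_that("a single fixed-zero-area component leaves counts minus background", {
  sc <- smallC1sScenario()
  gen <- generateSeries(sc, seed = 3)
  s <- gen$series[[1]]
  m <- regionModel("C1s", list(
    peakComponent("only", 286, area = 0,
                  fixed = c("area", "center", "gaussianFwhm",
                            "lorentzianFwhm"))))
  fit <- fitRegion(s, m, fitBackgroundOffsets = FALSE,
                   reiterateBackground = 0)
  expect_equal(residuals(fit), intensity(s) - backgroundCurve(fit),
               tolerance = 1e-12)
  expect_equal(componentAreas(fit)$area, 0)
  expect_equal(componentAreas(fit)$sigma, 0)
})

test_that("the P2p doublet link enforces the 2:1 ratio and 1 eV splitting", {
  models <- dnaRegionModels()
  sc <- damageScenario("p2p", models["P2p"],
    initialAreas = c(P2p_32 = 2 / 3, P2p_12 = 1 / 3),
    rates = numeric(0), timepoints = c(0, 3600), atmosphere = "N2")
  gen <- generateSeries(sc, seed = 2)
  fit <- fitRegion(gen$series[[1]], models$P2p)
  ca <- componentAreas(fit)
  expect_equal(ca$area[ca$label == "P2p_32"] / ca$area[ca$label == "P2p_12"],
               2, tolerance = 1e-12)
  ctr <- vapply(fit@model@components, function(p) p@center, numeric(1))
  expect_equal(unname(diff(ctr)), 1.0, tolerance = 1e-12)
})

test_that("non-convergence is flagged, never silent", {
  sc <- smallC1sScenario()
  gen <- generateSeries(sc, seed = 4)
  fit <- suppressWarnings(fitRegion(gen$series[[1]], sc@regionModels$C1s,
                                    maxIter = 1))
  expect_false(converged(fit))
  expect_true(any(grepl("converge", fit@messages)))
})

test_that("warm-started series fits stay ordered and labelled", {
  sc <- smallC1sScenario(timepoints = c(0, 1800, 3600))
  gen <- generateSeries(sc, seed = 5)
  fits <- fitRegionSeries(gen$series, fixModelWidths(sc@regionModels$C1s))
  expect_length(fits, 3)
  tps <- vapply(fits, function(f) f@spectrumInfo$timepoint, numeric(1))
  expect_equal(tps, c(0, 1800, 3600))
  for (f in fits)
    expect_equal(componentAreas(f)$label,
                 c("C1s_285", "C1s_286", "C1s_288", "C1s_289"))
})

test_that("amplitude-only fits reproduce closed-form linear least squares", {
  x <- seq(278, 296, by = 0.05)
  m <- dnaRegionModels()$C1s
  m@components <- lapply(m@components, function(p) {
    p@fixed <- c("center", "gaussianFwhm", "lorentzianFwhm")
    p
  })
  set.seed(99)
  truthAreas <- c(4000, 8000, 3500, 2500)
  curve <- Reduce(`+`, Map(function(p, a)
    voigtProfile(x, p@center, a, p@gaussianFwhm, p@lorentzianFwhm),
    m@components, truthAreas)) + 200
  y <- curve + rnorm(length(x), 0, 10)
  y <- pmax(y, 0)
  fit <- fitRegion(Spectrum("C1s", x, y), m, weighting = "none",
                   fitBackgroundOffsets = FALSE, reiterateBackground = 0,
                   initAreasFromData = FALSE)
  # closed form: unweighted LSQ of (y - bg) on the unit profiles
  X <- vapply(m@components, function(p)
    voigtProfile(x, p@center, 1, p@gaussianFwhm, p@lorentzianFwhm),
    numeric(length(x)))
  yc <- y - backgroundCurve(fit)
  XtXi <- solve(crossprod(X))
  beta <- drop(XtXi %*% crossprod(X, yc))
  resid <- yc - X %*% beta
  s2 <- sum(resid^2) / (length(x) - 4)
  sigmaRef <- sqrt(s2 * diag(XtXi))
  ca <- componentAreas(fit)
  expect_equal(ca$area, beta, tolerance = 1e-8)
  expect_equal(ca$sigma, sigmaRef, tolerance = 1e-7)
  # estimateUncertainties reproduces the stored sigmas
  su <- estimateUncertainties(fit)
  expect_equal(unname(su), ca$sigma, tolerance = 1e-7)
})

test_that("zero-residual fits report zero uncertainty", {
  # pure Gaussian line (no Lorentzian tails) on a flat background: the
  # Shirley estimate is exact and the model reproduces the data to
  # rounding, so the residual-variance scale collapses to zero
  x <- seq(278, 296, by = 0.1)
  m <- regionModel("C1s", list(
    peakComponent("one", 286, area = 1000, lorentzianFwhm = 0,
                  fixed = c("center", "gaussianFwhm", "lorentzianFwhm"))))
  y <- voigtProfile(x, 286, 1000, 1.3, 0) + 50
  fit <- fitRegion(Spectrum("C1s", x, y), m, weighting = "none",
                   fitBackgroundOffsets = FALSE, reiterateBackground = 0)
  expect_lt(fit@reducedChiSquare, 1e-12)
  expect_lt(componentAreas(fit)$sigma, 1e-4)
})

test_that("doubling the noise doubles the reported area sigmas", {
  x <- seq(278, 296, by = 0.05)
  m <- dnaRegionModels()$C1s
  m@components <- lapply(m@components, function(p) {
    p@fixed <- c("center", "gaussianFwhm", "lorentzianFwhm"); p })
  curve <- Reduce(`+`, lapply(m@components, function(p)
    voigtProfile(x, p@center, 5000, p@gaussianFwhm, p@lorentzianFwhm))) + 300
  sig1 <- sig2 <- NULL
  set.seed(11)
  for (r in 1:50) {
    y1 <- pmax(curve + rnorm(length(x), 0, 15), 0)
    y2 <- pmax(curve + rnorm(length(x), 0, 30), 0)
    f1 <- fitRegion(Spectrum("C1s", x, y1), m, weighting = "none",
                    fitBackgroundOffsets = FALSE, reiterateBackground = 0)
    f2 <- fitRegion(Spectrum("C1s", x, y2), m, weighting = "none",
                    fitBackgroundOffsets = FALSE, reiterateBackground = 0)
    sig1 <- c(sig1, mean(componentAreas(f1)$sigma))
    sig2 <- c(sig2, mean(componentAreas(f2)$sigma))
  }
  expect_equal(mean(sig2) / mean(sig1), 2, tolerance = 0.1)
})

test_that("covariance is symmetric positive semi-definite with named rows", {
  sc <- smallC1sScenario()
  gen <- generateSeries(sc, seed = 8)
  fit <- fitRegion(gen$series[[1]], sc@regionModels$C1s)
  cv <- fit@covariance
  expect_true(isSymmetric(unname(cv), tol = 1e-10))
  expect_gte(min(eigen(cv, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8 * max(abs(cv)))
  expect_true(all(grepl("^(area|center|gw|lw|bg)_", rownames(cv))))
})

test_that("fit preconditions are enforced", {
  s <- Spectrum("C1s", seq(282, 292, by = 0.5), rep(10, 21))
  expect_error(fitRegion(s, dnaRegionModels()$C1s), "free parameters")
  s2 <- Spectrum("C1s", seq(260, 270, by = 0.05), rep(10, 201))
  expect_error(fitRegion(s2, dnaRegionModels()$C1s), "outside")
})
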