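test_that("pure-width limits match the Gaussian and Lorentzian closed forms", {
  x <- seq(280, 292, by = 0.01)
  sigma <- 1.2 / (2 * sqrt(2 * log(2)))
  gauss <- 700 * exp(-(x - 286)^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
  expect_lt(max(abs(voigtProfile(x, 286, 700, 1.2, 0) - gauss) / gauss),
            1e-10)
  gamma <- 0.4 / 2
  lor <- 700 * gamma / (pi * ((x - 286)^2 + gamma^2))
  expect_lt(max(abs(voigtProfile(x, 286, 700, 0, 0.4) - lor) / lor), 1e-10)
  expect_error(voigtProfile(x, 286, 700, 0, 0), "degenerate")
})

test_that("quadrature recovers the area to 1e-6 relative", {
  cases <- list(c(1.3, 0.2), c(0.8, 0.6), c(2.5, 0.05), c(1.0, 1.0))
  for (cs in cases) {
    q <- integrate(function(t) voigtProfile(t, 0, 1234, cs[1], cs[2]),
                   -Inf, Inf, rel.tol = 1e-10, subdivisions = 2000L)
    expect_lt(abs(q$value - 1234) / 1234, 1e-6)
    # a +/- 40 FWHM window misses only the Lorentzian tail mass,
    # bounded by 2 gamma / (pi * 40 fw)
    fw <- voigtFwhm(cs[1], cs[2])
    qw <- integrate(function(t) voigtProfile(t, 0, 1234, cs[1], cs[2]),
                    -40 * fw, 40 * fw, rel.tol = 1e-10,
                    subdivisions = 2000L)
    tailBound <- 2 * (cs[2] / 2) / (pi * 40 * fw)
    expect_lt(abs(qw$value - 1234) / 1234, tailBound * 1.2 + 1e-9)
  }
})

test_that("the profile is symmetric about its center", {
  d <- seq(0.05, 6, by = 0.05)
  left  <- voigtProfile(286 - d, 286, 100, 1.3, 0.3)
  right <- voigtProfile(286 + d, 286, 100, 1.3, 0.3)
  expect_equal(left, right, tolerance = 1e-12)
})

test_that("area is conserved under grid refinement and FWHM grows with widths", {
  grids <- c(0.1, 0.05, 0.01)
  areas <- vapply(grids, function(step) {
    x <- seq(270, 302, by = step)
    sum(voigtProfile(x, 286, 500, 1.3, 0.2)) * step
  }, numeric(1))
  expect_lt(max(abs(areas - 500) / 500), 5e-3)   # finite-window tails
  expect_lt(max(abs(areas - areas[3])) / 500, 1e-4)  # grid-independent
  # numeric FWHM increases monotonically in each width parameter
  numFwhm <- function(gw, lw) {
    x <- seq(-15, 15, by = 0.001)
    y <- voigtProfile(x, 0, 1, gw, lw)
    rng <- range(x[y >= max(y) / 2])
    diff(rng)
  }
  gws <- c(0.7, 1.0, 1.5, 2.2)
  expect_true(all(diff(vapply(gws, numFwhm, numeric(1), lw = 0.3)) > 0))
  lws <- c(0.05, 0.2, 0.4, 0.6)
  expect_true(all(diff(vapply(lws, numFwhm, numeric(1), gw = 1.3)) > 0))
})

test_that("the Faddeeva evaluation agrees with an independent route", {
  # w(z) = exp(-z^2) erfc(-iz) through pracma's complex error function
  zs <- c(0.3 + 0.1i, 1 + 1i, 0.01 + 3i, 10 + 0.5i, 2 + 0i, 7 + 2i)
  w1 <- xpsdamage:::faddeeva(zs)
  w2 <- exp(-zs^2) * (1 - pracma::erfz(-1i * zs))
  expect_lt(max(abs(w1 - w2) / abs(w2)), 1e-10)
})

test_that("analytic Voigt derivatives match numeric differentiation", {
  x <- seq(282, 290, by = 0.05)
  g <- xpsdamage:::.voigtGrad(x, 286.1, 850, 1.25, 0.3)
  h <- 1e-6
  numd <- function(f) (f(h) - f(-h)) / (2 * h)
  dC <- numd(function(e) voigtProfile(x, 286.1 + e, 850, 1.25, 0.3))
  dA <- numd(function(e) voigtProfile(x, 286.1, 850 + e, 1.25, 0.3))
  dG <- numd(function(e) voigtProfile(x, 286.1, 850, 1.25 + e, 0.3))
  dL <- numd(function(e) voigtProfile(x, 286.1, 850, 1.25, 0.3 + e))
  scale <- max(abs(g$V))
  expect_lt(max(abs(g$dC - dC)) / max(abs(dC)), 1e-6)
  expect_lt(max(abs(g$dA - dA)) / max(abs(dA)), 1e-6)
  expect_lt(max(abs(g$dGw - dG)) / max(abs(dG)), 1e-6)
  expect_lt(max(abs(g$dLw - dL)) / max(abs(dL)), 1e-6)
  expect_equal(g$V, voigtProfile(x, 286.1, 850, 1.25, 0.3),
               tolerance = 1e-12)
})

test_that("pseudo-Voigt option is area-normalized and close to true Voigt", {
  x <- seq(-30, 30, by = 0.01)
  y <- voigtProfile(x, 0, 1000, 1.3, 0.4, shape = "pseudo")
  expect_lt(abs(sum(y) * 0.01 - 1000) / 1000, 2e-2)
  yv <- voigtProfile(x, 0, 1000, 1.3, 0.4)
  expect_lt(max(abs(y - yv)) / max(yv), 0.02)
})
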