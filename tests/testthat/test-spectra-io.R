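test_that("delimited spectra read back regardless of row order and dialect", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("# region: C1s", "# timepoint: 5", "# atmosphere: N2",
               "binding_energy\tcounts",
               "285.0\t10", "286.0\t20", "287.0\t10"), tmp)
  s <- readSpectrum(tmp)
  expect_s4_class(s, "Spectrum")
  expect_equal(bindingEnergy(s), c(285, 286, 287))
  expect_equal(intensity(s), c(10, 20, 10))
  expect_equal(timepoint(s), 5)
  expect_equal(atmosphere(s), "N2")

  # same rows in descending order -> identical spectrum
  tmp2 <- tempfile(fileext = ".tsv")
  writeLines(c("# region: C1s", "# timepoint: 5", "# atmosphere: N2",
               "binding_energy\tcounts",
               "287.0\t10", "286.0\t20", "285.0\t10"), tmp2)
  expect_equal(readSpectrum(tmp2), s)

  # csv dialect
  tmp3 <- tempfile(fileext = ".csv")
  writeLines(c("# region: O1s", "binding_energy,counts",
               "531,5", "532,6", "533,7"), tmp3)
  expect_equal(intensity(readSpectrum(tmp3, dialect = "csv")), c(5, 6, 7))
})

test_that("format and validation errors are specific", {
  bad <- tempfile()
  writeLines(c("# region: C1s", "binding_energy\tcounts",
               "285\t10", "286\t-1", "287\t10"), bad)
  expect_error(readSpectrum(bad), "row 2")
  noCols <- tempfile()
  writeLines(c("energy\tvalue", "285\t10"), noCols)
  expect_error(readSpectrum(noCols), "format error")
  dup <- tempfile()
  writeLines(c("# region: C1s", "binding_energy\tcounts",
               "285\t10", "285\t11", "286\t9"), dup)
  expect_error(readSpectrum(dup), "strictly increasing")
  expect_error(readSpectrum(tempfile()), "not found")
})

test_that("write/read round trip preserves a spectrum exactly", {
  s <- Spectrum("N1s", seq(393, 411, by = 0.07), runif(258, 0, 1e4),
                timepoint = 123.456, atmosphere = "H2O")
  tmp <- tempfile(fileext = ".tsv")
  writeSpectrum(s, tmp)
  s2 <- readSpectrum(tmp)
  expect_equal(bindingEnergy(s2), bindingEnergy(s))
  expect_equal(intensity(s2), intensity(s))
  expect_equal(timepoint(s2), timepoint(s))
  expect_error(writeSpectrum(s, tmp), "exists")
})

test_that("extractRegion windows the grid, closed on both ends", {
  s <- Spectrum("C1s", seq(280, 295, by = 0.5), rep(10, 31))
  w <- extractRegion(s, c(283, 291))
  expect_true(all(bindingEnergy(w) >= 283 & bindingEnergy(w) <= 291))
  expect_equal(range(bindingEnergy(w)), c(283, 291))
  expect_equal(extractRegion(s, c(280, 295)), s)
  expect_error(extractRegion(s, c(500, 510)), "window error")
  expect_error(extractRegion(s, c(280, 281.4)), "window error")
})

test_that("grid-uniformity tolerances warn then error", {
  be <- c(seq(280, 285, by = 0.5), 285.58)   # ~16 % deviation
  expect_warning(Spectrum("C1s", be, rep(1, length(be))), "uniform")
  be2 <- c(seq(280, 285, by = 0.5), 285.7)   # ~40 % deviation
  expect_error(Spectrum("C1s", be2, rep(1, length(be2))), "uniform")
})

test_that("report writing is round-trip safe at full precision", {
  d <- data.frame(
    timepoint = rep(c(0, 3600), each = 2),
    component = rep(c("C1s_285", "C1s_286"), 2),
    isGasPhase = FALSE,
    normalizedArea = c(1 / 3, 2 / 3, 0.3211234567891234, 0.6301234567891),
    normalizedSigma = rep(0.01234567890123456, 4))
  d$percentOfInitial <- 100 * d$normalizedArea / sum(d$normalizedArea[1:2])
  d$percentSigma <- d$percentOfInitial * 0.02
  as1 <- new("AreaSeries", region = "C1s", data = d)
  rep1 <- new("DamageReport", condition = list(gas = "N2"),
              strandBreak = c(value = 0.1234, sigma = 0.01),
              baseDamage = c(value = 0.07, sigma = 0.02),
              endStartRatios = data.frame())
  dir <- tempfile()
  files <- writeReport(list(C1s = as1), rep1, dir)
  back <- readAreaSeries(files[["areaSeries"]])
  expect_equal(back$C1s@data$normalizedArea, d$normalizedArea,
               tolerance = 0)
  expect_equal(back$C1s@data$percentSigma, d$percentSigma, tolerance = 0)
  # collision without overwrite errors; with overwrite succeeds
  expect_error(writeReport(list(C1s = as1), rep1, dir), "exists")
  expect_silent(writeReport(list(C1s = as1), rep1, dir, overwrite = TRUE))
  # empty series -> header-only file
  dir2 <- tempfile()
  f2 <- writeReport(list(), NULL, dir2)
  expect_equal(readAreaSeries(f2[["areaSeries"]]), list())
  expect_equal(length(readLines(f2[["areaSeries"]])), 1L)
})

test_that("the VAMAS subset reader parses REGULAR single-block files", {
  tmp <- tempfile(fileext = ".vms")
  counts <- c(100, 120, 180, 260, 180, 120, 100, 95, 90, 88)
  writeVamasFixture(tmp, start = 280, incr = 0.5, counts = counts)
  s <- readSpectrum(tmp, dialect = "vamas")
  expect_equal(regionLabel(s), "C1s")
  expect_equal(bindingEnergy(s), seq(280, by = 0.5, length.out = 10))
  expect_equal(intensity(s), counts)
  expect_equal(s@excitationEnergy, 1486.6)

  # anything but the supported subset is rejected loudly
  lines <- readLines(tmp)
  lines[7] <- "MAP"
  bad <- tempfile(); writeLines(lines, bad)
  expect_error(readSpectrum(bad, dialect = "vamas"), "NORM")
  lines <- readLines(tmp)
  lines[8] <- "IRREGULAR"
  bad2 <- tempfile(); writeLines(lines, bad2)
  expect_error(readSpectrum(bad2, dialect = "vamas"), "REGULAR")
  notv <- tempfile(); writeLines("not a vamas file", notv)
  expect_error(readSpectrum(notv, dialect = "vamas"), "identifier")
})
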