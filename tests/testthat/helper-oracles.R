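# Independent oracle implementations and shared fixture builders.
# These are deliberately coded differently from the package internals.

# Independently coded Shirley fixed point: midpoint-rule integration
# (the package uses trapezoids), explicit loop, run on any grid.
oracleShirley <- function(x, y, nEdge = 5L, tol = 1e-12, maxIter = 1000L) {
  n <- length(y)
  iLo <- mean(y[1:nEdge])
  iHi <- mean(y[(n - nEdge + 1):n])
  b <- rep(iLo, n)
  h <- diff(x)
  for (it in seq_len(maxIter)) {
    s <- pmax(y - b, 0)
    mid <- (s[-1] + s[-n]) / 2
    below <- c(0, cumsum(mid * h))
    tot <- below[n]
    bNew <- if (tot > 0) iLo + (iHi - iLo) * below / tot else b
    if (max(abs(bNew - b)) <= tol * max(abs(bNew), 1)) { b <- bNew; break }
    b <- bNew
  }
  b
}

# Shirley step fixture: a single Gaussian on a step between two levels,
# with the step following the Gaussian's cumulative (so it is a Shirley
# fixed point up to the edge tails).
shirleyStepFixture <- function(step = 0.05, lo = 50, hi = 10,
                               center = 286, fwhm = 1.2, area = 1000) {
  x <- seq(280, 292, by = step)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  g <- area * exp(-(x - center)^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
  cumfrac <- pnorm(x, center, sigma)
  bg <- lo + (hi - lo) * cumfrac
  list(x = x, y = g + bg, peaks = g, bg = bg)
}

# Independent log-log interpolator over the shipped cross-section table.
oracleMassAttenuation <- function(stoich, energy,
                                  tab = loadCrossSections()) {
  am <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974)
  w <- stoich * am[names(stoich)]
  w <- w / sum(w)
  out <- 0
  for (el in names(stoich)) {
    sub <- tab[tab$element == el, ]
    sub <- sub[order(sub$energy_eV), ]
    # piecewise-linear in log-log via approx (the oracle path)
    v <- exp(approx(log(sub$energy_eV), log(sub$mu_rho_cm2g),
                    xout = log(energy))$y)
    out <- out + w[[el]] * v
  }
  unname(out)
}

# Minimal FitResult for metric tests (areas and sigmas set directly).
makeFit <- function(region, timepoint, labels, areas, sigmas = NULL,
                    gas = NULL) {
  nl <- length(labels)
  if (is.null(sigmas)) sigmas <- rep(0, nl)
  if (is.null(gas)) gas <- rep(FALSE, nl)
  comps <- mapply(function(l, a, g)
    peakComponent(l, 285, area = a, isGasPhase = g,
                  group = if (g && region == "O1s") "Water" else ""),
    labels, areas, gas, SIMPLIFY = FALSE)
  new("FitResult",
      model = regionModel(region, unname(comps)),
      spectrumInfo = list(region = region, timepoint = timepoint,
                          atmosphere = "vacuum"),
      bindingEnergy = c(0, 1), counts = c(0, 0),
      backgroundCurve = c(0, 0), residuals = c(0, 0),
      componentAreas = data.frame(label = labels, area = areas,
                                  sigma = sigmas, isGasPhase = gas,
                                  stringsAsFactors = FALSE),
      covariance = matrix(0, 0, 0), parNames = character(0),
      areaJacobian = matrix(0, nl, 0, dimnames = list(labels, NULL)),
      reducedChiSquare = 0, converged = TRUE, nIterations = 0,
      messages = character(), weights = c(1, 1), options = list())
}

# A small single-region C1s scenario (two timepoints) shared across tests.
smallC1sScenario <- function(timepoints = c(0, 7200), snr = 100) {
  models <- dnaRegionModels()
  damageScenario("c1s-test", models["C1s"],
    initialAreas = c(C1s_285 = 2.0, C1s_286 = 3.3, C1s_288 = 1.7,
                     C1s_289 = 1.2),
    rates = c(C1s_286 = 2.0e-5),
    timepoints = timepoints, atmosphere = "N2", snr = snr)
}

# Write a minimal single-block NORM/REGULAR VAMAS file.
writeVamasFixture <- function(path, species = "C", transition = "1s",
                              start = 280, incr = 0.5, counts = NULL) {
  if (is.null(counts)) counts <- round(100 + 50 * sin(seq(0, 3, length.out = 25)))
  lines <- c(
    "VAMAS Surface Chemical Analysis Standard Data Transfer Format 1988 May 4",
    "test institution", "test instrument", "test operator", "test experiment",
    "0",            # experiment comment lines
    "NORM", "REGULAR",
    "1",            # number of spectral regions
    "0",            # experimental variables
    "0", "0",       # inclusion list, manual entries
    "0", "0",       # future upgrade entries
    "1",            # number of blocks
    "block-1", "sample-1",
    "2021", "4", "9", "12", "0", "0", "1",
    "0",            # block comment lines
    "XPS",
    "Al K alpha", "1486.6", "300",
    "1", "1",       # source beam widths
    "54", "0",      # source polar / azimuth
    "FAT", "20",
    "1",            # transfer-lens magnification
    "4.5",          # work function
    "0",            # target bias
    "1", "1", "0", "0",   # analysis widths + take-off angles
    species, transition,
    "-1",
    "binding energy", "eV",
    sprintf("%.6g", start), sprintf("%.6g", incr),
    "1",            # corresponding variables
    "counts", "d",
    "pulse counting", "0.1", "1", "0",
    "0", "0", "0",  # sample tilt/rotation
    "0",            # additional numerical parameters
    sprintf("%d", length(counts)),
    sprintf("%.6g", min(counts)), sprintf("%.6g", max(counts)),
    sprintf("%.6g", counts))
  writeLines(lines, path)
  invisible(path)
}
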