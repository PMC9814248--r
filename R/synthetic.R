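# Synthetic spectrum series with known ground truth.
#
# Component areas follow first-order damage kinetics A(t) = A0 exp(-k t);
# each region's noiseless curve is the Voigt component sum on a
# Shirley-consistent step background whose high-BE offset is proportional
# to the current total peak area (so damage lowers the background too);
# counts are Poisson with one global scale chosen so the largest generated
# peak reaches the target peak signal-to-noise ratio.

#' Construct a damage scenario
#'
#' @param name scenario name.
#' @param regionModels named list of \linkS4class{RegionModel}.
#' @param initialAreas named numeric: initial area per component label, in
#'   P2p-normalized units (total P2p = 1).
#' @param rates named numeric: first-order rate constants (1/s); labels not
#'   listed decay with rate 0.  Negative rates grow.
#' @param timepoints seconds, strictly increasing.
#' @param atmosphere condition label.
#' @param snr target peak signal-to-noise ratio.
#' @param gridStep acquisition step, eV.
#' @param windows named list region -> c(low, high) eV; defaults to
#'   \code{\link{defaultWindows}} entries.
#' @param backgroundBase,backgroundStep background shape coefficients, see
#'   \linkS4class{DamageScenario}.
#' @param condition extra condition metadata.
#' @return a \linkS4class{DamageScenario}.
#' @export
damageScenario <- function(name, regionModels, initialAreas, rates,
                           timepoints = seq(0, 7200, by = 800),
                           atmosphere = "vacuum", snr = 100,
                           gridStep = 0.05, windows = defaultWindows(),
                           backgroundBase = 0.5, backgroundStep = 0.4,
                           condition = list()) {
  new("DamageScenario", name = name, atmosphere = atmosphere,
      regionModels = regionModels, initialAreas = initialAreas,
      rates = rates, timepoints = as.numeric(timepoints), gridStep = gridStep,
      windows = windows, snr = snr, backgroundBase = backgroundBase,
      backgroundStep = backgroundStep, condition = condition)
}

#' Generate a spectrum series from a scenario
#'
#' @param sc a \linkS4class{DamageScenario}.
#' @param seed RNG seed; identical scenario + seed gives a bitwise
#'   identical series.
#' @param noise draw Poisson counts (default TRUE); FALSE returns the
#'   noiseless curves (the SNR target still sets the count scale).
#' @return list with elements \code{series} (\linkS4class{SpectrumSeries})
#'   and \code{truth} (\linkS4class{TruthRecord}).
#' @export
generateSeries <- function(sc, seed = 1, noise = TRUE) {
  stopifnot(is(sc, "DamageScenario"))
  regions <- names(sc@regionModels)
  curves <- list(); truthRows <- list()
  for (r in regions) {
    m <- sc@regionModels[[r]]
    win <- sc@windows[[r]]
    if (is.null(win)) stop("no window for region ", r)
    x <- seq(win[1], win[2], by = sc@gridStep)
    W <- diff(range(x))
    labs <- componentLabels(m)
    a0 <- sc@initialAreas[labs]
    if (anyNA(a0)) stop("missing initial areas for: ",
                        paste(labs[is.na(a0)], collapse = ", "))
    k <- ifelse(labs %in% names(sc@rates), sc@rates[labs], 0)
    atot0 <- sum(a0)
    for (tp in sc@timepoints) {
      at <- a0 * exp(-k * tp)
      peaks <- numeric(length(x))
      for (i in seq_along(labs)) {
        p <- m@components[[i]]
        peaks <- peaks + voigtProfile(x, p@center, at[i], p@gaussianFwhm,
                                      p@lorentzianFwhm)
        truthRows[[length(truthRows) + 1L]] <- data.frame(
          region = r, component = labs[i], timepoint = tp,
          area = unname(at[i]), center = p@center,
          gaussianFwhm = p@gaussianFwhm, lorentzianFwhm = p@lorentzianFwhm,
          rate = unname(k[i]), stringsAsFactors = FALSE)
      }
      n <- length(x)
      cumA <- c(0, cumsum(diff(x) * (peaks[-1] + peaks[-n]) / 2))
      atotT <- sum(at)
      cumFrac <- if (cumA[n] > 0) cumA / cumA[n] else (x - x[1]) / W
      bg <- sc@backgroundBase * atot0 / W +
        sc@backgroundStep * atotT / W * cumFrac
      curves[[length(curves) + 1L]] <- list(region = r, timepoint = tp,
                                            x = x, y = peaks + bg)
    }
  }
  peakMax <- max(vapply(curves, function(cv) max(cv$y), numeric(1)))
  if (!is.finite(peakMax) || peakMax <= 0)
    stop(sprintf(
      "SNR target unreachable: peak of the noiseless curve is %g", peakMax))
  scale <- sc@snr^2 / peakMax
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  spectra <- lapply(curves, function(cv) {
    lam <- scale * cv$y
    yy <- if (noise) stats::rpois(length(lam), lam) else lam
    Spectrum(cv$region, cv$x, yy, timepoint = cv$timepoint,
             atmosphere = sc@atmosphere,
             meta = list(scenario = sc@name))
  })
  series <- SpectrumSeries(spectra, condition = c(sc@condition,
                                                  list(scenario = sc@name)))
  truth <- new("TruthRecord", scenario = sc@name, seed = as.numeric(seed),
               scale = scale, areas = do.call(rbind, truthRows))
  list(series = series, truth = truth)
}

#' Preset scenarios encoding the three irradiation atmospheres
#'
#' Synthetic encodings of the qualitative experimental findings, not
#' fitted values: backbone (C1s 286 eV) damage under H2O runs at exactly
#' twice the N2 rate, total-nitrogen loss at exactly three times the N2
#' rate, and vacuum rates sit slightly below N2.  Rate magnitudes are
#' chosen so that k * t_end is small (endpoint indices then track the rate
#' ratios).  The vacuum scenario carries an adsorbed-water O1s component
#' equivalent to 0.25 water molecules per nucleotide (via the default
#' sensitivity factors); N2 adds the gas-phase N1s line; H2O a strong
#' water line.
#'
#' @param snr target peak signal-to-noise ratio (default 100).
#' @param timepoints seconds (default: 10 points over 2 h).
#' @return named list of \linkS4class{DamageScenario}:
#'   vacuum, N2, H2O.
#' @export
presetScenarios <- function(snr = 100, timepoints = seq(0, 7200, by = 800)) {
  models <- dnaRegionModels()
  rsf <- defaultRsf()
  waterEq <- function(nPerNt) nPerNt * rsf[["O1s"]] / rsf[["P2p"]]  # P2p = 1
  baseAreas <- c(
    C1s_285 = 2.0, C1s_286 = 3.3, C1s_288 = 1.7, C1s_289 = 1.2,
    N1s_399 = 3.1, N1s_401 = 2.55,
    O1s_531 = 7.4, O1s_532 = 9.8,
    P2p_32 = 2 / 3, P2p_12 = 1 / 3)
  n1sNoGas <- models$N1s
  n1sNoGas@components <- Filter(function(p) !p@isGasPhase,
                                n1sNoGas@components)
  mk <- function(name, atmosphere, mods, areas, rates, pressure) {
    damageScenario(name, mods, areas, rates, timepoints = timepoints,
                   atmosphere = atmosphere, snr = snr,
                   condition = list(pressure_mbar = pressure,
                                    gas = atmosphere))
  }
  kN2 <- c(C1s_285 = -2e-6, C1s_286 = 2.0e-5, C1s_288 = 3e-6,
           C1s_289 = 3e-6, N1s_399 = 1.0e-5, N1s_401 = 1.0e-5,
           O1s_531 = 5e-6, O1s_532 = 1.8e-5)
  kVac <- c(C1s_285 = -2e-6, C1s_286 = 1.6e-5, C1s_288 = 2e-6,
            C1s_289 = 2e-6, N1s_399 = 4e-6, N1s_401 = 4e-6,
            O1s_531 = 3e-6, O1s_532 = 1.4e-5)
  kH2O <- c(C1s_285 = 0, C1s_286 = 4.0e-5, C1s_288 = 1.5e-5,
            C1s_289 = 8e-6, N1s_399 = 3.0e-5, N1s_401 = 3.0e-5,
            O1s_531 = 1.2e-5, O1s_532 = 3.6e-5)
  list(
    vacuum = mk("vacuum", "vacuum",
      list(C1s = models$C1s, N1s = n1sNoGas, O1s = models$O1s,
           P2p = models$P2p),
      c(baseAreas, O1s_535 = unname(waterEq(0.25))), kVac, 1e-8),
    N2 = mk("N2", "N2",
      models,
      c(baseAreas, N1s_405 = 0.8, O1s_535 = unname(waterEq(0.3))),
      kN2, 10),
    H2O = mk("H2O", "H2O",
      list(C1s = models$C1s, N1s = n1sNoGas, O1s = models$O1s,
           P2p = models$P2p),
      c(baseAreas, O1s_535 = unname(waterEq(1.0))), kH2O, 10)
  )
}
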