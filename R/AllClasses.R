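#' @import methods
NULL

ATMOSPHERES <- c("vacuum", "N2", "H2O")

#' Spectrum: a single core-level region scan
#'
#' One binding-energy scan of a named core-level region (C1s, O1s, N1s, P2p,
#' or user-defined), together with the acquisition metadata the downstream
#' analysis needs.  The binding-energy grid is always stored ascending;
#' constructors normalize input order.  Kinetic energy is never stored; it is
#' \code{excitationEnergy - bindingEnergy} on demand.
#'
#' @slot region region label, e.g. \code{"C1s"}.
#' @slot bindingEnergy strictly increasing grid of binding energies (eV).
#' @slot counts nonnegative, finite intensities, one per grid point.
#' @slot timepoint seconds since the start of irradiation.
#' @slot atmosphere one of \code{"vacuum"}, \code{"N2"}, \code{"H2O"}.
#' @slot excitationEnergy photon energy in eV (Al K-alpha, 1486.6, by default).
#' @slot meta free-form acquisition metadata.
#'
#' @export
setClass("Spectrum",
  representation(
    region           = "character",
    bindingEnergy    = "numeric",
    counts           = "numeric",
    timepoint        = "numeric",
    atmosphere       = "character",
    excitationEnergy = "numeric",
    meta             = "list"
  ),
  prototype(
    timepoint = 0, atmosphere = "vacuum", excitationEnergy = 1486.6,
    meta = list()
  )
)

setValidity("Spectrum", function(object) {
  be <- object@bindingEnergy
  y  <- object@counts
  msgs <- character()
  if (length(object@region) != 1L || !nzchar(object@region))
    msgs <- c(msgs, "region must be a single nonempty string")
  if (length(be) < 2L)
    msgs <- c(msgs, "binding-energy grid needs at least 2 points")
  if (anyNA(be) || any(!is.finite(be)))
    msgs <- c(msgs, "binding energies must be finite")
  d <- diff(be)
  if (length(d) && any(d <= 0))
    msgs <- c(msgs, "binding energy must be strictly increasing")
  if (length(y) != length(be))
    msgs <- c(msgs, "counts length must equal grid length")
  if (anyNA(y) || any(!is.finite(y)))
    msgs <- c(msgs, "counts must be finite")
  else if (any(y < 0)) {
    bad <- which(y < 0)[1L]
    msgs <- c(msgs, sprintf("negative counts at row %d (BE = %g eV)",
                            bad, be[bad]))
  }
  if (length(d) > 1L && all(d > 0)) {
    dev <- max(abs(d - median(d))) / median(d)
    if (dev > 0.25)
      msgs <- c(msgs, sprintf(
        "grid spacing deviates %.0f%% from uniform (hard limit 25%%)",
        100 * dev))
  }
  if (!(object@atmosphere %in% ATMOSPHERES))
    msgs <- c(msgs, "atmosphere must be one of vacuum, N2, H2O")
  if (length(msgs)) msgs else TRUE
})

#' Construct a Spectrum
#'
#' Input rows may be in any order; they are sorted to an ascending
#' binding-energy grid.  Grids more than 10 % away from uniform spacing
#' trigger a warning (the Shirley background assumes near-uniform sampling);
#' more than 25 % is an error.
#'
#' @param region region label.
#' @param bindingEnergy binding energies in eV.
#' @param counts intensities, same length.
#' @param timepoint seconds since irradiation start.
#' @param atmosphere \code{"vacuum"}, \code{"N2"} or \code{"H2O"}.
#' @param excitationEnergy photon energy in eV.
#' @param meta list of extra acquisition metadata.
#' @return A validated \linkS4class{Spectrum}.
#' @examples
#' s <- Spectrum("C1s", c(287, 285, 286), c(10, 10, 20))
#' bindingEnergy(s)   # ascending
#' @export
Spectrum <- function(region, bindingEnergy, counts, timepoint = 0,
                     atmosphere = "vacuum", excitationEnergy = 1486.6,
                     meta = list()) {
  o <- order(bindingEnergy)
  be <- as.numeric(bindingEnergy[o])
  y  <- as.numeric(counts[o])
  obj <- new("Spectrum", region = region, bindingEnergy = be, counts = y,
             timepoint = as.numeric(timepoint), atmosphere = atmosphere,
             excitationEnergy = excitationEnergy, meta = meta)
  d <- diff(be)
  if (length(d) > 1L) {
    dev <- max(abs(d - median(d))) / median(d)
    if (dev > 0.10 && dev <= 0.25)
      warning(sprintf("grid spacing deviates %.0f%% from uniform", 100 * dev))
  }
  obj
}

#' SpectrumSeries: spectra grouped by region, ordered in time
#'
#' @slot spectra list of \linkS4class{Spectrum}.
#' @slot condition condition metadata (pressure in mbar, gas identity, ...).
#' @export
setClass("SpectrumSeries",
  representation(spectra = "list", condition = "list"),
  prototype(condition = list())
)

setValidity("SpectrumSeries", function(object) {
  if (!all(vapply(object@spectra, is, logical(1), "Spectrum")))
    return("all elements of spectra must be Spectrum objects")
  reg <- vapply(object@spectra, function(s) s@region, character(1))
  tp  <- vapply(object@spectra, function(s) s@timepoint, numeric(1))
  for (r in unique(reg)) {
    t_r <- tp[reg == r]
    if (any(diff(t_r) <= 0))
      return(sprintf("timepoints not strictly increasing within region %s", r))
  }
  TRUE
})

#' @rdname SpectrumSeries-class
#' @param spectra list of \linkS4class{Spectrum}, any order.
#' @param condition condition metadata list.
#' @return A \linkS4class{SpectrumSeries} sorted by region then timepoint.
#' @export
SpectrumSeries <- function(spectra, condition = list()) {
  reg <- vapply(spectra, function(s) s@region, character(1))
  tp  <- vapply(spectra, function(s) s@timepoint, numeric(1))
  new("SpectrumSeries", spectra = spectra[order(reg, tp)],
      condition = condition)
}

#' PeakComponent: one Voigt component of a region model
#'
#' Encodes one row of the peak-assignment scheme: a labelled Voigt line with
#' its binding-energy position (and fit bounds), Gaussian/Lorentzian FWHM
#' (and global width bounds), its area, and whether it is a gas-phase line
#' (gas-phase lines report the atmosphere, not the DNA, and are excluded
#' from damage metrics).
#'
#' @slot label unique label within its region, e.g. \code{"C1s_286"}.
#' @slot bonds chemical bonds assigned to the line.
#' @slot group assignment group (Bases/Backbone/Sugar/Water/Nitrogen).
#' @slot center binding energy in eV.
#' @slot centerBounds length-2 numeric, allowed center range.
#' @slot gaussianFwhm,lorentzianFwhm widths (FWHM, eV).
#' @slot gaussianBounds,lorentzianBounds length-2 numeric width bounds.
#' @slot area peak area in counts*eV.
#' @slot isGasPhase logical flag.
#' @slot fixed names of parameters held fixed during fitting
#'   (subset of \code{"area"}, \code{"center"}, \code{"gaussianFwhm"},
#'   \code{"lorentzianFwhm"}).
#' @export
setClass("PeakComponent",
  representation(
    label = "character", bonds = "character", group = "character",
    center = "numeric", centerBounds = "numeric",
    gaussianFwhm = "numeric", lorentzianFwhm = "numeric",
    gaussianBounds = "numeric", lorentzianBounds = "numeric",
    area = "numeric", isGasPhase = "logical", fixed = "character"
  ),
  prototype(
    bonds = character(), group = "", gaussianFwhm = 1.3,
    lorentzianFwhm = 0.2, gaussianBounds = c(0.6, 2.5),
    lorentzianBounds = c(0, 0.6), area = 1, isGasPhase = FALSE,
    fixed = character()
  )
)

setValidity("PeakComponent", function(object) {
  msgs <- character()
  if (length(object@centerBounds) != 2L ||
      object@center < object@centerBounds[1L] ||
      object@center > object@centerBounds[2L])
    msgs <- c(msgs, sprintf("center %g outside its bounds", object@center))
  if (object@gaussianFwhm < object@gaussianBounds[1L] ||
      object@gaussianFwhm > object@gaussianBounds[2L])
    msgs <- c(msgs, "gaussianFwhm outside bounds")
  if (object@lorentzianFwhm < object@lorentzianBounds[1L] ||
      object@lorentzianFwhm > object@lorentzianBounds[2L])
    msgs <- c(msgs, "lorentzianFwhm outside bounds")
  if (object@area < 0) msgs <- c(msgs, "area must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' @rdname PeakComponent-class
#' @param label,bonds,group,center,centerBounds,gaussianFwhm,lorentzianFwhm
#'   see slots.
#' @param gaussianBounds,lorentzianBounds,area,isGasPhase,fixed see slots.
#' @export
peakComponent <- function(label, center,
                          centerBounds = center + c(-0.5, 0.5),
                          area = 1, gaussianFwhm = 1.3, lorentzianFwhm = 0.2,
                          gaussianBounds = c(0.6, 2.5),
                          lorentzianBounds = c(0, 0.6),
                          bonds = character(), group = "",
                          isGasPhase = FALSE, fixed = character()) {
  new("PeakComponent", label = label, bonds = bonds, group = group,
      center = center, centerBounds = as.numeric(centerBounds),
      gaussianFwhm = gaussianFwhm, lorentzianFwhm = lorentzianFwhm,
      gaussianBounds = as.numeric(gaussianBounds),
      lorentzianBounds = as.numeric(lorentzianBounds),
      area = area, isGasPhase = isGasPhase, fixed = fixed)
}

#' RegionModel: the deconvolution model of one core-level region
#'
#' @slot region region label.
#' @slot components list of \linkS4class{PeakComponent}.
#' @slot sharedGaussianWidth if TRUE a single Gaussian FWHM is shared by all
#'   components of the region.
#' @slot doublets list of doublet links; each is a list with elements
#'   \code{primary}, \code{secondary} (component labels), \code{ratio}
#'   (primary:secondary area ratio, > 0) and \code{splitting} (eV; the
#'   secondary center is \code{primary center + splitting}).
#' @slot background \code{"shirley"} or \code{"linear"}.
#' @export
setClass("RegionModel",
  representation(
    region = "character", components = "list",
    sharedGaussianWidth = "logical", doublets = "list",
    background = "character"
  ),
  prototype(sharedGaussianWidth = FALSE, doublets = list(),
            background = "shirley")
)

setValidity("RegionModel", function(object) {
  msgs <- character()
  if (!all(vapply(object@components, is, logical(1), "PeakComponent")))
    msgs <- c(msgs, "components must be PeakComponent objects")
  labs <- vapply(object@components, function(p) p@label, character(1))
  if (anyDuplicated(labs))
    msgs <- c(msgs, "component labels must be unique within a region")
  for (d in object@doublets) {
    if (!all(c("primary", "secondary", "ratio", "splitting") %in% names(d)))
      msgs <- c(msgs, "doublet link needs primary, secondary, ratio, splitting")
    else {
      if (!all(c(d$primary, d$secondary) %in% labs))
        msgs <- c(msgs, "doublet link references unknown component labels")
      if (d$primary == d$secondary)
        msgs <- c(msgs, "doublet link must reference exactly two components")
      if (!is.numeric(d$ratio) || d$ratio <= 0)
        msgs <- c(msgs, "doublet area ratio must be > 0")
    }
  }
  if (!(object@background %in% c("shirley", "linear")))
    msgs <- c(msgs, "background must be 'shirley' or 'linear'")
  if (length(msgs)) msgs else TRUE
})

#' @rdname RegionModel-class
#' @param region,components,sharedGaussianWidth,doublets,background see slots.
#' @export
regionModel <- function(region, components, sharedGaussianWidth = FALSE,
                        doublets = list(), background = "shirley") {
  new("RegionModel", region = region, components = components,
      sharedGaussianWidth = sharedGaussianWidth, doublets = doublets,
      background = background)
}

#' FitResult: a fitted region deconvolution
#'
#' Holds the fitted model, the (frozen) background curve, residuals, the
#' covariance matrix over free parameters, and per-component areas with
#' their propagated one-sigma uncertainties.  The stored arrays satisfy
#' \code{componentSum + backgroundCurve + residuals == counts} exactly.
#'
#' @slot model fitted \linkS4class{RegionModel}.
#' @slot spectrumInfo list: region, timepoint, atmosphere of the input.
#' @slot bindingEnergy,counts the fitted window.
#' @slot backgroundCurve background intensity per grid point.
#' @slot residuals counts - background - component sum.
#' @slot componentAreas data.frame: label, area, sigma, isGasPhase.
#' @slot covariance covariance matrix over free parameters.
#' @slot parNames free-parameter names (covariance dimnames).
#' @slot areaJacobian d(component area)/d(free parameters).
#' @slot reducedChiSquare weighted residual sum of squares / dof.
#' @slot converged logical convergence flag.
#' @slot nIterations optimizer iterations.
#' @slot messages warnings recorded during the fit (bounds hit, ...).
#' @slot weights per-point weights used (1/variance).
#' @slot options fit options needed to reproduce the covariance
#'   (weighting, shape, background-offset flag).
#' @export
setClass("FitResult",
  representation(
    model = "RegionModel", spectrumInfo = "list",
    bindingEnergy = "numeric", counts = "numeric",
    backgroundCurve = "numeric", residuals = "numeric",
    componentAreas = "data.frame", covariance = "matrix",
    parNames = "character", areaJacobian = "matrix",
    reducedChiSquare = "numeric", converged = "logical",
    nIterations = "numeric", messages = "character", weights = "numeric",
    options = "list"
  )
)

setValidity("FitResult", function(object) {
  msgs <- character()
  n <- length(object@bindingEnergy)
  if (length(object@backgroundCurve) != n || length(object@residuals) != n ||
      length(object@counts) != n)
    msgs <- c(msgs, "curve lengths must match the grid")
  cv <- object@covariance
  if (length(cv) && nrow(cv) > 0) {
    if (!isSymmetric(unname(cv), tol = 1e-8))
      msgs <- c(msgs, "covariance must be symmetric")
    else if (min(eigen(cv, symmetric = TRUE,
                       only.values = TRUE)$values) < -1e-8 * max(abs(cv), 1))
      msgs <- c(msgs, "covariance must be positive semi-definite")
  }
  if (length(msgs)) msgs else TRUE
})

#' AreaSeries: time-resolved normalized areas of one region
#'
#' Per component and timepoint: the P2p-normalized area (component area
#' divided by the total P2p area at the same timepoint) and the percent of
#' the region's initial total (normalized area as a percentage of the
#' region's non-gas total at the first timepoint), both with propagated
#' one-sigma uncertainties.
#'
#' @slot region region label.
#' @slot data data.frame with columns timepoint, component, isGasPhase,
#'   normalizedArea, normalizedSigma, percentOfInitial, percentSigma.
#' @export
setClass("AreaSeries",
  representation(region = "character", data = "data.frame"))

setValidity("AreaSeries", function(object) {
  need <- c("timepoint", "component", "isGasPhase", "normalizedArea",
            "normalizedSigma", "percentOfInitial", "percentSigma")
  if (!all(need %in% names(object@data)))
    return(paste("data must have columns:", paste(need, collapse = ", ")))
  if (any(object@data$normalizedSigma < 0, na.rm = TRUE) ||
      any(object@data$percentSigma < 0, na.rm = TRUE))
    return("sigmas must be nonnegative")
  d <- object@data[!object@data$isGasPhase, ]
  if (nrow(d)) {
    t0 <- min(d$timepoint)
    s0 <- sum(d$percentOfInitial[d$timepoint == t0])
    if (abs(s0 - 100) > 1e-9)
      return(sprintf("non-gas percent_of_initial at t0 sums to %.12g, not 100",
                     s0))
  }
  TRUE
})

#' DamageReport: scalar damage and hydration indices for one condition
#'
#' @slot condition condition metadata.
#' @slot strandBreak c(value, sigma): fractional start-to-end decrease of the
#'   P2p-normalized C1s 286 eV (C-O/C-N) component.
#' @slot baseDamage c(value, sigma): fractional decrease of the summed
#'   non-gas N1s signal.
#' @slot waterPerNucleotide c(value, sigma), NA if not computed.
#' @slot endStartRatios data.frame: region, component, ratio end/start, sigma.
#' @export
setClass("DamageReport",
  representation(
    condition = "list", strandBreak = "numeric", baseDamage = "numeric",
    waterPerNucleotide = "numeric", endStartRatios = "data.frame"
  ),
  prototype(waterPerNucleotide = c(value = NA_real_, sigma = NA_real_))
)

#' Material: an elemental mixture with a phase and a density
#'
#' For gases the density is derived from pressure and temperature by the
#' ideal-gas law; for condensed materials it is given directly.
#'
#' @slot name material name.
#' @slot stoichiometry named numeric: atoms per formula unit by element.
#' @slot density g/cm^3 (derived for gases).
#' @slot phase \code{"gas"} or \code{"condensed"}.
#' @slot pressure mbar (gases only).
#' @slot temperature K (gases only).
#' @export
setClass("Material",
  representation(
    name = "character", stoichiometry = "numeric", density = "numeric",
    phase = "character", pressure = "numeric", temperature = "numeric"
  ),
  prototype(pressure = NA_real_, temperature = NA_real_)
)

setValidity("Material", function(object) {
  msgs <- character()
  if (!length(object@stoichiometry) || is.null(names(object@stoichiometry)))
    msgs <- c(msgs, "stoichiometry must be a nonempty named vector")
  if (!(object@phase %in% c("gas", "condensed")))
    msgs <- c(msgs, "phase must be 'gas' or 'condensed'")
  if (!is.finite(object@density) || object@density <= 0)
    msgs <- c(msgs, "density must be positive")
  if (length(msgs)) msgs else TRUE
})

#' SlabGeometry: ordered layers traversed by the incident beam
#'
#' Layers are listed from the source side downward; the DNA film is the last
#' (deepest) layer and the scoring region is its top \code{scoringDepth}
#' nanometres, the depth XPS effectively probes.
#'
#' @slot layers list of lists with elements \code{material}
#'   (\linkS4class{Material}) and \code{thickness} (nm).
#' @slot scoringDepth nm, measured from the film's top surface.
#' @export
setClass("SlabGeometry",
  representation(layers = "list", scoringDepth = "numeric"),
  prototype(scoringDepth = 10))

setValidity("SlabGeometry", function(object) {
  msgs <- character()
  if (!length(object@layers)) msgs <- c(msgs, "at least one layer required")
  for (ly in object@layers) {
    if (!is(ly$material, "Material") || !is.numeric(ly$thickness) ||
        ly$thickness <= 0)
      msgs <- c(msgs, "each layer needs a Material and a positive thickness")
  }
  if (!length(msgs)) {
    phases <- vapply(object@layers, function(ly) ly$material@phase,
                     character(1))
    if (any(phases == "condensed")) {
      film <- object@layers[[length(object@layers)]]
      if (film$material@phase != "condensed")
        msgs <- c(msgs, "the last (film) layer must be condensed")
      else if (object@scoringDepth < 0 ||
               object@scoringDepth > film$thickness)
        msgs <- c(msgs, "scoringDepth must lie within the film layer")
    }
    # all-gas geometries are allowed: no film, all film tallies are zero
  }
  if (length(msgs)) msgs else TRUE
})

#' TransportResult: tallies of a photon-transport run
#'
#' @slot nHistories number of photon histories.
#' @slot energy photon energy (eV).
#' @slot meanDeposit mean energy (eV) deposited per incident photon in the
#'   scoring region, with standard error \code{meanDepositSE}.
#' @slot ionizationFraction fraction of incident photons photoionizing a
#'   film atom within the scoring depth, with SE.
#' @slot thermalizedElectrons electrons per photon thermalizing (falling
#'   below the energy cut) inside the scoring region, with SE.
#' @slot layerDeposits named numeric: mean deposit (eV/photon) by region.
#' @slot seed RNG seed used.
#' @slot meanDepositSE,ionizationFractionSE,thermalizedElectronsSE standard
#'   errors of the corresponding tallies.
#' @export
setClass("TransportResult",
  representation(
    nHistories = "numeric", energy = "numeric",
    meanDeposit = "numeric", meanDepositSE = "numeric",
    ionizationFraction = "numeric", ionizationFractionSE = "numeric",
    thermalizedElectrons = "numeric", thermalizedElectronsSE = "numeric",
    layerDeposits = "numeric", seed = "numeric"
  )
)

setValidity("TransportResult", function(object) {
  v <- c(object@meanDeposit, object@ionizationFraction,
         object@thermalizedElectrons)
  if (any(v < 0)) return("tallies must be nonnegative")
  TRUE
})

#' DamageScenario: ground-truth recipe for synthetic spectrum series
#'
#' Component areas evolve in time as first-order kinetics
#' \code{A(t) = A0 exp(-k t)} (negative rates grow); counts are Poisson with
#' a global scale chosen so the largest generated peak reaches the target
#' peak signal-to-noise ratio.
#'
#' @slot name scenario name.
#' @slot atmosphere condition label.
#' @slot regionModels named list of \linkS4class{RegionModel}.
#' @slot initialAreas named numeric: initial area per component label, in
#'   P2p-normalized units.
#' @slot rates named numeric: first-order rate constant (1/s) per component
#'   label; missing labels default to 0.
#' @slot timepoints increasing vector of seconds.
#' @slot gridStep acquisition step (eV).
#' @slot windows named list region -> c(low, high) eV.
#' @slot snr target peak signal-to-noise ratio (sqrt of peak counts).
#' @slot backgroundBase low-BE background level, as a fraction of the
#'   region's initial total area divided by the window width.
#' @slot backgroundStep high-BE Shirley step coefficient: the step height is
#'   \code{backgroundStep * totalArea(t) / windowWidth}, so radiation damage
#'   lowers the background along with the peaks.
#' @slot condition condition metadata passed to the series.
#' @export
setClass("DamageScenario",
  representation(
    name = "character", atmosphere = "character", regionModels = "list",
    initialAreas = "numeric", rates = "numeric", timepoints = "numeric",
    gridStep = "numeric", windows = "list", snr = "numeric",
    backgroundBase = "numeric", backgroundStep = "numeric", condition = "list"
  ),
  prototype(gridStep = 0.05, snr = 100, backgroundBase = 0.5,
            backgroundStep = 0.4, condition = list())
)

setValidity("DamageScenario", function(object) {
  msgs <- character()
  if (any(object@initialAreas < 0)) msgs <- c(msgs, "initial areas must be >= 0")
  if (any(diff(object@timepoints) <= 0))
    msgs <- c(msgs, "timepoints must be strictly increasing")
  if (!is.finite(object@snr) || object@snr <= 0)
    msgs <- c(msgs, "snr must be > 0")
  if (!(object@atmosphere %in% ATMOSPHERES))
    msgs <- c(msgs, "atmosphere must be one of vacuum, N2, H2O")
  if (length(msgs)) msgs else TRUE
})

#' TruthRecord: every generating parameter of a synthetic series
#'
#' Sufficient to recompute each noiseless spectrum bit-identically.
#'
#' @slot scenario scenario name.
#' @slot seed RNG seed used for the Poisson draw.
#' @slot scale counts per normalized-area unit (the Poisson scale).
#' @slot areas data.frame: region, component, timepoint, area (noiseless,
#'   normalized units), center, gaussianFwhm, lorentzianFwhm, rate.
#' @export
setClass("TruthRecord",
  representation(scenario = "character", seed = "numeric", scale = "numeric",
                 areas = "data.frame"))
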