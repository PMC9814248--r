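# Materials, photon attenuation, and electron stopping-power tables.
#
# Elemental photoelectric cross sections and the electron collision
# stopping power are shipped as plain-text tables under inst/extdata (see
# their provenance headers); photon physics at 1.4 keV is photoelectric
# absorption only.

ATOMIC_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974)

.materialsCache <- new.env(parent = emptyenv())

#' Load the elemental photoelectric cross-section table
#'
#' @param path TSV with columns \code{element}, \code{energy_eV},
#'   \code{mu_rho_cm2g} (photoelectric mass attenuation); default: the
#'   shipped table.
#' @return data.frame (cached for the shipped table).
#' @export
loadCrossSections <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.materialsCache$xs)) return(.materialsCache$xs)
    path <- system.file("extdata", "photoelectric_xs.tsv",
                        package = "xpsdamage", mustWork = TRUE)
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             comment.char = "#", stringsAsFactors = FALSE)
    .materialsCache$xs <- tab
    return(tab)
  }
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Define a condensed material
#'
#' @param name material name.
#' @param stoichiometry named numeric: atoms per formula unit, e.g.
#'   \code{c(H = 2, O = 1)}.
#' @param density g/cm^3.
#' @return a \linkS4class{Material}.
#' @export
condensedMaterial <- function(name, stoichiometry, density) {
  new("Material", name = name, stoichiometry = stoichiometry,
      density = density, phase = "condensed")
}

#' Define a gas: density from the ideal-gas law
#'
#' @param name gas name.
#' @param stoichiometry named numeric atoms per molecule.
#' @param pressure mbar.
#' @param temperature K (default 300).
#' @return a \linkS4class{Material}.
#' @export
gasMaterial <- function(name, stoichiometry, pressure, temperature = 300) {
  M <- sum(stoichiometry * ATOMIC_MASS[names(stoichiometry)])   # g/mol
  if (anyNA(M)) stop("configuration error: unknown element in stoichiometry")
  # p [Pa] * M [g/mol] / (R T) -> g/m^3 -> g/cm^3
  rho <- (pressure * 100) * M / (8.31446 * temperature) / 1e6
  new("Material", name = name, stoichiometry = stoichiometry, density = rho,
      phase = "gas", pressure = pressure, temperature = temperature)
}

#' The default DNA film material
#'
#' Average nucleotide stoichiometry: the equal-weight mean of the four
#' deoxyribonucleotide-monophosphate residues (C9.75 H12.25 N3.75 O7.25 P),
#' at 1.35 g/cm^3.  These are configuration defaults of this package, not
#' measured film properties.
#'
#' @param density g/cm^3.
#' @return a \linkS4class{Material}.
#' @export
dnaFilm <- function(density = 1.35) {
  condensedMaterial("DNA",
    c(C = 9.75, H = 12.25, N = 3.75, O = 7.25, P = 1), density)
}

#' Mass attenuation coefficient of a material (mixture rule)
#'
#' Mass-weighted sum of elemental photoelectric mass-attenuation values,
#' log-log interpolated in energy between table rows.
#'
#' @param m a \linkS4class{Material}.
#' @param energy photon energy in eV (within the table range).
#' @param table optional cross-section table (see
#'   \code{\link{loadCrossSections}}).
#' @return mass attenuation coefficient, cm^2/g.
#' @export
massAttenuation <- function(m, energy, table = NULL) {
  tab <- if (is.null(table)) loadCrossSections() else table
  st <- m@stoichiometry
  masses <- ATOMIC_MASS[names(st)]
  if (anyNA(masses))
    stop("configuration error: no atomic mass for element(s) ",
         paste(names(st)[is.na(masses)], collapse = ", "))
  wfrac <- st * masses / sum(st * masses)
  mu <- 0
  for (el in names(st)) {
    sub <- tab[tab$element == el, ]
    if (!nrow(sub))
      stop("configuration error: element ", el,
           " missing from the cross-section table")
    if (energy < min(sub$energy_eV) || energy > max(sub$energy_eV))
      stop(sprintf("range error: %g eV outside table range [%g, %g] for %s",
                   energy, min(sub$energy_eV), max(sub$energy_eV), el))
    mu <- mu + wfrac[[el]] * .loglogInterp(sub$energy_eV, sub$mu_rho_cm2g,
                                           energy)
  }
  unname(mu)
}

#' Linear attenuation coefficient of a material
#'
#' \code{massAttenuation} times the material density.
#'
#' @inheritParams massAttenuation
#' @return linear attenuation coefficient, 1/cm.
#' @export
attenuationCoefficient <- function(m, energy, table = NULL) {
  massAttenuation(m, energy, table) * m@density
}

.loglogInterp <- function(ex, y, e) {
  # exact at the table knots; power-law between them
  i <- findInterval(e, ex, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(ex) - 1L)
  hit <- match(e, ex)
  if (!is.na(hit)) return(y[hit])
  b <- log(y[i + 1] / y[i]) / log(ex[i + 1] / ex[i])
  y[i] * (e / ex[i])^b
}

#' Construct a layered slab geometry
#'
#' @param layers list of \code{list(material = , thickness = )} with
#'   thickness in nm, ordered from the source side; the last layer is the
#'   film that contains the scoring region.
#' @param scoringDepth nm from the film's top surface (default 10, the
#'   depth XPS effectively probes).
#' @return a \linkS4class{SlabGeometry}.
#' @export
slabGeometry <- function(layers, scoringDepth = 10) {
  new("SlabGeometry", layers = layers, scoringDepth = scoringDepth)
}

#' Default irradiation geometries for the three atmospheres
#'
#' Vacuum: the bare 200 nm DNA film.  N2: a 1 mm column of N2 at
#' \code{pressure} mbar above the film.  H2O: a 1 mm column of water vapour
#' plus a 0.3 nm adsorbed-water layer on the film.  Gas path length and
#' layer thicknesses are configuration defaults of this package (order of
#' the aperture-sample distance in near-ambient-pressure instruments), not
#' measured values.
#'
#' @param condition \code{"vacuum"}, \code{"N2"} or \code{"H2O"}.
#' @param pressure gas pressure in mbar (default 10).
#' @param gasPath gas column length in nm (default 1e6 = 1 mm).
#' @param filmThickness DNA film thickness in nm (default 200).
#' @param scoringDepth nm (default 10).
#' @param temperature gas temperature in K.
#' @return a \linkS4class{SlabGeometry}.
#' @export
defaultGeometry <- function(condition = c("vacuum", "N2", "H2O"),
                            pressure = 10, gasPath = 1e6,
                            filmThickness = 200, scoringDepth = 10,
                            temperature = 300) {
  condition <- match.arg(condition)
  film <- list(material = dnaFilm(), thickness = filmThickness)
  layers <- switch(condition,
    vacuum = list(film),
    N2 = list(
      list(material = gasMaterial("N2", c(N = 2), pressure, temperature),
           thickness = gasPath),
      film),
    H2O = list(
      list(material = gasMaterial("H2O_vapour", c(H = 2, O = 1), pressure,
                                  temperature),
           thickness = gasPath),
      list(material = condensedMaterial("H2O_adsorbed", c(H = 2, O = 1), 1.0),
           thickness = 0.3),
      film))
  slabGeometry(layers, scoringDepth)
}

# ---- electron stopping power ----------------------------------------------

#' Load the electron collision stopping-power table
#'
#' Mass collision stopping power of a generic condensed organic medium
#' (water proxy), used for all condensed layers after density scaling.
#'
#' @param path TSV with columns \code{energy_eV}, \code{stopping_MeV_cm2_g};
#'   default: the shipped table.
#' @return data.frame.
#' @export
loadStoppingPower <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.materialsCache$sp)) return(.materialsCache$sp)
    path <- system.file("extdata", "stopping_power.tsv",
                        package = "xpsdamage", mustWork = TRUE)
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             comment.char = "#", stringsAsFactors = FALSE)
    .materialsCache$sp <- tab
    return(tab)
  }
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

# CSDA range-energy relation from the stopping table.  The range at the
# table knots is the analytic integral of 1/S through the log-log segments;
# between knots both R(E) and E(R) are log-log linear on the same knots, so
# the pair is exactly mutually inverse (energy bookkeeping telescopes).
.rangeTable <- function(sp = loadStoppingPower()) {
  key <- "rangeTab"
  if (!is.null(.materialsCache[[key]])) return(.materialsCache[[key]])
  E <- sp$energy_eV; S <- sp$stopping_MeV_cm2_g * 1e6   # eV cm^2/g
  n <- length(E)
  seg <- numeric(n - 1)
  for (i in seq_len(n - 1)) {
    b <- log(S[i + 1] / S[i]) / log(E[i + 1] / E[i])
    seg[i] <- if (abs(1 - b) > 1e-12)
      E[i] / (S[i] * (1 - b)) * ((E[i + 1] / E[i])^(1 - b) - 1)
    else E[i] / S[i] * log(E[i + 1] / E[i])
  }
  R <- c(E[1] / S[1], E[1] / S[1] + cumsum(seg))  # start from ~E/S at E_min
  out <- list(E = E, R = R)
  .materialsCache[[key]] <- out
  out
}

.rangeOfEnergy <- function(energy, rt = .rangeTable()) {
  exp(stats::approx(log(rt$E), log(rt$R), xout = log(energy),
                    rule = 2)$y)
}

.energyOfRange <- function(r, rt = .rangeTable()) {
  r <- pmax(r, rt$R[1])
  exp(stats::approx(log(rt$R), log(rt$E), xout = log(r), rule = 2)$y)
}
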