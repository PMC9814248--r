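#' Accessors for spectral objects
#'
#' @param object a package object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("bindingEnergy", function(object) standardGeneric("bindingEnergy"))

#' @rdname accessors
#' @export
setGeneric("intensity", function(object) standardGeneric("intensity"))

#' @rdname accessors
#' @export
setGeneric("regionLabel", function(object) standardGeneric("regionLabel"))

#' @rdname accessors
#' @export
setGeneric("timepoint", function(object) standardGeneric("timepoint"))

#' @rdname accessors
#' @export
setGeneric("atmosphere", function(object) standardGeneric("atmosphere"))

#' @rdname accessors
#' @export
setGeneric("kineticEnergy", function(object) standardGeneric("kineticEnergy"))

#' @rdname accessors
#' @export
setGeneric("componentAreas", function(object) standardGeneric("componentAreas"))

#' @rdname accessors
#' @export
setGeneric("backgroundCurve", function(object) standardGeneric("backgroundCurve"))

#' @rdname accessors
#' @export
setGeneric("converged", function(object) standardGeneric("converged"))

#' @rdname accessors
#' @export
setGeneric("componentLabels", function(object) standardGeneric("componentLabels"))

#' @rdname accessors
#' @export
setGeneric("seriesData", function(object) standardGeneric("seriesData"))

#' @rdname accessors
#' @export
setMethod("bindingEnergy", "Spectrum", function(object) object@bindingEnergy)

#' @rdname accessors
#' @export
setMethod("intensity", "Spectrum", function(object) object@counts)

#' @rdname accessors
#' @export
setMethod("regionLabel", "Spectrum", function(object) object@region)

#' @rdname accessors
#' @export
setMethod("timepoint", "Spectrum", function(object) object@timepoint)

#' @rdname accessors
#' @export
setMethod("atmosphere", "Spectrum", function(object) object@atmosphere)

#' @rdname accessors
#' @export
setMethod("kineticEnergy", "Spectrum",
          function(object) object@excitationEnergy - object@bindingEnergy)

#' @rdname accessors
#' @export
setMethod("regionLabel", "RegionModel", function(object) object@region)

#' @rdname accessors
#' @export
setMethod("componentLabels", "RegionModel",
          function(object) vapply(object@components, function(p) p@label,
                                  character(1)))

#' @rdname accessors
#' @export
setMethod("componentAreas", "FitResult", function(object) object@componentAreas)

#' @rdname accessors
#' @export
setMethod("backgroundCurve", "FitResult", function(object) object@backgroundCurve)

#' @rdname accessors
#' @export
setMethod("converged", "FitResult", function(object) object@converged)

#' @rdname accessors
#' @export
setMethod("residuals", "FitResult", function(object) object@residuals)

#' @rdname accessors
#' @export
setMethod("seriesData", "AreaSeries", function(object) object@data)

#' @rdname accessors
#' @export
setMethod("regionLabel", "AreaSeries", function(object) object@region)

#' Number of spectra in a series
#' @param x a SpectrumSeries.
#' @export
setMethod("length", "SpectrumSeries", function(x) length(x@spectra))

#' Extract one spectrum from a series
#' @param x a SpectrumSeries.
#' @param i index.
#' @param j,drop,... unused.
#' @export
setMethod("[[", "SpectrumSeries", function(x, i, j, ...) x@spectra[[i]])

#' @rdname accessors
#' @export
setMethod("regionLabel", "SpectrumSeries",
          function(object) unique(vapply(object@spectra,
                                         function(s) s@region, character(1))))

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum: %s | %d points, %.2f-%.2f eV | t = %g s | %s\n",
              object@region, length(object@bindingEnergy),
              min(object@bindingEnergy), max(object@bindingEnergy),
              object@timepoint, object@atmosphere))
})

setMethod("show", "SpectrumSeries", function(object) {
  reg <- vapply(object@spectra, function(s) s@region, character(1))
  cat(sprintf("SpectrumSeries: %d spectra, regions: %s\n",
              length(object@spectra),
              paste(unique(reg), collapse = ", ")))
})

setMethod("show", "RegionModel", function(object) {
  cat(sprintf("RegionModel %s: %d components (%s background)\n",
              object@region, length(object@components), object@background))
  for (p in object@components)
    cat(sprintf("  %-10s center %7.2f eV  [%s]%s\n", p@label, p@center,
                paste(p@bonds, collapse = ", "),
                if (p@isGasPhase) "  (gas phase)" else ""))
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult %s (t = %g s): %s, red. chi^2 = %.3g\n",
              object@model@region,
              if (length(object@spectrumInfo$timepoint))
                object@spectrumInfo$timepoint else NA,
              if (object@converged) "converged" else "NOT converged",
              object@reducedChiSquare))
  ca <- object@componentAreas
  for (i in seq_len(nrow(ca)))
    cat(sprintf("  %-10s area %12.4g +/- %.3g\n",
                ca$label[i], ca$area[i], ca$sigma[i]))
})

setMethod("show", "AreaSeries", function(object) {
  cat(sprintf("AreaSeries %s: %d timepoints x %d components\n",
              object@region, length(unique(object@data$timepoint)),
              length(unique(object@data$component))))
})

setMethod("show", "DamageReport", function(object) {
  cat("DamageReport\n")
  cat(sprintf("  strand-break index: %.4f +/- %.4f\n",
              object@strandBreak[1], object@strandBreak[2]))
  cat(sprintf("  base-damage index:  %.4f +/- %.4f\n",
              object@baseDamage[1], object@baseDamage[2]))
  if (is.finite(object@waterPerNucleotide[1]))
    cat(sprintf("  water/nucleotide:   %.3f +/- %.3f\n",
                object@waterPerNucleotide[1], object@waterPerNucleotide[2]))
})

setMethod("show", "Material", function(object) {
  st <- paste(sprintf("%s%g", names(object@stoichiometry),
                      object@stoichiometry), collapse = " ")
  cat(sprintf("Material %s (%s): %s, %.3g g/cm^3\n", object@name,
              object@phase, st, object@density))
})

setMethod("show", "SlabGeometry", function(object) {
  cat(sprintf("SlabGeometry: %d layers, scoring depth %.1f nm\n",
              length(object@layers), object@scoringDepth))
  for (ly in object@layers)
    cat(sprintf("  %-12s %10.3g nm (%s)\n", ly$material@name, ly$thickness,
                ly$material@phase))
})

setMethod("show", "TransportResult", function(object) {
  cat(sprintf("TransportResult: %g histories at %.1f eV\n",
              object@nHistories, object@energy))
  cat(sprintf("  mean deposit in scoring layer: %.4g +/- %.2g eV/photon\n",
              object@meanDeposit, object@meanDepositSE))
  cat(sprintf("  ionization fraction:           %.4g +/- %.2g\n",
              object@ionizationFraction, object@ionizationFractionSE))
  cat(sprintf("  thermalized electrons:         %.4g +/- %.2g per photon\n",
              object@thermalizedElectrons, object@thermalizedElectronsSE))
})

setMethod("show", "DamageScenario", function(object) {
  cat(sprintf("DamageScenario '%s' (%s): %d regions, %d timepoints, SNR %g\n",
              object@name, object@atmosphere, length(object@regionModels),
              length(object@timepoints), object@snr))
})
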