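#' Accessor generics
#'
#' Small accessor family for the package's data classes: `mz()` and
#' `intensity()` for spectra, `ccsValues()` for CCS distributions,
#' `cvAxis()`/`mobilityAxis()` for CIU fingerprints, `coords()`,
#' `elements()` and `collisionRadii()` for atomic structures, and
#' `kd()`/`kdSe()` for binding fits.
#'
#' @param object a package data object.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("mz", function(object) standardGeneric("mz"))
#' @rdname accessors
#' @export
setGeneric("intensity", function(object) standardGeneric("intensity"))
#' @rdname accessors
#' @export
setGeneric("ccsValues", function(object) standardGeneric("ccsValues"))
#' @rdname accessors
#' @export
setGeneric("cvAxis", function(object) standardGeneric("cvAxis"))
#' @rdname accessors
#' @export
setGeneric("mobilityAxis", function(object) standardGeneric("mobilityAxis"))
#' @rdname accessors
#' @export
setGeneric("coords", function(object) standardGeneric("coords"))
#' @rdname accessors
#' @export
setGeneric("elements", function(object) standardGeneric("elements"))
#' @rdname accessors
#' @export
setGeneric("collisionRadii", function(object) standardGeneric("collisionRadii"))
#' @rdname accessors
#' @export
setGeneric("kd", function(object) standardGeneric("kd"))
#' @rdname accessors
#' @export
setGeneric("kdSe", function(object) standardGeneric("kdSe"))

#' @rdname accessors
setMethod("mz", "MassSpectrum", function(object) object@mz)
#' @rdname accessors
setMethod("intensity", "MassSpectrum", function(object) object@intensity)
#' @rdname accessors
setMethod("intensity", "CCSDistribution", function(object) object@intensity)
#' @rdname accessors
setMethod("intensity", "CIUFingerprint", function(object) object@intensity)
#' @rdname accessors
setMethod("ccsValues", "CCSDistribution", function(object) object@ccs)
#' @rdname accessors
setMethod("cvAxis", "CIUFingerprint", function(object) object@cv)
#' @rdname accessors
setMethod("mobilityAxis", "CIUFingerprint", function(object) object@mobility)
#' @rdname accessors
setMethod("coords", "AtomicStructure", function(object) object@coords)
#' @rdname accessors
setMethod("elements", "AtomicStructure", function(object) object@elements)
#' @rdname accessors
setMethod("collisionRadii", "AtomicStructure", function(object) object@radii)
#' @rdname accessors
setMethod("kd", "BindingFit", function(object) object@kd)
#' @rdname accessors
setMethod("kdSe", "BindingFit", function(object) object@kdSe)

setMethod("show", "MassSpectrum", function(object) {
  cat(sprintf("MassSpectrum: %d points, m/z %.2f-%.2f\n",
              length(object@mz), min(object@mz), max(object@mz)))
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
})

setMethod("show", "Calibration", function(object) {
  cat(sprintf(
    "TW-IMS calibration: slope %.6g, intercept %.6g (r^2 = %.6g)\n",
    object@slope, object@intercept, object@rSquared))
  cat(sprintf("  EDC %.4g ms/sqrt(Da/e), gas mass %.4f Da, %d calibrants\n",
              object@edcCoefficient, object@gasMass, object@nCalibrants))
})

setMethod("show", "CCSDistribution", function(object) {
  cat(sprintf("CCSDistribution (%s+): %d points, CCS %.2f-%.2f nm^2\n",
              ifelse(is.na(object@charge), "?", object@charge),
              length(object@ccs), min(object@ccs), max(object@ccs)))
})

setMethod("show", "TitrationSeries", function(object) {
  cat(sprintf(
    "TitrationSeries: [P]0 = %.3g uM, %d points, [L]0 %.3g-%.3g uM\n",
    object@p0, length(object@l0), min(object@l0), max(object@l0)))
})

setMethod("show", "CIUFingerprint", function(object) {
  cat(sprintf(
    "CIUFingerprint: %d voltages (%.0f-%.0f V) x %d mobility bins, %s-normalized\n",
    length(object@cv), min(object@cv), max(object@cv),
    length(object@mobility), object@normalization))
})

setMethod("show", "AtomicStructure", function(object) {
  cat(sprintf("AtomicStructure%s: %d atoms, elements {%s}\n",
              if (nzchar(object@label)) paste0(" '", object@label, "'") else "",
              nrow(object@coords),
              paste(unique(object@elements), collapse = ", ")))
})

setMethod("show", "SpeciesSpec", function(object) {
  cat(sprintf("SpeciesSpec '%s': M = %.1f Da, z = %s, abundance %.3g, %d proteoform shift(s)\n",
              object@label, object@neutralMass,
              paste(range(object@chargeStates), collapse = "-"),
              object@relAbundance, nrow(object@shifts)))
})

setMethod("show", "CIUGroundTruth", function(object) {
  cat(sprintf("CIUGroundTruth: %d conformers, midpoints %s V, compaction %.2g nm^2\n",
              length(object@centroids),
              paste(object@midpoints, collapse = "/"), object@compaction))
})

setMethod("show", "TheoreticalCCS", function(object) {
  cat(sprintf("%s CCS: %.3f +/- %.3f nm^2 (%d orientations x %d samples, gas radius %.2f A)\n",
              object@method, object@value, object@se, object@nOrientations,
              object@nSamples, object@gasRadius))
  if (object@nDiscarded > 0)
    cat(sprintf("  %d trajectories discarded at reflection cap\n",
                object@nDiscarded))
})

setMethod("show", "BindingFit", function(object) {
  cat(sprintf("BindingFit: K_D = %.4g +/- %.2g nM (n = %d, residual norm %.3g%s)\n",
              object@kd, object@kdSe, object@nPoints, object@residualNorm,
              if (object@converged) "" else "; NOT CONVERGED"))
})
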