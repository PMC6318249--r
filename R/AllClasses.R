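#' @import methods
NULL

setClassUnion("CalibrationOrNULL", "NULL")

#' MassSpectrum: a centroid-free continuum mass spectrum
#'
#' Paired m/z and intensity arrays from a native electrospray acquisition
#' (or a synthetic emulation of one), plus free-form acquisition metadata.
#'
#' @slot mz numeric, m/z axis in Da/e, strictly increasing.
#' @slot intensity numeric, non-negative intensities, same length as `mz`.
#' @slot metadata list of free-form key/value pairs.
#' @exportClass MassSpectrum
setClass("MassSpectrum",
  representation(mz = "numeric", intensity = "numeric", metadata = "list"),
  prototype(metadata = list())
)

setValidity("MassSpectrum", function(object) {
  msg <- NULL
  if (length(object@mz) != length(object@intensity))
    msg <- c(msg, "mz and intensity must have equal length")
  if (length(object@mz) > 1 && any(diff(object@mz) <= 0))
    msg <- c(msg, "mz must be strictly increasing")
  if (any(!is.finite(object@intensity)))
    msg <- c(msg, "intensities must be finite")
  if (any(object@intensity < 0))
    msg <- c(msg, "intensities must be non-negative")
  if (is.null(msg)) TRUE else msg
})

#' Construct a MassSpectrum
#'
#' @param mz numeric m/z axis (Da/e), strictly increasing.
#' @param intensity numeric intensities, same length.
#' @param metadata list of acquisition metadata.
#' @return A [MassSpectrum-class] object.
#' @export
MassSpectrum <- function(mz, intensity, metadata = list()) {
  new("MassSpectrum", mz = as.numeric(mz), intensity = as.numeric(intensity),
      metadata = metadata)
}

#' Calibration: a fitted TW-IMS power-law CCS calibration
#'
#' Holds the slope and intercept of the log-log regression of reduced CCS
#' on corrected drift time, together with the enhanced-duty-cycle (EDC)
#' delay coefficient and the buffer-gas mass that entered the reduced mass.
#'
#' @slot slope numeric, power-law exponent (dimensionless).
#' @slot intercept numeric, log-space intercept (dimensionless).
#' @slot edcCoefficient numeric, ms per sqrt(Da/e); mass-dependent time the
#'   ion spends in the TOF analyser, removed before calibration.
#' @slot gasMass numeric, buffer gas mass in Da entering the reduced mass.
#' @slot rSquared numeric, coefficient of determination of the fit.
#' @slot nCalibrants integer, number of calibrant points used.
#' @exportClass Calibration
setClass("Calibration",
  representation(slope = "numeric", intercept = "numeric",
                 edcCoefficient = "numeric", gasMass = "numeric",
                 rSquared = "numeric", nCalibrants = "integer")
)

setValidity("Calibration", function(object) {
  msg <- NULL
  if (length(object@slope) != 1 || !is.finite(object@slope))
    msg <- c(msg, "slope must be a finite scalar")
  if (length(object@intercept) != 1 || !is.finite(object@intercept))
    msg <- c(msg, "intercept must be a finite scalar")
  if (object@gasMass <= 0) msg <- c(msg, "gasMass must be positive")
  if (is.null(msg)) TRUE else msg
})

setIs("Calibration", "CalibrationOrNULL")

#' Construct a Calibration directly from known coefficients
#'
#' Mostly useful for round-trip tests and for reloading a stored calibration;
#' fitted calibrations come from [fitCalibration()].
#'
#' @param slope power-law exponent.
#' @param intercept log-space intercept.
#' @param edcCoefficient EDC delay coefficient (ms per sqrt(Da/e)).
#' @param gasMass buffer gas mass (Da); defaults to helium, the reference
#'   gas of the calibrant CCS values.
#' @param rSquared coefficient of determination (NA if not fitted).
#' @param nCalibrants number of calibrant points (0 if constructed directly).
#' @return A [Calibration-class] object.
#' @export
Calibration <- function(slope, intercept, edcCoefficient = 0,
                        gasMass = 4.0026, rSquared = NA_real_,
                        nCalibrants = 0L) {
  new("Calibration", slope = as.numeric(slope),
      intercept = as.numeric(intercept),
      edcCoefficient = as.numeric(edcCoefficient),
      gasMass = as.numeric(gasMass), rSquared = as.numeric(rSquared),
      nCalibrants = as.integer(nCalibrants))
}

#' CCSDistribution: intensity versus collision cross section
#'
#' The CCS-domain image of an arrival-time distribution for one charge
#' state, carrying the calibration used to produce it.
#'
#' @slot ccs numeric, CCS axis in nm^2, strictly increasing.
#' @slot intensity numeric, non-negative, same length.
#' @slot charge integer, charge state of the selected ion.
#' @slot calibration the [Calibration-class] used, or NULL for synthetic
#'   distributions built directly in CCS space.
#' @exportClass CCSDistribution
setClass("CCSDistribution",
  representation(ccs = "numeric", intensity = "numeric", charge = "integer",
                 calibration = "CalibrationOrNULL")
)

setValidity("CCSDistribution", function(object) {
  msg <- NULL
  if (length(object@ccs) != length(object@intensity))
    msg <- c(msg, "ccs and intensity must have equal length")
  if (length(object@ccs) > 1 && any(diff(object@ccs) <= 0))
    msg <- c(msg, "ccs must be strictly increasing")
  if (any(object@intensity < 0)) msg <- c(msg, "intensities must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' Construct a CCSDistribution
#'
#' @param ccs CCS axis (nm^2), strictly increasing.
#' @param intensity intensities, same length.
#' @param charge charge state (integer).
#' @param calibration optional [Calibration-class] provenance.
#' @return A [CCSDistribution-class] object.
#' @export
CCSDistribution <- function(ccs, intensity, charge = NA_integer_,
                            calibration = NULL) {
  new("CCSDistribution", ccs = as.numeric(ccs),
      intensity = as.numeric(intensity), charge = as.integer(charge),
      calibration = calibration)
}

#' TitrationSeries: ligand titration of bound/unbound peak-area ratios
#'
#' A constant protein concentration titrated with increasing ligand, with
#' the intensity ratio I(PL)/I(P) of the ligand-bound complex over the
#' unbound protein at each point. The I(P) denominator is the unbound
#' dimer area only; monomer signal never enters the ratio.
#'
#' @slot p0 numeric, protein concentration in uM (held constant).
#' @slot l0 numeric, ligand concentrations in uM.
#' @slot ratio numeric, I(PL)/I(P) at each ligand concentration.
#' @exportClass TitrationSeries
setClass("TitrationSeries",
  representation(p0 = "numeric", l0 = "numeric", ratio = "numeric")
)

setValidity("TitrationSeries", function(object) {
  msg <- NULL
  if (length(object@p0) != 1 || object@p0 <= 0)
    msg <- c(msg, "p0 must be a positive scalar (uM)")
  if (length(object@l0) != length(object@ratio))
    msg <- c(msg, "l0 and ratio must have equal length")
  if (any(object@l0 < 0)) msg <- c(msg, "ligand concentrations must be >= 0")
  if (any(object@ratio < 0)) msg <- c(msg, "ratios must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' Construct a TitrationSeries
#'
#' @param p0 protein concentration (uM).
#' @param l0 ligand concentrations (uM).
#' @param ratio bound/unbound intensity ratios.
#' @return A [TitrationSeries-class] object.
#' @export
TitrationSeries <- function(p0, l0, ratio) {
  new("TitrationSeries", p0 = as.numeric(p0), l0 = as.numeric(l0),
      ratio = as.numeric(ratio))
}

#' CIUFingerprint: collision-induced unfolding intensity surface
#'
#' Intensity over collision voltage (rows) by mobility (columns), the
#' matrix behind a CIU contour plot. The mobility axis is CCS in nm^2
#' (or drift time in ms, used consistently).
#'
#' @slot cv numeric, collision-voltage axis in V, strictly increasing.
#' @slot mobility numeric, mobility axis, strictly increasing.
#' @slot intensity matrix, length(cv) x length(mobility), non-negative.
#' @slot normalization character, one of "none", "max", "sum" recording
#'   the per-voltage-column normalization applied.
#' @exportClass CIUFingerprint
setClass("CIUFingerprint",
  representation(cv = "numeric", mobility = "numeric", intensity = "matrix",
                 normalization = "character"),
  prototype(normalization = "none")
)

setValidity("CIUFingerprint", function(object) {
  msg <- NULL
  if (nrow(object@intensity) != length(object@cv) ||
      ncol(object@intensity) != length(object@mobility))
    msg <- c(msg, "intensity must be length(cv) x length(mobility)")
  if (length(object@cv) > 1 && any(diff(object@cv) <= 0))
    msg <- c(msg, "cv axis must be strictly increasing")
  if (length(object@mobility) > 1 && any(diff(object@mobility) <= 0))
    msg <- c(msg, "mobility axis must be strictly increasing")
  if (any(object@intensity < 0)) msg <- c(msg, "intensities must be >= 0")
  if (!object@normalization %in% c("none", "max", "sum"))
    msg <- c(msg, "normalization must be 'none', 'max' or 'sum'")
  if (is.null(msg)) TRUE else msg
})

#' Construct a CIUFingerprint
#'
#' @param cv collision-voltage axis (V), increasing.
#' @param mobility mobility axis (CCS nm^2 or drift ms), increasing.
#' @param intensity matrix, rows indexed by cv, columns by mobility.
#' @param normalization per-voltage normalization applied ("none", "max",
#'   "sum").
#' @return A [CIUFingerprint-class] object.
#' @export
CIUFingerprint <- function(cv, mobility, intensity,
                           normalization = "none") {
  new("CIUFingerprint", cv = as.numeric(cv), mobility = as.numeric(mobility),
      intensity = intensity, normalization = normalization)
}

#' AtomicStructure: coordinates with hard-sphere collision radii
#'
#' The minimal structural model the hard-sphere CCS engines need: element
#' symbols, Cartesian coordinates and a collision radius per atom.
#'
#' @slot elements character vector of element symbols.
#' @slot coords numeric N x 3 matrix of coordinates in Angstrom.
#' @slot radii numeric, collision radius in Angstrom per atom.
#' @slot label character, free-text identifier.
#' @exportClass AtomicStructure
setClass("AtomicStructure",
  representation(elements = "character", coords = "matrix",
                 radii = "numeric", label = "character"),
  prototype(label = "")
)

setValidity("AtomicStructure", function(object) {
  msg <- NULL
  n <- length(object@elements)
  if (nrow(object@coords) != n || length(object@radii) != n)
    msg <- c(msg, "elements, coords rows and radii must agree in length")
  if (ncol(object@coords) != 3) msg <- c(msg, "coords must be N x 3")
  if (any(!is.finite(object@coords))) msg <- c(msg, "coords must be finite")
  if (any(object@radii <= 0)) msg <- c(msg, "radii must be positive")
  if (is.null(msg)) TRUE else msg
})

#' Construct an AtomicStructure
#'
#' @param coords N x 3 coordinate matrix (Angstrom).
#' @param elements element symbols (recycled default "C").
#' @param radii collision radii in Angstrom; defaults to the per-element
#'   hard-sphere table (see [elementRadii()]).
#' @param label free-text identifier.
#' @return An [AtomicStructure-class] object.
#' @export
AtomicStructure <- function(coords, elements = "C", radii = NULL,
                            label = "") {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop("coords must have three columns")
  elements <- rep_len(as.character(elements), nrow(coords))
  if (is.null(radii)) radii <- elementRadii(elements)
  radii <- rep_len(as.numeric(radii), nrow(coords))
  new("AtomicStructure", elements = elements, coords = coords,
      radii = radii, label = label)
}

#' SpeciesSpec: ground-truth description of one spectral species
#'
#' Everything the spectrum generator needs for one species: its neutral
#' mass, the charge states it appears at, its relative abundance and an
#' optional proteoform ladder (mass shift, fraction) — e.g. +79.966 Da
#' phosphorylation shifts.
#'
#' @slot label character identifier.
#' @slot neutralMass numeric, Da.
#' @slot chargeStates integer vector of positive charges.
#' @slot relAbundance numeric, dimensionless >= 0.
#' @slot shifts data.frame with columns `massShift` (Da) and `fraction`
#'   (each in `[0,1]`, summing to <= 1; the remainder is the unmodified form).
#' @exportClass SpeciesSpec
setClass("SpeciesSpec",
  representation(label = "character", neutralMass = "numeric",
                 chargeStates = "integer", relAbundance = "numeric",
                 shifts = "data.frame")
)

setValidity("SpeciesSpec", function(object) {
  msg <- NULL
  if (object@neutralMass <= 0) msg <- c(msg, "neutralMass must be positive")
  if (length(object@chargeStates) == 0 || any(object@chargeStates < 1))
    msg <- c(msg, "chargeStates must be non-empty positive integers")
  if (object@relAbundance < 0) msg <- c(msg, "relAbundance must be >= 0")
  s <- object@shifts
  if (nrow(s) > 0) {
    if (!all(c("massShift", "fraction") %in% names(s)))
      msg <- c(msg, "shifts needs columns massShift and fraction")
    else if (any(s$fraction < 0) || any(s$fraction > 1) ||
             sum(s$fraction) > 1 + 1e-12)
      msg <- c(msg, "proteoform fractions must lie in [0,1] and sum to <= 1")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a SpeciesSpec
#'
#' @param label species identifier, e.g. "dimer".
#' @param neutralMass neutral mass in Da.
#' @param chargeStates positive integer charge states.
#' @param relAbundance relative abundance (any non-negative scale;
#'   normalized across species by the generator).
#' @param shifts proteoform ladder: data.frame(massShift, fraction), or a
#'   list of `c(shift, fraction)` pairs. Empty for a single proteoform.
#' @return A [SpeciesSpec-class] object.
#' @export
SpeciesSpec <- function(label, neutralMass, chargeStates, relAbundance = 1,
                        shifts = NULL) {
  if (is.null(shifts)) {
    shifts <- data.frame(massShift = numeric(0), fraction = numeric(0))
  } else if (is.list(shifts) && !is.data.frame(shifts)) {
    shifts <- data.frame(
      massShift = vapply(shifts, `[`, numeric(1), 1),
      fraction = vapply(shifts, `[`, numeric(1), 2))
  }
  new("SpeciesSpec", label = as.character(label),
      neutralMass = as.numeric(neutralMass),
      chargeStates = as.integer(chargeStates),
      relAbundance = as.numeric(relAbundance), shifts = shifts)
}

#' CIUGroundTruth: generating parameters of a synthetic unfolding profile
#'
#' Conformer CCS centroids, logistic transition midpoints and widths, and
#' an optional initial compaction applied before the first transition —
#' the ground truth a synthetic CIU fingerprint is built from.
#'
#' @slot centroids numeric, conformer CCS centroids (nm^2), strictly
#'   increasing; one more than the number of transitions.
#' @slot midpoints numeric, transition midpoints (V), strictly increasing.
#' @slot widths numeric, logistic widths (V), positive; recycled.
#' @slot compaction numeric >= 0, CCS decrease (nm^2) ramped over the
#'   pre-transition voltage range.
#' @exportClass CIUGroundTruth
setClass("CIUGroundTruth",
  representation(centroids = "numeric", midpoints = "numeric",
                 widths = "numeric", compaction = "numeric"),
  prototype(compaction = 0)
)

setValidity("CIUGroundTruth", function(object) {
  msg <- NULL
  if (length(object@centroids) != length(object@midpoints) + 1)
    msg <- c(msg, "need exactly one more centroid than midpoints")
  if (length(object@centroids) > 1 && any(diff(object@centroids) <= 0))
    msg <- c(msg, "centroids must be strictly increasing")
  if (length(object@midpoints) > 1 && any(diff(object@midpoints) <= 0))
    msg <- c(msg, "midpoints must be strictly increasing")
  if (any(object@widths <= 0)) msg <- c(msg, "widths must be positive")
  if (object@compaction < 0) msg <- c(msg, "compaction must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' Construct a CIUGroundTruth
#'
#' @param centroids conformer CCS centroids (nm^2), increasing; the first
#'   is the native conformer, each later one an unfolding product.
#' @param midpoints transition midpoints (V), increasing; one fewer than
#'   centroids.
#' @param widths logistic transition widths (V); recycled across
#'   transitions.
#' @param compaction initial structural contraction (nm^2) ramped in
#'   before the first transition; 0 disables it.
#' @return A [CIUGroundTruth-class] object.
#' @export
CIUGroundTruth <- function(centroids, midpoints, widths = 2,
                           compaction = 0) {
  new("CIUGroundTruth", centroids = as.numeric(centroids),
      midpoints = as.numeric(midpoints),
      widths = rep_len(as.numeric(widths), length(midpoints)),
      compaction = as.numeric(compaction))
}

#' TheoreticalCCS: a Monte Carlo hard-sphere CCS estimate
#'
#' @slot method character, "PA" or "EHSS".
#' @slot value numeric, CCS in nm^2.
#' @slot se numeric, Monte Carlo standard error (nm^2), from the
#'   between-orientation variance.
#' @slot nOrientations integer, orientations averaged.
#' @slot nSamples integer, samples (projection hits or trajectories) per
#'   orientation.
#' @slot gasRadius numeric, buffer-gas collision radius (Angstrom).
#' @slot seed integer, RNG seed used.
#' @slot nDiscarded integer, trajectories discarded at the reflection cap
#'   (EHSS only; always 0 for PA).
#' @exportClass TheoreticalCCS
setClass("TheoreticalCCS",
  representation(method = "character", value = "numeric", se = "numeric",
                 nOrientations = "integer", nSamples = "integer",
                 gasRadius = "numeric", seed = "integer",
                 nDiscarded = "integer"),
  prototype(nDiscarded = 0L)
)

setValidity("TheoreticalCCS", function(object) {
  msg <- NULL
  if (!object@method %in% c("PA", "EHSS"))
    msg <- c(msg, "method must be 'PA' or 'EHSS'")
  if (object@value <= 0) msg <- c(msg, "value must be positive")
  if (is.null(msg)) TRUE else msg
})

#' BindingFit: a fitted dissociation constant
#'
#' @slot kd numeric, dissociation constant in nM.
#' @slot kdSe numeric, asymptotic standard error in nM (delta method from
#'   the log-space fit).
#' @slot residualNorm numeric, Euclidean norm of the fit residuals.
#' @slot nPoints integer, titration points used.
#' @slot converged logical, optimizer convergence flag.
#' @slot kdBoot numeric, bootstrap K_D resamples (empty if not requested).
#' @exportClass BindingFit
setClass("BindingFit",
  representation(kd = "numeric", kdSe = "numeric", residualNorm = "numeric",
                 nPoints = "integer", converged = "logical",
                 kdBoot = "numeric"),
  prototype(kdBoot = numeric(0))
)

setValidity("BindingFit", function(object) {
  if (object@kd <= 0) "kd must be positive" else TRUE
})
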