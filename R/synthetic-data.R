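PROTON_MASS <- 1.00728  # Da; protonation is the only adduct modelled

#' Simulate a native electrospray mass spectrum
#'
#' Builds a continuum spectrum as the sum, over species x charge state x
#' proteoform, of Gaussian peaks centred at (M + shift + z * 1.00728)/z.
#' Within a species the envelope area is split equally across its charge
#' states and across its proteoform ladder by the stated fractions, so the
#' integrated envelope of each species is proportional to its relative
#' abundance. Optional additive Gaussian noise (scaled by the maximum of
#' the clean spectrum, floored at zero) emulates detector noise.
#'
#' @param species list of [SpeciesSpec-class] objects (non-empty).
#' @param mzRange length-2 numeric, m/z window; must cover every implied
#'   peak centre.
#' @param peakSigma Gaussian peak width (sigma) in Da/e.
#' @param noiseLevel additive noise standard deviation as a fraction of the
#'   maximum clean intensity; 0 gives a deterministic spectrum.
#' @param seed RNG seed (used only when `noiseLevel > 0`).
#' @param mzStep grid spacing in Da/e; defaults to `peakSigma / 6`.
#' @return A [MassSpectrum-class]; `metadata$groundTruth` holds the peak
#'   table (species, charge, shift, centre, area) the spectrum was built
#'   from, and `metadata$abundanceFractions` the normalized species
#'   fractions.
#' @export
#' @examples
#' sp <- list(SpeciesSpec("monomer", 37000, 11:13, 10.5),
#'            SpeciesSpec("dimer",   74000, 16:19, 89.5))
#' ms <- simulateMassSpectrum(sp, c(2500, 5200), peakSigma = 2)
simulateMassSpectrum <- function(species, mzRange, peakSigma,
                                 noiseLevel = 0, seed = 1L,
                                 mzStep = peakSigma / 6) {
  if (length(species) == 0) stop("species list must be non-empty")
  if (peakSigma <= 0) stop("peakSigma must be positive")
  lapply(species, function(s) stopifnot(is(s, "SpeciesSpec")))

  totalAb <- sum(vapply(species, function(s) s@relAbundance, numeric(1)))
  if (totalAb <= 0) stop("total relative abundance must be positive")

  peaks <- do.call(rbind, lapply(species, function(s) {
    f0 <- 1 - sum(s@shifts$fraction)
    forms <- rbind(
      data.frame(massShift = 0, fraction = f0),
      s@shifts[, c("massShift", "fraction")])
    forms <- forms[forms$fraction > 0, , drop = FALSE]
    nz <- length(s@chargeStates)
    do.call(rbind, lapply(s@chargeStates, function(z) {
      data.frame(
        species = s@label, charge = z, massShift = forms$massShift,
        centre = (s@neutralMass + forms$massShift + z * PROTON_MASS) / z,
        area = (s@relAbundance / totalAb) * forms$fraction / nz)
    }))
  }))

  if (any(peaks$centre < mzRange[1]) || any(peaks$centre > mzRange[2]))
    stop("mzRange does not cover every implied peak centre (need ",
         sprintf("%.1f-%.1f", min(peaks$centre), max(peaks$centre)), ")")

  grid <- seq(mzRange[1], mzRange[2], by = mzStep)
  intens <- numeric(length(grid))
  amp <- peaks$area / (peakSigma * sqrt(2 * pi))
  for (i in seq_len(nrow(peaks)))
    intens <- intens + amp[i] * exp(-(grid - peaks$centre[i])^2 /
                                      (2 * peakSigma^2))
  if (noiseLevel > 0) {
    set.seed(seed)
    intens <- pmax(intens + rnorm(length(grid),
                                  sd = noiseLevel * max(intens)), 0)
  }

  fr <- vapply(species, function(s) s@relAbundance / totalAb, numeric(1))
  names(fr) <- vapply(species, function(s) s@label, character(1))
  MassSpectrum(grid, intens, metadata = list(
    groundTruth = peaks, abundanceFractions = fr,
    peakSigma = peakSigma, noiseLevel = noiseLevel, seed = seed))
}

#' Species specs for a monomer/dimer equilibrium scenario
#'
#' Convenience constructor for the two-species envelopes typical of a
#' partially dissociated homodimer under native electrospray: a monomer
#' at low charge states and a dimer at exactly twice the monomer mass.
#' The construct mass defaults to 37 kDa, representative of a ~330-residue
#' transcription-factor DNA-binding domain; ground truth is always the
#' argument, never a literature value.
#'
#' @param monomerPercent monomer peak-area percentage (0-100); the dimer
#'   takes the remainder.
#' @param monomerMass monomer neutral mass, Da.
#' @param monomerCharges,dimerCharges observed charge-state windows.
#' @return List of two [SpeciesSpec-class] objects (monomer, dimer).
#' @export
homodimerSpecies <- function(monomerPercent, monomerMass = 37000,
                             monomerCharges = 11:13,
                             dimerCharges = 16:19) {
  list(
    SpeciesSpec("monomer", monomerMass, monomerCharges, monomerPercent),
    SpeciesSpec("dimer", 2 * monomerMass, dimerCharges,
                100 - monomerPercent))
}

#' Simulate a ligand titration series
#'
#' Evaluates the 1:1 binding-ratio model (see [bindingRatio()]) at the
#' requested ligand concentrations and optionally adds Gaussian noise to
#' the ratios (floored at zero). With `noiseSd = 0` the series carries the
#' exact model values.
#'
#' @param kdNM generating dissociation constant, nM.
#' @param p0 protein concentration, uM.
#' @param l0 ligand concentrations, uM.
#' @param noiseSd additive noise standard deviation on the ratio scale.
#' @param seed RNG seed (used only when `noiseSd > 0`).
#' @return A [TitrationSeries-class].
#' @export
simulateTitrationSeries <- function(kdNM, p0, l0, noiseSd = 0, seed = 1L) {
  r <- bindingRatio(p0, l0, kdNM)
  if (noiseSd > 0) {
    set.seed(seed)
    r <- pmax(r + rnorm(length(r), sd = noiseSd), 0)
  }
  TitrationSeries(p0, l0, r)
}

# Occupancy-weighted centroid of the generating model at each voltage:
# state occupancies follow sequential logistic hand-offs, the native-state
# centroid is lowered by the compaction ramp over the pre-transition range.
ciuTruthCentroid <- function(truth, cv) {
  k <- length(truth@midpoints)
  if (k == 0) return(rep(truth@centroids[1], length(cv)))
  s <- vapply(seq_len(k), function(j)
    1 / (1 + exp(-(cv - truth@midpoints[j]) / truth@widths[j])),
    numeric(length(cv)))
  s <- cbind(rep(1, length(cv)), matrix(s, nrow = length(cv)), 0)
  occ <- s[, 1:(k + 1), drop = FALSE] - s[, 2:(k + 2), drop = FALSE]
  cen <- truth@centroids
  cenMat <- matrix(cen, nrow = length(cv), ncol = k + 1, byrow = TRUE)
  if (truth@compaction > 0 && k > 0) {
    ramp <- (cv - min(cv)) / (truth@midpoints[1] - min(cv))
    ramp <- pmin(pmax(ramp, 0), 1)
    cenMat[, 1] <- cen[1] - truth@compaction * ramp
  }
  rowSums(occ * cenMat)
}

#' Simulate a collision-induced unfolding fingerprint
#'
#' At each collision voltage the mobility profile is a single Gaussian
#' centred on the occupancy-weighted conformer centroid, with occupancies
#' handed from state to state by logistic transitions at the ground-truth
#' midpoints and widths, and the native-state centroid lowered by the
#' initial compaction ramped linearly over the pre-transition voltage
#' range. Every voltage column is normalized to unit sum.
#'
#' @param truth a [CIUGroundTruth-class]; every transition midpoint must
#'   lie inside `cv`.
#' @param cv collision-voltage grid (V), increasing.
#' @param ccsAxis mobility grid (nm^2), increasing.
#' @param peakSigma Gaussian mobility peak width (nm^2).
#' @param noiseLevel additive intensity noise as a fraction of the column
#'   maximum before renormalization; 0 is deterministic.
#' @param seed RNG seed (used only when `noiseLevel > 0`).
#' @return A [CIUFingerprint-class] with `normalization = "sum"`.
#' @export
#' @examples
#' tr <- CIUGroundTruth(c(44, 50, 55, 61), c(40, 48, 58), widths = 2)
#' fp <- simulateCIUFingerprint(tr, cv = 10:80, ccsAxis = seq(38, 70, 0.1),
#'                              peakSigma = 1.2)
simulateCIUFingerprint <- function(truth, cv, ccsAxis, peakSigma,
                                   noiseLevel = 0, seed = 1L) {
  stopifnot(is(truth, "CIUGroundTruth"))
  if (any(diff(cv) <= 0) || (length(ccsAxis) > 1 && any(diff(ccsAxis) <= 0)))
    stop("cv and ccsAxis must be strictly increasing")
  if (length(truth@midpoints) > 0 &&
      (any(truth@midpoints < min(cv)) || any(truth@midpoints > max(cv))))
    stop("every transition midpoint must lie inside the cv axis")
  if (peakSigma <= 0) stop("peakSigma must be positive")

  mu <- ciuTruthCentroid(truth, cv)
  m <- outer(mu, ccsAxis, function(m0, x)
    exp(-(x - m0)^2 / (2 * peakSigma^2)))
  if (noiseLevel > 0) {
    set.seed(seed)
    m <- pmax(m + matrix(rnorm(length(m), sd = noiseLevel * max(m)),
                         nrow = nrow(m)), 0)
  }
  m <- m / rowSums(m)
  CIUFingerprint(cv, ccsAxis, m, normalization = "sum")
}

#' Simulate a (multi-)conformer CCS distribution
#'
#' Gaussian mixture on a CCS grid, emulating the calibrated image of an
#' arrival-time distribution for one charge state. Ground-truth means,
#' widths and weights are the arguments.
#'
#' @param means conformer CCS means (nm^2).
#' @param sigmas Gaussian widths (nm^2); recycled.
#' @param weights mixture weights; recycled, normalized to sum 1.
#' @param ccsAxis CCS grid (nm^2), increasing.
#' @param charge charge state recorded on the distribution.
#' @param noiseLevel additive noise as a fraction of the maximum; 0 exact.
#' @param seed RNG seed.
#' @return A [CCSDistribution-class].
#' @export
simulateCCSDistribution <- function(means, sigmas, weights = 1, ccsAxis,
                                    charge = NA_integer_, noiseLevel = 0,
                                    seed = 1L) {
  sigmas <- rep_len(sigmas, length(means))
  weights <- rep_len(weights, length(means))
  weights <- weights / sum(weights)
  y <- numeric(length(ccsAxis))
  for (i in seq_along(means))
    y <- y + weights[i] * dnorm(ccsAxis, means[i], sigmas[i])
  if (noiseLevel > 0) {
    set.seed(seed)
    y <- pmax(y + rnorm(length(y), sd = noiseLevel * max(y)), 0)
  }
  CCSDistribution(ccsAxis, y, charge = charge)
}

#' Generate a toy atomic structure for CCS-engine validation
#'
#' Three analytic validation bodies: `"sphere-shell"` (points uniform on a
#' sphere of radius `scale`), `"two-sphere-dimer"` (two shells of half the
#' atoms each, centres `separation` apart along x), and `"helix"` (a
#' B-form-like helix of radius `scale`, 3.4 Angstrom rise and 36 degree
#' twist per point, a crude double-helix stand-in). Deterministic given
#' the seed.
#'
#' @param geometry one of "sphere-shell", "two-sphere-dimer", "helix".
#' @param nAtoms number of atoms (>= 1).
#' @param scale characteristic radius in Angstrom.
#' @param seed RNG seed (sphere-point sampling).
#' @param atomRadius uniform collision radius per atom (Angstrom).
#' @param separation centre separation of the dimer (Angstrom); default
#'   `2.5 * scale`.
#' @return An [AtomicStructure-class].
#' @export
simulateToyStructure <- function(geometry = c("sphere-shell",
                                              "two-sphere-dimer", "helix"),
                                 nAtoms, scale = 10, seed = 1L,
                                 atomRadius = 1.7,
                                 separation = 2.5 * scale) {
  geometry <- match.arg(geometry)
  if (nAtoms < 1) stop("nAtoms must be >= 1")
  set.seed(seed)
  sphere <- function(n, r) {
    if (n == 1) return(matrix(0, 1, 3))
    v <- matrix(rnorm(3 * n), ncol = 3)
    r * v / sqrt(rowSums(v^2))
  }
  xyz <- switch(geometry,
    "sphere-shell" = sphere(nAtoms, scale),
    "two-sphere-dimer" = {
      n1 <- ceiling(nAtoms / 2)
      a <- sphere(n1, scale); a[, 1] <- a[, 1] - separation / 2
      b <- sphere(nAtoms - n1, scale); b[, 1] <- b[, 1] + separation / 2
      rbind(a, b)
    },
    "helix" = {
      i <- seq_len(nAtoms) - 1
      ang <- i * 36 * pi / 180
      cbind(scale * cos(ang), scale * sin(ang), i * 3.4)
    })
  AtomicStructure(xyz, elements = "C", radii = atomRadius,
                  label = geometry)
}
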