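#' Correct a measured drift time for TOF residence
#'
#' Removes the mass-dependent time an ion spends in the time-of-flight
#' analyser after the mobility cell: `t' = t_d - edc * sqrt(m/z)`. The EDC
#' (enhanced duty cycle) delay coefficient is instrument-specific and must
#' be supplied with the calibration.
#'
#' @param td measured drift time(s), ms.
#' @param mzValue m/z of the ion(s), Da/e.
#' @param edcCoefficient EDC delay coefficient, ms per sqrt(Da/e).
#' @return Corrected drift time(s) t', ms (all positive, or an error
#'   naming the offending record).
#' @export
correctDriftTime <- function(td, mzValue, edcCoefficient) {
  if (any(td <= 0)) stop("drift times must be positive")
  tp <- td - edcCoefficient * sqrt(mzValue)
  bad <- which(tp <= 0)
  if (length(bad))
    stop("corrected drift time non-positive for record(s) ",
         paste(bad, collapse = ", "),
         " (td = ", paste(signif(td[bad], 4), collapse = ", "), " ms)")
  tp
}

# reduced mass of ion and buffer gas, Da
reducedMass <- function(neutralMass, gasMass) {
  neutralMass * gasMass / (neutralMass + gasMass)
}

#' Fit the TW-IMS power-law CCS calibration
#'
#' Travelling-wave drift times have no first-principles CCS relation;
#' calibrant ions of known helium-reference CCS anchor an empirical power
#' law. Each calibrant's reference CCS is reduced by its charge and its
#' ion-gas reduced mass (`CCS * sqrt(mu) / q`), and the log of the reduced
#' CCS is regressed on the log of the corrected drift time by ordinary
#' least squares. The slope and intercept of that line are the calibration
#' constants applied to unknowns.
#'
#' @param calibrants data.frame with columns `label`, `mass` (Da), `charge`
#'   (e), `ccsRef` (nm^2, helium reference) and `driftMs` (measured drift
#'   time, ms); at least 3 rows.
#' @param edcCoefficient EDC delay coefficient, ms per sqrt(Da/e).
#' @param gasMass buffer gas mass entering the reduced mass, Da; default
#'   helium (4.0026), the reference gas of the calibrant CCS values.
#' @return A [Calibration-class] with slope, intercept, r-squared.
#' @export
#' @examples
#' cal0 <- Calibration(slope = 0.55, intercept = 2.0, edcCoefficient = 1.4)
#' tbl <- synthesizeCalibrants(cal0)
#' fitCalibration(tbl, edcCoefficient = 1.4)
fitCalibration <- function(calibrants, edcCoefficient, gasMass = 4.0026) {
  req <- c("mass", "charge", "ccsRef", "driftMs")
  if (!all(req %in% names(calibrants)))
    stop("calibrants needs columns: ", paste(req, collapse = ", "))
  if (nrow(calibrants) < 3) stop("need >= 3 calibrant points")
  tp <- correctDriftTime(calibrants$driftMs,
                         (calibrants$mass + calibrants$charge * PROTON_MASS) /
                           calibrants$charge,
                         edcCoefficient)
  if (length(unique(signif(tp, 12))) < 2)
    stop("degenerate calibrant set: identical corrected drift times")
  mu <- reducedMass(calibrants$mass, gasMass)
  yRed <- log(calibrants$ccsRef * sqrt(mu) / calibrants$charge)
  xLog <- log(tp)
  fit <- lm(yRed ~ xLog)
  Calibration(slope = unname(coef(fit)[2]),
              intercept = unname(coef(fit)[1]),
              edcCoefficient = edcCoefficient, gasMass = gasMass,
              rSquared = summary(fit)$r.squared,
              nCalibrants = nrow(calibrants))
}

#' Apply a calibration to a corrected drift time
#'
#' The fitted power law in its working form:
#' `CCS = (q / sqrt(mu)) * t'^m * exp(C)`, with the reduced mass `mu`
#' computed from the ion's neutral mass and the calibration's gas mass.
#'
#' @param tPrime corrected drift time(s), ms (positive).
#' @param q charge state, e.
#' @param neutralMass ion neutral mass, Da.
#' @param cal a [Calibration-class].
#' @return CCS value(s), nm^2.
#' @export
applyCalibration <- function(tPrime, q, neutralMass, cal) {
  stopifnot(is(cal, "Calibration"))
  if (any(tPrime <= 0)) stop("corrected drift times must be positive")
  mu <- reducedMass(neutralMass, cal@gasMass)
  (q / sqrt(mu)) * tPrime^cal@slope * exp(cal@intercept)
}

#' Invert a calibration: drift time that maps to a given CCS
#'
#' The exact inverse of [applyCalibration()] plus the EDC correction,
#' used to synthesize measured drift times with known ground truth for
#' round-trip validation.
#'
#' @param ccs target CCS, nm^2.
#' @param q charge state.
#' @param neutralMass ion neutral mass, Da.
#' @param cal a [Calibration-class].
#' @return Measured (uncorrected) drift time, ms.
#' @export
driftTimeForCCS <- function(ccs, q, neutralMass, cal) {
  stopifnot(is(cal, "Calibration"))
  mu <- reducedMass(neutralMass, cal@gasMass)
  tPrime <- (ccs * sqrt(mu) / (q * exp(cal@intercept)))^(1 / cal@slope)
  mzValue <- (neutralMass + q * PROTON_MASS) / q
  tPrime + cal@edcCoefficient * sqrt(mzValue)
}

#' Synthesize a calibrant table from a known calibration
#'
#' Builds drift times for a set of calibrant proteins by inverting a known
#' calibration, so that refitting must recover the generating constants.
#' The default table mimics the masses, charges and helium-reference CCS
#' magnitudes of the common native calibrant proteins (beta-lactoglobulin
#' A, transthyretin, avidin, serum albumin, concanavalin A).
#'
#' @param cal the generating [Calibration-class].
#' @param table optional data.frame with `label`, `mass`, `charge`,
#'   `ccsRef` to override the built-in calibrant set.
#' @return data.frame with `label`, `mass`, `charge`, `ccsRef`, `driftMs`.
#' @export
synthesizeCalibrants <- function(cal, table = NULL) {
  if (is.null(table)) {
    table <- data.frame(
      label = c("beta-lactoglobulin A", "transthyretin", "avidin",
                "serum albumin", "concanavalin A"),
      mass = c(35300, 55900, 64000, 66400, 102000),
      charge = c(12, 14, 15, 15, 20),
      ccsRef = c(33.1, 42.0, 46.0, 47.5, 61.0))
  }
  table$driftMs <- mapply(driftTimeForCCS, table$ccsRef, table$charge,
                          table$mass, MoreArgs = list(cal = cal))
  table
}

#' Transform an arrival-time distribution to CCS space
#'
#' Maps every drift-time sample of an ATD through the calibration
#' (EDC correction then power law) and re-grids increasing. Intensities
#' are carried over sample-by-sample without Jacobian reweighting, the
#' common TWIMS practice; set `jacobian = TRUE` to weight by |dt'/dCCS|
#' instead.
#'
#' @param driftMs measured drift times, ms.
#' @param intensityValues intensities, same length.
#' @param q charge state.
#' @param neutralMass ion neutral mass, Da.
#' @param cal a [Calibration-class].
#' @param jacobian logical; apply the change-of-variable weighting.
#' @return A [CCSDistribution-class] carrying the calibration.
#' @export
ccsDistributionFromATD <- function(driftMs, intensityValues, q, neutralMass,
                                   cal, jacobian = FALSE) {
  if (length(driftMs) == 0) stop("empty arrival-time distribution")
  if (length(driftMs) != length(intensityValues))
    stop("drift times and intensities must have equal length")
  mzValue <- (neutralMass + q * PROTON_MASS) / q
  tp <- correctDriftTime(driftMs, mzValue, cal@edcCoefficient)
  ccs <- applyCalibration(tp, q, neutralMass, cal)
  wt <- intensityValues
  if (jacobian) {
    # dCCS/dt' = m * CCS / t'  (power law), so dt'/dCCS = t'/(m*CCS)
    wt <- wt * tp / (cal@slope * ccs)
  }
  o <- order(ccs)
  CCSDistribution(ccs[o], wt[o], charge = q, calibration = cal)
}

#' CCSD: full width at half maximum of a CCS distribution
#'
#' The conformational-spread measure reported alongside a CCS value: the
#' distance between the outermost crossings of half the global maximum,
#' with linear interpolation between grid points. Works for asymmetric
#' and multimodal profiles (the outermost-crossing convention).
#'
#' @param dist a [CCSDistribution-class] with a positive maximum.
#' @return FWHM in nm^2. Errors if the profile never drops below half
#'   maximum inside the grid (the width would be truncated).
#' @export
#' @examples
#' d <- simulateCCSDistribution(44.3, sigmas = 2.9 / 2.3548,
#'                              ccsAxis = seq(30, 60, 0.02))
#' ccsd(d)  # ~2.9
ccsd <- function(dist) {
  stopifnot(is(dist, "CCSDistribution"))
  x <- dist@ccs; y <- dist@intensity
  ymax <- max(y)
  if (ymax <= 0) stop("distribution maximum must be positive")
  h <- ymax / 2
  above <- y >= h
  if (above[1] || above[length(y)])
    stop("distribution does not drop below half maximum inside the grid; ",
         "FWHM would be truncated")
  iFirst <- which(above)[1]
  iLast <- which(above)[sum(above)]
  interp <- function(i0, i1)
    x[i0] + (h - y[i0]) * (x[i1] - x[i0]) / (y[i1] - y[i0])
  left <- interp(iFirst - 1, iFirst)
  right <- interp(iLast + 1, iLast)
  right - left
}

#' Decompose a CCS distribution into Gaussian conformers
#'
#' Least-squares fit of an `n`-component Gaussian mixture to the profile
#' (Levenberg-Marquardt, non-negative amplitudes), for resolving partially
#' overlapping conformer families. Components are reported sorted by
#' mean; weights are the component areas normalized to sum 1.
#'
#' @param dist a [CCSDistribution-class].
#' @param n number of Gaussian components (>= 1).
#' @param maxRestarts jittered restarts on non-convergence.
#' @return data.frame with `mean` (nm^2), `sigma` (nm^2), `weight`;
#'   attribute `converged`.
#' @export
decomposeConformers <- function(dist, n, maxRestarts = 5) {
  stopifnot(is(dist, "CCSDistribution"))
  if (n < 1) stop("n must be >= 1")
  x <- dist@ccs; y <- dist@intensity
  if (sum(y) <= 0) stop("distribution has no intensity")

  # init: split the intensity-weighted quantile range
  cdf <- cumsum(y) / sum(y)
  qs <- (seq_len(n) - 0.5) / n
  mu0 <- approx(cdf, x, xout = qs, ties = "ordered", rule = 2)$y
  mu0 <- mu0 + seq(0, 1e-6, length.out = n)  # break exact ties
  sdAll <- sqrt(sum(y * (x - sum(y * x) / sum(y))^2) / sum(y))
  s0 <- rep(max(sdAll / n, 2 * median(diff(x))), n)
  a0 <- approx(x, y, xout = mu0, rule = 2)$y

  fit <- NULL; conv <- FALSE
  for (attempt in 0:maxRestarts) {
    jit <- if (attempt == 0) 1 else exp(runif(1, -0.7, 0.7))
    p0 <- c(rbind(a0, mu0, s0 * jit))
    res <- tryCatch(
      minpack.lm::nls.lm(
        par = p0,
        fn = function(p) {
          yy <- numeric(length(x))
          for (j in seq_len(n))
            yy <- yy + p[3 * j - 2] *
              exp(-(x - p[3 * j - 1])^2 / (2 * p[3 * j]^2))
          y - yy
        },
        lower = rep(c(0, min(x), 1e-9), n),
        upper = rep(c(Inf, max(x), diff(range(x))), n),
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(res) && res$info %in% 1:4) { fit <- res; conv <- TRUE; break }
    if (!is.null(res) && is.null(fit)) fit <- res
  }
  if (is.null(fit)) stop("conformer decomposition failed outright")
  p <- fit$par
  out <- data.frame(
    mean = p[seq(2, 3 * n, by = 3)],
    sigma = abs(p[seq(3, 3 * n, by = 3)]),
    amp = p[seq(1, 3 * n, by = 3)])
  out$weight <- out$amp * out$sigma
  out$weight <- out$weight / sum(out$weight)
  out <- out[order(out$mean), c("mean", "sigma", "weight")]
  rownames(out) <- NULL
  attr(out, "converged") <- conv
  out
}

#' Charge-state-averaged CCS
#'
#' Intensity-weighted mean CCS of each distribution, averaged across
#' charge states — the convention behind a single reported CCS for a
#' species observed over several charges.
#'
#' @param dists list of [CCSDistribution-class] objects.
#' @return Mean of the per-charge apex-independent centroid CCS values.
#' @export
chargeAveragedCCS <- function(dists) {
  v <- vapply(dists, function(d) {
    sum(d@ccs * d@intensity) / sum(d@intensity)
  }, numeric(1))
  mean(v)
}
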