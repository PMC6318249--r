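#' Pick candidate peak centres from a mass spectrum
#'
#' Local-maximum scan: grid points higher than both neighbours, above a
#' relative height threshold, thinned so surviving centres are at least
#' `minSeparation` apart (keeping the taller of any close pair). Returns
#' centres sorted by m/z.
#'
#' @param spectrum a [MassSpectrum-class].
#' @param minRelHeight minimum peak height as a fraction of the spectrum
#'   maximum, in (0, 1).
#' @param minSeparation minimum distance between reported centres, Da/e.
#' @return Numeric vector of candidate m/z centres (possibly empty).
#' @export
pickPeaks <- function(spectrum, minRelHeight = 0.02, minSeparation = 0) {
  stopifnot(is(spectrum, "MassSpectrum"))
  x <- spectrum@mz; y <- spectrum@intensity
  if (length(x) == 0) stop("empty spectrum")
  if (minRelHeight <= 0 || minRelHeight >= 1)
    stop("minRelHeight must lie in (0, 1)")
  ymax <- max(y)
  if (ymax <= 0) return(numeric(0))
  n <- length(y)
  if (n < 3) return(numeric(0))
  i <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1
  i <- i[y[i] >= minRelHeight * ymax]
  if (length(i) == 0) return(numeric(0))
  # greedy thinning, tallest first
  keep <- logical(0); centres <- numeric(0)
  for (j in i[order(y[i], decreasing = TRUE)]) {
    if (all(abs(x[j] - centres) >= minSeparation)) {
      centres <- c(centres, x[j])
    }
  }
  sort(centres)
}

# model: baseline + sum of Gaussians; p = (b, a1, c1, s1, a2, c2, s2, ...)
multiGaussEval <- function(p, x) {
  k <- (length(p) - 1) / 3
  y <- rep(p[1], length(x))
  for (j in seq_len(k)) {
    a <- p[3 * j - 1]; c0 <- p[3 * j]; s <- p[3 * j + 1]
    y <- y + a * exp(-(x - c0)^2 / (2 * s^2))
  }
  y
}

# crude per-peak sigma from the half-height width around a local maximum
estimateSigma <- function(x, y, centre) {
  i0 <- which.min(abs(x - centre))
  h <- y[i0] / 2
  iL <- i0; while (iL > 1 && y[iL] > h) iL <- iL - 1
  iR <- i0; while (iR < length(y) && y[iR] > h) iR <- iR + 1
  fw <- x[iR] - x[iL]
  max(fw / 2.3548, 2 * (x[2] - x[1]))
}

#' Fit a sum of Gaussians plus a constant baseline to a spectrum
#'
#' Nonlinear least squares (Levenberg-Marquardt) of
#' `baseline + sum_k a_k exp(-(x - c_k)^2 / (2 s_k^2))` over the full
#' spectrum, initialized at the supplied centres with sigmas taken from
#' each local maximum's half-height width. On non-convergence the fit is
#' restarted up to `maxRestarts` times with jittered sigmas; a fit that
#' still fails is returned flagged, never silently dropped. Peak areas are
#' `a_k * s_k * sqrt(2 pi)`.
#'
#' @param spectrum a [MassSpectrum-class].
#' @param initialCentres starting centres, all within the spectrum range.
#' @param maxRestarts restarts with jittered initial sigmas.
#' @return A data.frame of class `peakFits` with one row per peak:
#'   `centre`, `sigma`, `area`, `centreSe`, `species` (NA until assigned),
#'   `charge` (NA until assigned); attributes `residualNorm` and
#'   `converged`.
#' @export
fitMultiGaussian <- function(spectrum, initialCentres, maxRestarts = 5) {
  stopifnot(is(spectrum, "MassSpectrum"))
  x <- spectrum@mz; y <- spectrum@intensity
  if (length(initialCentres) == 0) stop("need at least one initial centre")
  if (any(initialCentres < min(x)) || any(initialCentres > max(x)))
    stop("initial centres must lie within the spectrum range")

  k <- length(initialCentres)
  sig0 <- vapply(initialCentres, function(c0) estimateSigma(x, y, c0),
                 numeric(1))
  amp0 <- vapply(initialCentres, function(c0) y[which.min(abs(x - c0))],
                 numeric(1))
  startVec <- function(jit) {
    p <- c(0, rbind(amp0, initialCentres, sig0 * jit))
    names(p) <- c("b", paste0(rep(c("a", "c", "s"), k),
                              rep(seq_len(k), each = 3)))
    p
  }
  lower <- c(-Inf, rep(c(0, min(x), 1e-9), k))
  upper <- c(Inf, rep(c(Inf, max(x), diff(range(x))), k))

  fit <- NULL; conv <- FALSE
  for (attempt in 0:maxRestarts) {
    jit <- if (attempt == 0) 1 else exp(runif(1, -0.7, 0.7))
    res <- tryCatch(
      minpack.lm::nls.lm(
        par = startVec(jit),
        fn = function(p) y - multiGaussEval(p, x),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 400)),
      error = function(e) NULL)
    if (!is.null(res) && res$info %in% 1:4) { fit <- res; conv <- TRUE; break }
    if (!is.null(res) && is.null(fit)) fit <- res
  }
  if (is.null(fit)) stop("multi-Gaussian fit failed outright")

  p <- fit$par
  covSe <- rep(NA_real_, length(p))
  se <- tryCatch({
    s <- summary(fit)
    s$coefficients[, "Std. Error"]
  }, error = function(e) covSe)
  out <- data.frame(
    centre = p[seq(3, length(p), by = 3)],
    sigma = abs(p[seq(4, length(p), by = 3)]),
    area = p[seq(2, length(p), by = 3)] *
      abs(p[seq(4, length(p), by = 3)]) * sqrt(2 * pi),
    centreSe = se[seq(3, length(p), by = 3)],
    species = NA_character_, charge = NA_integer_,
    row.names = NULL)
  out <- out[order(out$centre), ]
  rownames(out) <- NULL
  attr(out, "residualNorm") <- sqrt(sum(fit$fvec^2))
  attr(out, "converged") <- conv
  attr(out, "baseline") <- unname(p[1])
  class(out) <- c("peakFits", "data.frame")
  out
}

#' Assign fitted peaks to species and charge states
#'
#' Each peak is matched to the (species, z) hypothesis minimizing the m/z
#' residual `|centre - (M + z * 1.00728) / z|` over the candidate masses
#' and their allowed charge windows; hypotheses outside `tolerance` are
#' rejected and the peak stays unassigned (contaminant peaks are
#' expected). Ties are broken deterministically: smaller residual first,
#' then lower charge.
#'
#' @param peaks a `peakFits` data.frame from [fitMultiGaussian()].
#' @param candidateMasses data.frame with columns `label`, `mass` (Da) and
#'   optionally `zmin`, `zmax` bounding the charge window (default 1-60).
#' @param tolerance maximum acceptable residual, Da/e.
#' @return The peak table with `species` and `charge` filled in where a
#'   hypothesis matched.
#' @export
assignChargeStates <- function(peaks, candidateMasses, tolerance = 1) {
  stopifnot(is.data.frame(peaks), is.data.frame(candidateMasses))
  if (any(candidateMasses$mass <= 0)) stop("candidate masses must be positive")
  if (is.null(candidateMasses$zmin)) candidateMasses$zmin <- 1L
  if (is.null(candidateMasses$zmax)) candidateMasses$zmax <- 60L

  hyp <- do.call(rbind, lapply(seq_len(nrow(candidateMasses)), function(i) {
    z <- seq(candidateMasses$zmin[i], candidateMasses$zmax[i])
    data.frame(label = candidateMasses$label[i], z = z,
               mzTheo = (candidateMasses$mass[i] + z * PROTON_MASS) / z)
  }))
  for (i in seq_len(nrow(peaks))) {
    resid <- abs(peaks$centre[i] - hyp$mzTheo)
    ok <- which(resid <= tolerance)
    if (length(ok) == 0) next
    ord <- ok[order(resid[ok], hyp$z[ok])]
    best <- ord[1]
    peaks$species[i] <- as.character(hyp$label[best])
    peaks$charge[i] <- hyp$z[best]
  }
  peaks
}

#' Deconvolute a neutral mass from assigned charge-state peaks
#'
#' Converts each assigned peak back to a neutral mass,
#' `M = z * centre - z * 1.00728`, and summarises the ladder as a mean
#' and standard deviation. With a single charge state the mass is still
#' returned but the spread is flagged undefined. A +79.966 Da spacing
#' between ladders resolves phospho-proteoform states.
#'
#' @param peaks a `peakFits` data.frame with `charge` assigned (rows with
#'   NA charge are dropped).
#' @return List with `mass` (Da), `sd` (Da, NA for one charge state),
#'   `n` (charge states used), `perPeak` (per-peak masses).
#' @export
deconvoluteNeutralMass <- function(peaks) {
  pk <- peaks[!is.na(peaks$charge), , drop = FALSE]
  if (nrow(pk) == 0) stop("no assigned peaks")
  m <- pk$charge * pk$centre - pk$charge * PROTON_MASS
  list(mass = mean(m),
       sd = if (length(m) >= 2) sd(m) else NA_real_,
       n = length(m), perPeak = m)
}

#' Quantify species from assigned peak areas
#'
#' Sums fitted peak areas per species label over all assigned charge
#' states and normalizes to fractions over the requested label set —
#' e.g. `c("monomer", "dimer")` for a dimerization contrast, or
#' `c("dimer", "dimer:DNA")` for DNA occupancy, which the source
#' experiments report as separate contrasts.
#'
#' @param peaks an assigned `peakFits` data.frame.
#' @param labels species labels forming the denominator; default all
#'   assigned labels.
#' @return A data.frame (class `abundanceTable`) with `species`, `area`,
#'   `fraction`; fractions sum to 1 over the listed species.
#' @export
quantifySpecies <- function(peaks, labels = NULL) {
  pk <- peaks[!is.na(peaks$species), , drop = FALSE]
  if (nrow(pk) == 0) stop("no assigned peaks to quantify")
  if (is.null(labels)) labels <- unique(pk$species)
  pk <- pk[pk$species %in% labels, , drop = FALSE]
  if (nrow(pk) == 0) stop("no peaks assigned to the requested labels")
  area <- vapply(labels, function(l) sum(pk$area[pk$species == l]),
                 numeric(1))
  out <- data.frame(species = labels, area = unname(area),
                    fraction = unname(area / sum(area)),
                    row.names = NULL)
  class(out) <- c("abundanceTable", "data.frame")
  out
}

#' Full spectrum deconvolution convenience wrapper
#'
#' Chains [pickPeaks()], [fitMultiGaussian()], [assignChargeStates()] and
#' [quantifySpecies()] with sensible defaults for baseline-resolved
#' native spectra.
#'
#' @param spectrum a [MassSpectrum-class].
#' @param candidateMasses see [assignChargeStates()].
#' @param minRelHeight,minSeparation see [pickPeaks()].
#' @param tolerance see [assignChargeStates()].
#' @param labels see [quantifySpecies()].
#' @return List with `peaks` (assigned fits) and `abundance` (table).
#' @export
deconvoluteSpectrum <- function(spectrum, candidateMasses,
                                minRelHeight = 0.02, minSeparation = 5,
                                tolerance = 2, labels = NULL) {
  centres <- pickPeaks(spectrum, minRelHeight, minSeparation)
  fits <- fitMultiGaussian(spectrum, centres)
  fits <- assignChargeStates(fits, candidateMasses, tolerance)
  list(peaks = fits, abundance = quantifySpecies(fits, labels))
}
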