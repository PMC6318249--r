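#' Equilibrium bound/unbound intensity ratio for 1:1 binding
#'
#' Closed-form titration model for a protein P at fixed total concentration
#' titrated with ligand L. Solving the 1:1 mass-balance quadratic for the
#' complex concentration gives the expected intensity ratio of the bound
#' complex over the unbound protein,
#'
#' I(PL)/I(P) = 1/2 ( -1 - p + l + sqrt( 4 l + (l - p - 1)^2 ) ),
#'
#' with p = `[P]0`/K_D and l = `[L]0`/K_D. All concentrations are converted
#' to nM internally before the division, so mixed micromolar protein /
#' nanomolar K_D inputs are handled consistently. The ratio is 0 at
#' `l0 = 0` and is non-negative everywhere.
#'
#' @param p0 total protein concentration, uM.
#' @param l0 total ligand concentration(s), uM; vectorized.
#' @param kdNM dissociation constant, nM.
#' @return Numeric vector of expected I(PL)/I(P) ratios.
#' @seealso [fitKd()], [simulateTitrationSeries()]
#' @export
#' @examples
#' bindingRatio(p0 = 3, l0 = c(0, 1, 3, 6), kdNM = 37)
bindingRatio <- function(p0, l0, kdNM) {
  if (kdNM <= 0) stop("kdNM must be positive")
  if (p0 <= 0) stop("p0 must be positive")
  if (any(l0 < 0)) stop("ligand concentrations must be non-negative")
  p <- p0 * 1000 / kdNM      # uM -> nM, then per K_D
  l <- l0 * 1000 / kdNM
  r <- 0.5 * (-1 - p + l + sqrt(4 * l + (l - p - 1)^2))
  pmax(r, 0)                 # guards tiny negative round-off at l0 = 0
}

#' Fit a dissociation constant to a titration series
#'
#' Nonlinear least squares of the 1:1 binding-ratio model (see
#' [bindingRatio()]) against observed I(PL)/I(P) ratios. The single free
#' parameter is log(K_D), so the optimizer cannot wander into negative
#' dissociation constants; the standard error is transported back to the
#' nM scale by the delta method. The default start is the geometric mean
#' of the protein concentration and the smallest nonzero ligand
#' concentration.
#'
#' @param series a [TitrationSeries-class].
#' @param kdInit starting K_D in nM; NULL for the default heuristic.
#' @param bootstrap number of bootstrap resamples over titration points for
#'   an empirical K_D distribution (0 disables).
#' @param seed RNG seed for the bootstrap.
#' @return A [BindingFit-class] with `kd` (nM), `kdSe`, residual norm,
#'   convergence flag and any bootstrap resamples.
#' @export
#' @examples
#' ts <- simulateTitrationSeries(kdNM = 37, p0 = 3,
#'                               l0 = c(0.2, 0.5, 1, 2, 3, 4.5, 6))
#' fitKd(ts)
fitKd <- function(series, kdInit = NULL, bootstrap = 0, seed = 1L) {
  stopifnot(is(series, "TitrationSeries"))
  l0 <- series@l0; ratio <- series@ratio; p0 <- series@p0
  if (length(l0) < 3 || length(unique(l0)) < 2)
    stop("need >= 3 titration points with >= 2 distinct ligand concentrations")
  if (all(ratio == 0)) stop("all ratios are zero; no binding signal to fit")
  if (is.null(kdInit)) {
    lmin <- min(l0[l0 > 0])
    kdInit <- sqrt(p0 * lmin) * 1000      # geometric mean, uM -> nM
  }
  if (kdInit <= 0) stop("kdInit must be positive")

  # Levenberg-Marquardt on log(K_D); nls.lm keeps stepping where a plain
  # Gauss-Newton would abort on the flat low-K_D limit (saturated binding)
  fit1 <- function(l, r, start) {
    minpack.lm::nls.lm(
      par = c(logkd = log(start)),
      fn = function(p) r - bindingRatio(p0, l, exp(p[["logkd"]])),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15))
  }
  fit <- fit1(l0, ratio, kdInit)
  kdHat <- exp(fit$par[["logkd"]])
  seLog <- tryCatch(summary(fit)$coefficients[1, "Std. Error"],
                    error = function(e) NA_real_)
  kdSe <- kdHat * seLog   # delta method
  conv <- fit$info %in% 1:4

  kdBoot <- numeric(0)
  if (bootstrap > 0) {
    set.seed(seed)
    n <- length(l0)
    kdBoot <- vapply(seq_len(bootstrap), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(l0[idx])) < 2 || all(ratio[idx] == 0))
        return(NA_real_)
      tryCatch(exp(fit1(l0[idx], ratio[idx], kdHat)$par[["logkd"]]),
               error = function(e) NA_real_)
    }, numeric(1))
    kdBoot <- kdBoot[is.finite(kdBoot)]
  }

  new("BindingFit", kd = kdHat, kdSe = kdSe,
      residualNorm = sqrt(sum(fit$fvec^2)),
      nPoints = length(l0), converged = isTRUE(conv), kdBoot = kdBoot)
}

#' Relative binding affinity of a variant versus a reference
#'
#' Expresses a test dissociation constant as a percentage affinity
#' relative to a reference: `100 * kdRef / kdTest`. A weaker binder
#' (larger K_D) scores below 100%. Rounding is left to presentation.
#'
#' @param kdRef reference K_D (nM).
#' @param kdTest test K_D (nM).
#' @return Relative affinity in percent.
#' @export
#' @examples
#' relativeAffinity(37, 424)  # ~8.7 %
relativeAffinity <- function(kdRef, kdTest) {
  if (kdRef <= 0 || kdTest <= 0) stop("dissociation constants must be positive")
  100 * kdRef / kdTest
}
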