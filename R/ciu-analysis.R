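#' Assemble a CIU fingerprint from per-voltage mobility profiles
#'
#' Takes one mobility profile per collision voltage, re-grids ragged
#' profiles onto the union mobility grid by linear interpolation (zero
#' outside each profile's support), and max-normalizes every voltage
#' column — the standard CIU contour convention. Raw intensities can be
#' kept with `normalize = "none"`.
#'
#' @param profiles list of entries, each a list/record with `cv` (scalar,
#'   V), `mobility` (increasing numeric) and `intensity` (same length).
#' @param normalize "max" (default), "sum" or "none".
#' @return A [CIUFingerprint-class], voltages sorted increasing.
#' @export
buildFingerprint <- function(profiles, normalize = c("max", "sum", "none")) {
  normalize <- match.arg(normalize)
  if (length(profiles) < 2) stop("need profiles at >= 2 collision voltages")
  cvs <- vapply(profiles, function(p) as.numeric(p$cv), numeric(1))
  if (anyDuplicated(cvs)) stop("duplicate collision voltage values")

  grids <- lapply(profiles, function(p) as.numeric(p$mobility))
  common <- sort(unique(unlist(grids)))
  m <- t(vapply(profiles, function(p) {
    if (identical(as.numeric(p$mobility), common)) return(as.numeric(p$intensity))
    approx(p$mobility, p$intensity, xout = common, rule = 1)$y -> yy
    yy[is.na(yy)] <- 0
    yy
  }, numeric(length(common))))
  o <- order(cvs)
  m <- m[o, , drop = FALSE]
  m <- normalizeFingerprintMatrix(m, normalize)
  CIUFingerprint(cvs[o], common, m, normalization = normalize)
}

normalizeFingerprintMatrix <- function(m, normalize) {
  if (normalize == "max") {
    mx <- apply(m, 1, max)
    m[mx > 0, ] <- m[mx > 0, , drop = FALSE] / mx[mx > 0]
  } else if (normalize == "sum") {
    sm <- rowSums(m)
    m[sm > 0, ] <- m[sm > 0, , drop = FALSE] / sm[sm > 0]
  }
  m
}

#' Renormalize an existing fingerprint
#'
#' @param fp a [CIUFingerprint-class].
#' @param normalize "max", "sum" or "none" (no-op relabel).
#' @return The renormalized fingerprint. Idempotent for a given mode.
#' @export
normalizeFingerprint <- function(fp, normalize = c("max", "sum", "none")) {
  normalize <- match.arg(normalize)
  m <- normalizeFingerprintMatrix(fp@intensity, normalize)
  CIUFingerprint(fp@cv, fp@mobility, m, normalization = normalize)
}

#' Intensity-weighted centroid of each voltage column
#'
#' The centroid trace is the summary curve transition detection works on:
#' the intensity-weighted mean mobility at each collision voltage.
#'
#' @param fp a [CIUFingerprint-class].
#' @return data.frame with `cv` (V) and `centroid` (mobility units).
#'   Errors on an all-zero voltage column.
#' @export
centroidTrace <- function(fp) {
  stopifnot(is(fp, "CIUFingerprint"))
  sm <- rowSums(fp@intensity)
  if (any(sm <= 0))
    stop("all-zero intensity column at CV = ",
         paste(fp@cv[sm <= 0], collapse = ", "), " V")
  data.frame(cv = fp@cv,
             centroid = as.numeric(fp@intensity %*% fp@mobility) / sm)
}

# sum-of-logistic-steps model on the centroid trace
logisticStepsEval <- function(p, cv, k) {
  y <- rep(p[1], length(cv))
  for (j in seq_len(k)) {
    a <- p[3 * j - 1]; m0 <- p[3 * j]; w <- p[3 * j + 1]
    y <- y + a / (1 + exp(-(cv - m0) / w))
  }
  y
}

fitLogisticSteps <- function(trace, k, maxRestarts = 5) {
  cv <- trace$cv; y <- trace$centroid
  # initial midpoints from the k largest slope peaks, kept in CV order
  dy <- diff(y); mids <- cv[-1] - diff(cv) / 2
  cand <- order(dy, decreasing = TRUE)
  pick <- integer(0)
  for (i in cand) {
    if (all(abs(mids[i] - mids[pick]) > 2 * median(diff(cv)))) pick <- c(pick, i)
    if (length(pick) == k) break
  }
  m0 <- sort(mids[pick])
  if (length(m0) < k)
    m0 <- sort(c(m0, quantile(cv, (seq_len(k - length(m0))) / (k + 1))))
  amp0 <- rep((max(y) - min(y)) / k, k)
  w0 <- rep(2 * median(diff(cv)), k)

  best <- NULL
  for (attempt in 0:maxRestarts) {
    jit <- if (attempt == 0) 1 else exp(runif(1, -0.5, 0.5))
    p0 <- c(min(y), c(rbind(amp0, m0, w0 * jit)))
    res <- tryCatch(
      minpack.lm::nls.lm(
        par = p0,
        fn = function(p) y - logisticStepsEval(p, cv, k),
        lower = c(-Inf, rep(c(0, min(cv), 1e-3), k)),
        upper = c(Inf, rep(c(Inf, max(cv), diff(range(cv))), k)),
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(res) &&
        (is.null(best) || sum(res$fvec^2) < sum(best$fvec^2))) best <- res
  }
  if (is.null(best)) return(NULL)
  rss <- sum(best$fvec^2)
  nObs <- length(y)
  # floor the RSS at a tiny fraction of the trace rise so that BIC does
  # not reward fitting machine-precision residue on noiseless traces
  rssEff <- max(rss, nObs * (1e-6 * diff(range(y)))^2)
  list(par = best$par, rss = rss, k = k,
       bic = nObs * log(rssEff / nObs) + (3 * k + 1) * log(nObs),
       converged = best$info %in% 1:4)
}

#' Detect unfolding transitions in a CIU fingerprint
#'
#' Fits the column-centroid trace with a constant plus a sum of rising
#' logistic steps; each step is one unfolding transition, its midpoint
#' the CV50. With `nStates = "auto"` the number of transitions is chosen
#' by BIC over 1..`maxStates`. The trace should plateau at both ends of
#' the voltage range; if not, the result is flagged partial.
#'
#' @param fp a [CIUFingerprint-class].
#' @param nStates number of transitions, or "auto" for BIC selection.
#' @param maxStates largest model considered when automatic.
#' @return data.frame with one row per transition, sorted by `cv50`:
#'   `cv50` (V), `width` (V), `preCentroid`, `postCentroid` (model
#'   evaluations just before/after the step); attributes `converged`,
#'   `bic` (per candidate model when automatic) and `partial` (TRUE when
#'   a terminal plateau is missing).
#' @export
#' @examples
#' tr <- CIUGroundTruth(c(44, 50, 55, 61), c(40, 48, 58), widths = 2)
#' fp <- simulateCIUFingerprint(tr, 10:80, seq(38, 70, 0.1), 1.2)
#' detectTransitions(fp, nStates = 3)
detectTransitions <- function(fp, nStates = "auto", maxStates = 4) {
  trace <- centroidTrace(fp)
  cv <- trace$cv; y <- trace$centroid

  # plateau check: slope in the terminal fifths small vs overall rise
  nEdge <- max(3, floor(length(cv) / 5))
  rise <- max(y) - min(y)
  slopeA <- abs(mean(diff(y[seq_len(nEdge)])))
  slopeB <- abs(mean(diff(y[seq(length(y) - nEdge + 1, length(y))])))
  step <- median(diff(cv))
  partial <- rise > 0 && (slopeA > 0.05 * rise / step &&
                          slopeB > 0.05 * rise / step)

  if (identical(nStates, "auto")) {
    fits <- lapply(seq_len(maxStates), function(k) fitLogisticSteps(trace, k))
    ok <- !vapply(fits, is.null, logical(1))
    if (!any(ok)) stop("transition fitting failed for every model order")
    bics <- vapply(fits, function(f) if (is.null(f)) Inf else f$bic,
                   numeric(1))
    fit <- fits[[which.min(bics)]]
    bicAttr <- bics
  } else {
    fit <- fitLogisticSteps(trace, as.integer(nStates))
    if (is.null(fit)) stop("transition fitting failed")
    bicAttr <- fit$bic
  }

  p <- fit$par; k <- fit$k
  amp <- p[seq(2, 3 * k + 1, by = 3)]
  mid <- p[seq(3, 3 * k + 1, by = 3)]
  wid <- abs(p[seq(4, 3 * k + 1, by = 3)])
  if (identical(nStates, "auto")) {
    # drop negligible steps a redundant model order parked at ~0 amplitude
    rise <- max(y) - min(y)
    keep <- amp > 0.02 * rise
    if (any(keep)) { amp <- amp[keep]; mid <- mid[keep]; wid <- wid[keep]
                     k <- sum(keep) }
  }
  o <- order(mid)
  mid <- mid[o]; wid <- wid[o]
  kFit <- fit$k   # model order of the parameter vector, pre-filtering
  pre <- vapply(seq_along(mid), function(j)
    logisticStepsEval(p, mid[j] - 3 * wid[j], kFit), numeric(1))
  post <- vapply(seq_along(mid), function(j)
    logisticStepsEval(p, mid[j] + 3 * wid[j], kFit), numeric(1))
  out <- data.frame(cv50 = mid, width = wid,
                    preCentroid = pre, postCentroid = post)
  attr(out, "converged") <- fit$converged
  attr(out, "bic") <- bicAttr
  attr(out, "partial") <- partial
  out
}

#' Detect initial structural compaction before the first transition
#'
#' Collisional activation can first contract a complex (decreased CCS)
#' before unfolding elongates it. The magnitude is the drop from the
#' initial column centroid to the minimum centroid in the pre-transition
#' voltage window; it is called present when it exceeds twice the local
#' centroid noise (estimated from first differences in the same window).
#'
#' @param fp a [CIUFingerprint-class].
#' @param firstCv50 first-transition voltage; detected automatically when
#'   NULL.
#' @return List with `present` (logical), `magnitude` (mobility units),
#'   `noise` (the local noise scale used for the call).
#' @export
detectCompaction <- function(fp, firstCv50 = NULL) {
  trace <- centroidTrace(fp)
  if (is.null(firstCv50)) {
    tr <- detectTransitions(fp, nStates = "auto")
    firstCv50 <- tr$cv50[1] - 2 * tr$width[1]
  }
  pre <- trace[trace$cv < firstCv50, , drop = FALSE]
  if (nrow(pre) < 3) stop("need >= 3 CV points before the first transition")
  magnitude <- max(pre$centroid[1] - min(pre$centroid), 0)
  noise <- sd(diff(pre$centroid)) / sqrt(2)
  list(present = is.finite(noise) && magnitude > 2 * noise,
       magnitude = magnitude, noise = noise)
}

#' Stability shift between two unfolding fingerprints
#'
#' Difference between the first unfolding-transition midpoints of two
#' fingerprints: `cv50(b) - cv50(a)`. Positive when `b` (e.g. a
#' ligand-bound complex) resists unfolding to higher collision voltage
#' than `a`.
#'
#' @param fpA,fpB [CIUFingerprint-class] objects.
#' @param nStates passed to [detectTransitions()] for each fingerprint.
#' @return First-transition CV50 difference in V.
#' @export
stabilityShift <- function(fpA, fpB, nStates = "auto") {
  trA <- detectTransitions(fpA, nStates = nStates)
  trB <- detectTransitions(fpB, nStates = nStates)
  if (nrow(trA) < 1 || nrow(trB) < 1)
    stop("both fingerprints must yield at least one transition")
  trB$cv50[1] - trA$cv50[1]
}
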