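# Bondi van der Waals radii (Angstrom); the package's hard-sphere
# collision radii. The buffer-gas radius is added separately.
.ELEMENT_RADII <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, `NA` = 2.27, K = 2.75,
  MG = 1.73, CA = 2.31, ZN = 1.39, FE = 1.70, SE = 1.90)

#' Hard-sphere collision radii per element
#'
#' Looks up the package's element radius table (Bondi van der Waals
#' radii); unknown elements fall back to the carbon radius with a
#' warning. These are atom radii only — the buffer-gas radius is a
#' separate parameter of the CCS engines.
#'
#' @param symbols character vector of element symbols (case-insensitive).
#' @return Numeric radii in Angstrom.
#' @export
elementRadii <- function(symbols) {
  key <- toupper(trimws(symbols))
  r <- .ELEMENT_RADII[key]
  if (anyNA(r)) {
    warning("unknown element(s) ", paste(unique(key[is.na(r)]), collapse = ", "),
            "; using carbon radius")
    r[is.na(r)] <- .ELEMENT_RADII[["C"]]
  }
  unname(r)
}

# uniform random rotation matrices via quaternions (Shoemake)
randomRotation <- function() {
  u <- runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  w <- q[4]; x <- q[1]; y <- q[2]; z <- q[3]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    nrow = 3, byrow = TRUE)
}

#' Projection-approximation CCS by Monte Carlo
#'
#' The PA cross section is the orientation-averaged shadow area of the
#' union of atom spheres inflated by the buffer-gas radius. For each of
#' `nOrientations` uniformly random rotations the projected disk union's
#' area is estimated by rejection sampling of `nHits` points in the
#' projection's bounding box; the CCS is the mean over orientations with
#' a standard error from the between-orientation variance. PA is a lower
#' bound for concave bodies, where multiple scattering adds momentum
#' transfer that only EHSS captures.
#'
#' @param structure an [AtomicStructure-class].
#' @param gasRadius buffer-gas collision radius, Angstrom (helium ~1.0).
#' @param nOrientations random orientations averaged (>= 1).
#' @param nHits Monte Carlo sample points per orientation.
#' @param seed RNG seed; results are reproducible given the seed.
#' @return A [TheoreticalCCS-class] with `value` and `se` in nm^2.
#' @export
#' @examples
#' s <- AtomicStructure(matrix(0, 1, 3), radii = 2)
#' paCCS(s, gasRadius = 1, nOrientations = 50, nHits = 2000)
#' # analytic: pi * (2 + 1)^2 / 100 nm^2
paCCS <- function(structure, gasRadius = 1.0, nOrientations = 300,
                  nHits = 2000, seed = 1L) {
  stopifnot(is(structure, "AtomicStructure"))
  if (nOrientations < 1) stop("nOrientations must be >= 1")
  set.seed(seed)
  xyz <- structure@coords
  r <- structure@radii + gasRadius
  areas <- vapply(seq_len(nOrientations), function(i) {
    rot <- randomRotation()
    p <- xyz %*% t(rot)
    px <- p[, 1]; py <- p[, 2]
    xlim <- range(px - r, px + r); ylim <- range(py - r, py + r)
    sx <- runif(nHits, xlim[1], xlim[2])
    sy <- runif(nHits, ylim[1], ylim[2])
    # hit if inside any disk
    hit <- logical(nHits)
    for (a in seq_along(px)) {
      miss <- which(!hit)
      if (!length(miss)) break
      hit[miss] <- (sx[miss] - px[a])^2 + (sy[miss] - py[a])^2 <= r[a]^2
    }
    diff(xlim) * diff(ylim) * mean(hit)
  }, numeric(1))
  value <- mean(areas) / 100  # A^2 -> nm^2
  se <- if (nOrientations > 1) sd(areas) / sqrt(nOrientations) / 100 else NA_real_
  new("TheoreticalCCS", method = "PA", value = value, se = se,
      nOrientations = as.integer(nOrientations), nSamples = as.integer(nHits),
      gasRadius = gasRadius, seed = as.integer(seed))
}

# Trace one batch of parallel rays (direction +z) against spheres,
# accumulating specular reflections until escape or the reflection cap.
# Returns 1 - cos(total deflection) per ray.
ehssTraceBatch <- function(origins, centres, radii, maxReflections = 100) {
  nRay <- nrow(origins)
  o <- origins
  d <- matrix(rep(c(0, 0, 1), each = nRay), ncol = 3)
  active <- rep(TRUE, nRay)
  capped <- rep(FALSE, nRay)
  for (refl in seq_len(maxReflections + 1)) {
    idx <- which(active)
    if (!length(idx)) break
    if (refl == maxReflections + 1) { capped[idx] <- TRUE; break }
    tBest <- rep(Inf, length(idx))
    aBest <- rep(NA_integer_, length(idx))
    for (a in seq_len(nrow(centres))) {
      oc <- sweep(o[idx, , drop = FALSE], 2, centres[a, ])
      b <- -rowSums(oc * d[idx, , drop = FALSE])
      cc <- rowSums(oc^2) - radii[a]^2
      disc <- b^2 - cc
      ok <- disc >= 0
      t1 <- b - sqrt(pmax(disc, 0))
      ok <- ok & t1 > 1e-7
      better <- ok & t1 < tBest
      tBest[better] <- t1[better]
      aBest[better] <- a
    }
    hit <- is.finite(tBest)
    esc <- idx[!hit]
    active[esc] <- FALSE
    idxH <- idx[hit]
    if (!length(idxH)) next
    tH <- tBest[hit]; aH <- aBest[hit]
    pnt <- o[idxH, , drop = FALSE] + d[idxH, , drop = FALSE] * tH
    nrm <- pnt - centres[aH, , drop = FALSE]
    nrm <- nrm / sqrt(rowSums(nrm^2))   # renormalize: grazing hits drift
    dotdn <- rowSums(d[idxH, , drop = FALSE] * nrm)
    dNew <- d[idxH, , drop = FALSE] - 2 * dotdn * nrm
    dNew <- dNew / sqrt(rowSums(dNew^2))
    d[idxH, ] <- dNew
    o[idxH, ] <- pnt
  }
  list(w = 1 - d[, 3],  # initial direction was +z, so cos(theta) = dz
       capped = capped)
}

#' Exact-hard-sphere-scattering CCS by Monte Carlo
#'
#' The EHSS cross section is the orientation-averaged momentum-transfer
#' integral for a point buffer-gas particle reflecting specularly off the
#' union of hard atom spheres (radii inflated by the gas radius). For
#' each orientation, parallel trajectories are launched over the
#' projection's bounding box; each is traced through up to
#' `maxReflections` reflections and contributes `1 - cos(theta)` of its
#' total deflection. Multiple scattering in concave pockets makes
#' EHSS >= PA, with equality for convex bodies.
#'
#' @param structure an [AtomicStructure-class].
#' @param gasRadius buffer-gas collision radius, Angstrom.
#' @param nOrientations random orientations averaged.
#' @param nPerOrientation trajectories per orientation (total budget is
#'   the product; default 100 x 500 = 5e4).
#' @param seed RNG seed.
#' @param maxReflections reflection cap; trajectories exceeding it are
#'   discarded and counted in `nDiscarded`.
#' @return A [TheoreticalCCS-class] with `value` and `se` in nm^2.
#' @export
ehssCCS <- function(structure, gasRadius = 1.0, nOrientations = 100,
                    nPerOrientation = 500, seed = 1L,
                    maxReflections = 100) {
  stopifnot(is(structure, "AtomicStructure"))
  if (nOrientations < 1 || nPerOrientation < 1)
    stop("orientation and trajectory counts must be >= 1")
  set.seed(seed)
  xyz <- structure@coords
  r <- structure@radii + gasRadius
  nDisc <- 0L
  sig <- vapply(seq_len(nOrientations), function(i) {
    rot <- randomRotation()
    p <- xyz %*% t(rot)
    px <- p[, 1]; py <- p[, 2]
    xlim <- range(px - r, px + r); ylim <- range(py - r, py + r)
    z0 <- min(p[, 3] - r) - 1
    org <- cbind(runif(nPerOrientation, xlim[1], xlim[2]),
                 runif(nPerOrientation, ylim[1], ylim[2]),
                 z0)
    tr <- ehssTraceBatch(org, p, r, maxReflections)
    keep <- !tr$capped
    nDisc <<- nDisc + sum(tr$capped)
    diff(xlim) * diff(ylim) * mean(tr$w[keep])
  }, numeric(1))
  value <- mean(sig) / 100
  se <- if (nOrientations > 1) sd(sig) / sqrt(nOrientations) / 100 else NA_real_
  new("TheoreticalCCS", method = "EHSS", value = value, se = se,
      nOrientations = as.integer(nOrientations),
      nSamples = as.integer(nPerOrientation),
      gasRadius = gasRadius, seed = as.integer(seed),
      nDiscarded = nDisc)
}

#' RMSD after optimal rigid-body superposition
#'
#' Least-squares (Kabsch) superposition of matched coordinate sets, then
#' the coordinate root-mean-square deviation in Angstrom. The optional
#' percent mode divides by the reference structure's radius of gyration —
#' a package convention for scale-free comparison, clearly nonstandard,
#' reported alongside the absolute value.
#'
#' @param a reference [AtomicStructure-class].
#' @param b mobile [AtomicStructure-class]; same atom count and order.
#' @param percent also report RMSD as a percentage of a's radius of
#'   gyration.
#' @return List with `rmsd` (Angstrom) and, if requested, `percent`.
#' @export
superposeRMSD <- function(a, b, percent = FALSE) {
  stopifnot(is(a, "AtomicStructure"), is(b, "AtomicStructure"))
  if (nrow(a@coords) != nrow(b@coords))
    stop("atom-count mismatch: ", nrow(a@coords), " vs ", nrow(b@coords))
  va <- as.vector(t(a@coords))
  vb <- as.vector(t(b@coords))
  r <- suppressWarnings(bio3d::rmsd(va, vb, fit = TRUE))
  out <- list(rmsd = r)
  if (percent) {
    cen <- colMeans(a@coords)
    rg <- sqrt(mean(rowSums(sweep(a@coords, 2, cen)^2)))
    out$percent <- 100 * r / rg
  }
  out
}

#' Percent contraction of an experimental CCS versus theory
#'
#' `100 * (ccsTheory - ccsExp) / ccsTheory`: positive when the measured
#' (gas-phase) cross section is smaller than the theoretical one computed
#' from a condensed-phase structure, i.e. the ion contracted. Swapping
#' the roles flips the sign.
#'
#' @param ccsExp experimental CCS, nm^2.
#' @param ccsTheory theoretical CCS, nm^2.
#' @return Contraction in percent.
#' @export
#' @examples
#' contractionPercent(57.5, 62.5)  # 8 %
contractionPercent <- function(ccsExp, ccsTheory) {
  if (ccsExp <= 0 || ccsTheory <= 0) stop("CCS values must be positive")
  100 * (ccsTheory - ccsExp) / ccsTheory
}
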