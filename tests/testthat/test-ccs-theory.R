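test_that("PA on analytic bodies: single disk, union identity, dimer limit", {
  one <- AtomicStructure(matrix(0, 1, 3), radii = 2)
  pa <- paCCS(one, gasRadius = 1, nOrientations = 100, nHits = 2000,
              seed = 2)
  expect_lt(abs(pa@value - pi * 9 / 100), 3 * pa@se)

  # two fully overlapping atoms project like one
  two <- AtomicStructure(rbind(c(0, 0, 0), c(0, 0, 0)), radii = 2)
  pa2 <- paCCS(two, gasRadius = 1, nOrientations = 100, nHits = 2000,
               seed = 3)
  expect_lt(abs(pa2@value - pi * 9 / 100), 3 * sqrt(pa@se^2 + pa2@se^2))

  # far-separated dimer of shells: PA approaches twice the single shell
  sA <- simulateToyStructure("sphere-shell", 200, scale = 8, seed = 1)
  sD <- simulateToyStructure("two-sphere-dimer", 400, scale = 8, seed = 1,
                             separation = 120)
  paA <- paCCS(sA, 1, 120, 1500, seed = 6)
  paD <- paCCS(sD, 1, 120, 1500, seed = 7)
  expect_equal(paD@value / paA@value, 2, tolerance = 0.04)
})

test_that("PA matches an independent rasterized-projection oracle within 1%", {
  cl <- randomCluster(n = 50, spread = 6, seed = 12)
  pa <- paCCS(cl, gasRadius = 1, nOrientations = 800, nHits = 3000,
              seed = 5)
  # oracle: fine-grid rasterization of the projected disk union over its
  # own independent random orientations
  set.seed(777)
  r <- collisionRadii(cl) + 1
  areas <- vapply(1:400, function(i) {
    u <- runif(3)
    q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
           sqrt(1 - u[1]) * cos(2 * pi * u[2]),
           sqrt(u[1]) * sin(2 * pi * u[3]),
           sqrt(u[1]) * cos(2 * pi * u[3]))
    w <- q[4]; x <- q[1]; y <- q[2]; z <- q[3]
    rot <- matrix(c(
      1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
      2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
      2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
      3, byrow = TRUE)
    p <- coords(cl) %*% t(rot)
    step <- 0.2
    gx <- seq(min(p[, 1] - r), max(p[, 1] + r), by = step)
    gy <- seq(min(p[, 2] - r), max(p[, 2] + r), by = step)
    grid <- expand.grid(x = gx, y = gy)
    inside <- rep(FALSE, nrow(grid))
    for (a in seq_len(nrow(p)))
      inside <- inside |
        ((grid$x - p[a, 1])^2 + (grid$y - p[a, 2])^2 <= r[a]^2)
    sum(inside) * step^2   # midpoint-rule area
  }, numeric(1))
  oracle <- mean(areas) / 100
  expect_equal(pa@value, oracle, tolerance = 0.01)
})

test_that("EHSS equals PA on a convex body and exceeds it on concave ones", {
  one <- AtomicStructure(matrix(0, 1, 3), radii = 2)
  eh <- ehssCCS(one, gasRadius = 1, nOrientations = 80,
                nPerOrientation = 800, seed = 3)
  expect_lt(abs(eh@value - pi * 9 / 100), 3 * eh@se)

  # momentum transfer can only grow with concavity
  for (s in 1:3) {
    cl <- randomCluster(n = 40, spread = 6, seed = 100 + s)
    pa <- paCCS(cl, 1, 120, 1500, seed = s)
    ehc <- ehssCCS(cl, 1, 60, 400, seed = s + 50)
    expect_gte(ehc@value, pa@value - 3 * sqrt(pa@se^2 + ehc@se^2))
  }

  # a deep cavity: EHSS strictly above PA
  hemi <- hollowHemisphere()
  paH <- paCCS(hemi, 1, 150, 2000, seed = 4)
  ehH <- ehssCCS(hemi, 1, 100, 600, seed = 5)
  expect_gt(ehH@value - paH@value, 5 * sqrt(paH@se^2 + ehH@se^2))
})

test_that("both engines are invariant to rotation/translation and scale quadratically", {
  cl <- randomCluster(n = 30, spread = 5, seed = 8)
  rotate <- function(st, th) {
    R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
                byrow = TRUE)
    AtomicStructure(coords(st) %*% t(R) + 12.3, radii = collisionRadii(st))
  }
  pa0 <- paCCS(cl, 1, 150, 1500, seed = 1)
  pa1 <- paCCS(rotate(cl, 1.1), 1, 150, 1500, seed = 2)
  expect_lt(abs(pa0@value - pa1@value), 3 * sqrt(pa0@se^2 + pa1@se^2))
  eh0 <- ehssCCS(cl, 1, 60, 400, seed = 1)
  eh1 <- ehssCCS(rotate(cl, 1.1), 1, 60, 400, seed = 2)
  expect_lt(abs(eh0@value - eh1@value), 3 * sqrt(eh0@se^2 + eh1@se^2))

  # uniform scaling k doubles lengths: CCS scales by k^2 (gas radius too)
  k <- 2
  clK <- AtomicStructure(coords(cl) * k, radii = collisionRadii(cl) * k)
  paK <- paCCS(clK, gasRadius = k, nOrientations = 150, nHits = 1500,
               seed = 3)
  expect_lt(abs(paK@value - k^2 * pa0@value),
            3 * sqrt(paK@se^2 + (k^2 * pa0@se)^2))
})

test_that("Monte Carlo standard error shrinks roughly as 1/sqrt(n)", {
  cl <- randomCluster(n = 20, spread = 5, seed = 3)
  ses <- vapply(c(50, 200, 800), function(n)
    paCCS(cl, 1, nOrientations = n, nHits = 500, seed = 10)@se, numeric(1))
  expect_true(all(diff(ses) < 0))
  # quadrupling n should roughly halve the SE (allow x1.4-2.9)
  expect_gt(ses[1] / ses[2], 1.4); expect_lt(ses[1] / ses[2], 2.9)
  expect_gt(ses[2] / ses[3], 1.4); expect_lt(ses[2] / ses[3], 2.9)
})

test_that("superposition RMSD: identity, rigid invariance, closed-form displacement", {
  st <- randomCluster(n = 25, spread = 5, seed = 6)
  expect_equal(superposeRMSD(st, st)$rmsd, 0, tolerance = 1e-9)

  th <- 0.8
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
              byrow = TRUE)
  moved <- AtomicStructure(sweep(coords(st) %*% t(R), 2, c(5, -3, 2), "+"),
                           radii = collisionRadii(st))
  expect_equal(superposeRMSD(st, moved)$rmsd, 0, tolerance = 1e-9)

  # one atom displaced by d with the rest fixed: RMSD <= d/sqrt(N), the
  # unfit value; refitting can only reduce it (equality without refit)
  xyz <- coords(st); d <- 0.9
  xyz[1, 1] <- xyz[1, 1] + d
  pert <- AtomicStructure(xyz, radii = collisionRadii(st))
  r <- superposeRMSD(st, pert)$rmsd
  expect_lte(r, d / sqrt(25) + 1e-9)
  expect_gt(r, 0.8 * d / sqrt(25))

  pc <- superposeRMSD(st, pert, percent = TRUE)
  cen <- colMeans(coords(st))
  rg <- sqrt(mean(rowSums(sweep(coords(st), 2, cen)^2)))
  expect_equal(pc$percent, 100 * pc$rmsd / rg, tolerance = 1e-9)
  expect_error(superposeRMSD(st, randomCluster(n = 10)), "mismatch")
})

test_that("contraction percent does the stated arithmetic", {
  expect_equal(contractionPercent(50, 50), 0)
  expect_equal(contractionPercent(57.5, 62.5), 8)
  expect_equal(contractionPercent(62.5, 57.5), -100 * 5 / 57.5)
  expect_error(contractionPercent(-1, 5), "positive")
})

test_that("element radius table covers biomolecular atoms and warns on unknowns", {
  expect_equal(elementRadii(c("C", "N", "O", "S", "H")),
               c(1.70, 1.55, 1.52, 1.80, 1.20))
  expect_warning(r <- elementRadii("Xx"), "unknown")
  expect_equal(r, 1.70)
})
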