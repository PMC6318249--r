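test_that("drift-time correction does the stated arithmetic and guards positivity", {
  expect_identical(correctDriftTime(10, 2500, 0), 10)
  expect_equal(correctDriftTime(10, 2500, 0.001), 9.95)
  expect_error(correctDriftTime(1, 2500, 0.1), "record")
  # round trip through the inverse construction
  cal <- Calibration(0.52, 1.8, edcCoefficient = 1.4)
  td <- driftTimeForCCS(44.3, 17, 74000, cal)
  mzv <- (74000 + 17 * 1.00728) / 17
  tp <- correctDriftTime(td, mzv, 1.4)
  expect_equal(tp, td - 1.4 * sqrt(mzv), tolerance = 1e-12)
})

test_that("calibration fit inverts noiseless synthesis and matches closed-form OLS", {
  cal0 <- Calibration(0.55, 2.0, edcCoefficient = 1.41, gasMass = 4.0026)
  tbl <- synthesizeCalibrants(cal0)
  fit <- fitCalibration(tbl, edcCoefficient = 1.41)
  expect_equal(fit@slope, 0.55, tolerance = 1e-9)
  expect_equal(fit@intercept, 2.0, tolerance = 1e-9)
  expect_gte(fit@rSquared, 0.999)
  expect_identical(fit@nCalibrants, 5L)

  # closed-form simple-regression oracle on the log data
  mzv <- (tbl$mass + tbl$charge * 1.00728) / tbl$charge
  tp <- tbl$driftMs - 1.41 * sqrt(mzv)
  mu <- tbl$mass * 4.0026 / (tbl$mass + 4.0026)
  xl <- log(tp); yl <- log(tbl$ccsRef * sqrt(mu) / tbl$charge)
  slopeHand <- sum((xl - mean(xl)) * (yl - mean(yl))) / sum((xl - mean(xl))^2)
  interceptHand <- mean(yl) - slopeHand * mean(xl)
  expect_equal(fit@slope, slopeHand, tolerance = 1e-12)
  expect_equal(fit@intercept, interceptHand, tolerance = 1e-12)

  expect_error(fitCalibration(tbl[1:2, ], 1.41), ">= 3")
  degenerate <- tbl; degenerate$driftMs <- rep(tbl$driftMs[1], 5)
  degenerate$mass <- rep(tbl$mass[1], 5); degenerate$charge <- rep(12, 5)
  expect_error(fitCalibration(degenerate, 1.41), "degenerate")
})

test_that("the power law behaves: identity case, round trip, monotonicity", {
  # m = 1, C = 0, q/sqrt(mu) = 1 collapses to CCS = t'
  calId <- Calibration(1, 0, edcCoefficient = 0, gasMass = 4.0026)
  mu1 <- 4.0026 * 1 / (1 + 4.0026)  # pick mass so q/sqrt(mu) = 1: q = sqrt(mu)
  q <- sqrt(mu1)
  expect_equal(applyCalibration(7.3, q, 1, calId), 7.3, tolerance = 1e-12)

  # measured round trip for the dimer-scale ion at 17+
  cal0 <- Calibration(0.55, 2.0, edcCoefficient = 1.41)
  tbl <- synthesizeCalibrants(cal0)
  fit <- fitCalibration(tbl, edcCoefficient = 1.41)
  td <- driftTimeForCCS(44.3, 17, 74000, cal0)
  tp <- correctDriftTime(td, (74000 + 17 * 1.00728) / 17, 1.41)
  expect_equal(applyCalibration(tp, 17, 74000, fit), 44.3, tolerance = 1e-6)

  # CCS strictly increasing in t' (m > 0) and in q at fixed t'
  tgrid <- seq(2, 20, length.out = 50)
  ccs <- applyCalibration(tgrid, 16, 74000, cal0)
  expect_true(all(diff(ccs) > 0))
  ccsByQ <- vapply(15:20, function(qq)
    applyCalibration(8, qq, 74000, cal0), numeric(1))
  expect_true(all(diff(ccsByQ) > 0))
})

test_that("ATD mapping preserves profile shape and round-trips the apex CCS", {
  cal0 <- Calibration(0.55, 0.5, edcCoefficient = 0.05)
  tdApex <- driftTimeForCCS(44.3, 17, 74000, cal0)
  td <- seq(tdApex - 1.5, tdApex + 1.5, length.out = 301)
  inten <- dnorm(td, tdApex, 0.35)
  d <- ccsDistributionFromATD(td, inten, 17, 74000, cal0)
  expect_s4_class(d, "CCSDistribution")
  expect_true(all(diff(ccsValues(d)) > 0))
  expect_equal(ccsValues(d)[which.max(intensity(d))], 44.3,
               tolerance = 1e-6)
  expect_error(ccsDistributionFromATD(numeric(0), numeric(0), 17, 74000,
                                      cal0), "empty")
})

test_that("CCSD equals the analytic FWHM and recovers generated widths", {
  ax <- seq(20, 70, 0.02)
  unitG <- simulateCCSDistribution(44.3, 1, ccsAxis = ax)
  expect_equal(ccsd(unitG), 2 * sqrt(2 * log(2)), tolerance = 1e-4)
  for (w in c(2.9, 4.6, 5.0)) {
    d <- simulateCCSDistribution(42.2, w / 2.3548, ccsAxis = ax)
    expect_equal(ccsd(d), w, tolerance = 0.02 / w)
  }
  # never dropping below half max inside the grid is flagged
  truncated <- CCSDistribution(seq(40, 44, 0.1),
                               dnorm(seq(40, 44, 0.1), 42, 5))
  expect_error(ccsd(truncated), "half maximum")
})

test_that("conformer decomposition recovers mixture parameters and weight order", {
  ax <- seq(44, 60, 0.05)
  # the two unresolved DNA-bound conformers
  d <- simulateCCSDistribution(c(51.1, 53.3), c(1.0, 1.1), c(0.45, 0.55),
                               ccsAxis = ax)
  fit <- decomposeConformers(d, 2)
  expect_equal(fit$mean, c(51.1, 53.3), tolerance = 0.1 / 51)
  expect_equal(fit$weight, c(0.45, 0.55), tolerance = 0.02)

  # single pure Gaussian: exact
  g <- simulateCCSDistribution(50, 1.3, ccsAxis = ax)
  f1 <- decomposeConformers(g, 1)
  expect_equal(f1$mean, 50, tolerance = 1e-6)
  expect_equal(f1$sigma, 1.3, tolerance = 1e-6)

  # swapping amplitudes swaps the reported weights (means stay sorted)
  dSwap <- simulateCCSDistribution(c(51.1, 53.3), c(1.0, 1.1), c(0.55, 0.45),
                                   ccsAxis = ax)
  fSwap <- decomposeConformers(dSwap, 2)
  expect_equal(fSwap$weight, c(0.55, 0.45), tolerance = 0.02)
})

test_that("charge-averaged CCS of identical per-charge distributions is the single value", {
  ax <- seq(40, 50, 0.02)
  ds <- lapply(16:18, function(z)
    simulateCCSDistribution(44.3, 1.2, ccsAxis = ax, charge = z))
  single <- sum(ax * intensity(ds[[1]])) / sum(intensity(ds[[1]]))
  expect_equal(chargeAveragedCCS(ds), single, tolerance = 1e-12)
})

test_that("calibration JSON round-trips exactly", {
  cal0 <- Calibration(0.55, 2.0, 1.41, 4.0026, 0.9995, 5L)
  path <- withr::local_tempfile(fileext = ".json")
  writeCalibrationJSON(cal0, path)
  cal1 <- readCalibrationJSON(path)
  expect_equal(cal1@slope, cal0@slope)
  expect_equal(cal1@intercept, cal0@intercept)
  expect_equal(cal1@edcCoefficient, cal0@edcCoefficient)
  expect_equal(cal1@gasMass, cal0@gasMass)
})
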