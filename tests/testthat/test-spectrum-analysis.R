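test_that("pickPeaks finds the generated centres and drops close neighbours", {
  ms <- wtLikeSpectrum()
  centres <- pickPeaks(ms, minRelHeight = 0.02, minSeparation = 5)
  gt <- sort(ms@metadata$groundTruth$centre)
  expect_length(centres, 7)
  expect_equal(centres, gt, tolerance = (2 / 6) / min(gt))

  # flat spectrum: nothing to report
  flat <- MassSpectrum(1:100, rep(1, 100))
  expect_length(pickPeaks(flat, 0.5, 1), 0)

  # two peaks closer than minSeparation: only the taller survives,
  # cross-checked against a brute-force maximum scan
  x <- seq(100, 120, 0.01)
  y <- 2 * dnorm(x, 110, 0.5) + 1 * dnorm(x, 111, 0.5)
  two <- MassSpectrum(x, y)
  got <- pickPeaks(two, 0.05, minSeparation = 3)
  expect_length(got, 1)
  expect_equal(got, x[which.max(y)])
})

test_that("a single noiseless Gaussian is recovered essentially exactly", {
  x <- seq(900, 1100, 0.05)
  area <- 7.3; centre <- 1001.00728; sigma <- 1.7
  y <- area / (sigma * sqrt(2 * pi)) * exp(-(x - centre)^2 / (2 * sigma^2))
  fit <- fitMultiGaussian(MassSpectrum(x, y), initialCentres = 1000)
  expect_true(attr(fit, "converged"))
  expect_equal(fit$centre, centre, tolerance = 1e-6)
  expect_equal(fit$sigma, sigma, tolerance = 1e-6)
  expect_equal(fit$area, area, tolerance = 1e-6)
})

test_that("multi-Gaussian fit recovers every generated area when peaks are resolved", {
  ms <- wtLikeSpectrum(10.5)
  centres <- pickPeaks(ms, 0.02, 5)
  fit <- fitMultiGaussian(ms, centres)
  gt <- ms@metadata$groundTruth
  gt <- gt[order(gt$centre), ]
  expect_equal(fit$area, gt$area, tolerance = 5e-3)
  expect_equal(fit$centre, gt$centre, tolerance = 1e-6)
})

test_that("overlapping pair areas match per-component numerical integration", {
  x <- seq(1000, 1060, 0.02)
  y1 <- 3 / (2 * sqrt(2 * pi)) * exp(-(x - 1025)^2 / (2 * 4))
  y2 <- 5 / (2 * sqrt(2 * pi)) * exp(-(x - 1032)^2 / (2 * 4))
  oracle1 <- trapz(x, y1); oracle2 <- trapz(x, y2)
  fit <- fitMultiGaussian(MassSpectrum(x, y1 + y2), c(1025, 1032))
  expect_equal(fit$area[1], oracle1, tolerance = 0.01)
  expect_equal(fit$area[2], oracle2, tolerance = 0.01)
})

test_that("abundance fractions are invariant under uniform intensity rescaling", {
  ms <- wtLikeSpectrum(25.2)
  cand <- monomerDimerCandidates()
  q1 <- deconvoluteSpectrum(ms, cand, labels = c("monomer", "dimer"))$abundance
  scaled <- MassSpectrum(mz(ms), intensity(ms) * 137.5)
  q2 <- deconvoluteSpectrum(scaled, cand, labels = c("monomer", "dimer"))$abundance
  expect_equal(q1$fraction, q2$fraction, tolerance = 1e-9)
})

test_that("charge assignment matches the generator and breaks ties deterministically", {
  ms <- wtLikeSpectrum()
  dec <- deconvoluteSpectrum(ms, monomerDimerCandidates())
  pk <- dec$peaks
  gt <- ms@metadata$groundTruth[order(ms@metadata$groundTruth$centre), ]
  expect_equal(pk$charge, gt$charge)
  expect_equal(pk$species, gt$species)
  expect_setequal(pk$charge[pk$species == "dimer"], 16:19)

  # exact-position peak
  one <- data.frame(centre = (74000 + 17 * 1.00728) / 17, sigma = 1,
                    area = 1, centreSe = NA, species = NA_character_,
                    charge = NA_integer_)
  got <- assignChargeStates(one, data.frame(label = "dimer", mass = 74000),
                            tolerance = 0.5)
  expect_identical(got$charge, 17L)

  # ambiguous peak within tolerance of two hypotheses: enumerate all
  # residuals by hand; smaller |dm/z| wins, then lower z
  cand <- data.frame(label = c("a", "b"), mass = c(20000, 20010))
  peak <- data.frame(centre = (20000 + 10 * 1.00728) / 10 + 0.3, sigma = 1,
                     area = 1, centreSe = NA, species = NA_character_,
                     charge = NA_integer_)
  z <- 1:60
  resid <- rbind(
    data.frame(label = "a", z = z,
               r = abs(peak$centre - (20000 + z * 1.00728) / z)),
    data.frame(label = "b", z = z,
               r = abs(peak$centre - (20010 + z * 1.00728) / z)))
  resid <- resid[order(resid$r, resid$z), ]
  got <- assignChargeStates(peak, cand, tolerance = 2)
  expect_identical(got$species, resid$label[1])
  expect_identical(got$charge, as.integer(resid$z[1]))
})

test_that("neutral-mass deconvolution is exact on noiseless ladders and resolves proteoforms", {
  mass <- 41234.5
  mkPeaks <- function(m, zs) data.frame(
    centre = (m + zs * 1.00728) / zs, sigma = 1, area = 1,
    centreSe = NA, species = "p", charge = as.integer(zs))
  res <- deconvoluteNeutralMass(mkPeaks(mass, 29:31))
  expect_equal(res$mass, mass, tolerance = 1e-12)
  expect_equal(res$sd, 0, tolerance = 1e-9)

  # single charge state: mass returned, spread flagged undefined
  one <- deconvoluteNeutralMass(mkPeaks(mass, 30))
  expect_equal(one$mass, mass, tolerance = 1e-12)
  expect_true(is.na(one$sd))

  # +79.966 ladder separates phospho-proteoforms
  resP <- deconvoluteNeutralMass(mkPeaks(mass + 79.966, 29:31))
  expect_equal(resP$mass - res$mass, 79.966, tolerance = 1e-9)

  # closed-form two-peak solution agrees with the ladder mean:
  # z = (mz2 - mp) / (mz1 - mz2) for adjacent charges z, z+1
  pk <- mkPeaks(mass, 30:31)
  mz1 <- pk$centre[pk$charge == 31]; mz2 <- pk$centre[pk$charge == 30]
  # zSolved is the charge of the lower-m/z (higher-charge) peak mz1
  zSolved <- (mz2 - 1.00728) / (mz2 - mz1)
  mSolved <- zSolved * (mz1 - 1.00728)
  expect_equal(mSolved, deconvoluteNeutralMass(pk)$mass, tolerance = 1e-9)
})

test_that("species quantification reproduces generated fractions and fold changes", {
  cand <- monomerDimerCandidates()
  wt <- deconvoluteSpectrum(wtLikeSpectrum(10.5), cand,
                            labels = c("monomer", "dimer"))$abundance
  mut <- deconvoluteSpectrum(wtLikeSpectrum(25.2), cand,
                             labels = c("monomer", "dimer"))$abundance
  expect_equal(wt$fraction[wt$species == "monomer"], 0.105,
               tolerance = 0.002 / 0.105)
  expect_equal(mut$fraction[mut$species == "monomer"], 0.252,
               tolerance = 0.002 / 0.252)
  fold <- mut$fraction[mut$species == "monomer"] /
    wt$fraction[wt$species == "monomer"]
  expect_equal(fold, 2.4, tolerance = 0.1 / 2.4)
  expect_true(abs(sum(wt$fraction) - 1) < 1e-9)

  # single-species input: fraction 1 by construction
  onlyDimer <- wt[wt$species == "dimer", ]
  pk <- data.frame(centre = 4000, sigma = 1, area = 2, centreSe = NA,
                   species = "dimer", charge = 18L)
  expect_equal(quantifySpecies(pk)$fraction, 1)
  pk$species <- NA_character_
  expect_error(quantifySpecies(pk), "no assigned peaks")
})
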