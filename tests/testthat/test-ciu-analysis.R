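test_that("fingerprint assembly handles identical, ragged and duplicate profiles", {
  prof <- function(cv, mob, int) list(cv = cv, mobility = mob, intensity = int)
  mob <- seq(40, 60, 0.5)
  y <- dnorm(mob, 50, 1.5)
  fp <- buildFingerprint(list(prof(10, mob, y), prof(20, mob, y)))
  expect_equal(intensity(fp)[1, ], intensity(fp)[2, ])
  expect_equal(max(intensity(fp)[1, ]), 1)  # max-normalized

  expect_error(buildFingerprint(list(prof(10, mob, y), prof(10, mob, y))),
               "duplicate")
  expect_error(buildFingerprint(list(prof(10, mob, y))), ">= 2")

  # ragged grids: interpolation onto the union grid preserves integrals
  mobA <- seq(40, 60, 0.5); mobB <- seq(40.25, 60.25, 0.5)
  yA <- dnorm(mobA, 50, 2); yB <- dnorm(mobB, 52, 2)
  fpR <- buildFingerprint(list(prof(10, mobA, yA), prof(20, mobB, yB)),
                          normalize = "none")
  un <- mobilityAxis(fpR)
  intA <- trapz(un, intensity(fpR)[1, ])
  expect_equal(intA, trapz(mobA, yA), tolerance = 0.01)
})

test_that("generator fingerprints survive assembly up to normalization", {
  tr <- unboundCIUTruth()
  fp <- simulateCIUFingerprint(tr, 10:80, seq(38, 70, 0.1), 1.2)
  profiles <- lapply(seq_along(cvAxis(fp)), function(i)
    list(cv = cvAxis(fp)[i], mobility = mobilityAxis(fp),
         intensity = intensity(fp)[i, ]))
  re <- buildFingerprint(profiles, normalize = "sum")
  expect_equal(intensity(re), intensity(fp), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("normalization is idempotent and detection ignores per-column scaling", {
  tr <- unboundCIUTruth()
  fp <- simulateCIUFingerprint(tr, 10:80, seq(38, 70, 0.1), 1.2)
  n1 <- normalizeFingerprint(fp, "max")
  n2 <- normalizeFingerprint(n1, "max")
  expect_identical(intensity(n1), intensity(n2))

  set.seed(2)
  scale <- runif(length(cvAxis(fp)), 0.2, 5)
  scaled <- CIUFingerprint(cvAxis(fp), mobilityAxis(fp),
                           intensity(fp) * scale, normalization = "none")
  t1 <- detectTransitions(fp, nStates = 3)
  t2 <- detectTransitions(scaled, nStates = 3)
  expect_equal(t1$cv50, t2$cv50, tolerance = 1e-6)
})

test_that("transition detection recovers generator midpoints within one CV step", {
  truths <- list(
    unboundCIUTruth(),
    CIUGroundTruth(c(51, 56, 62), c(59, 70), widths = 2),
    CIUGroundTruth(c(45, 54), 50, widths = 3))
  for (tr in truths) {
    fp <- simulateCIUFingerprint(tr, 10:90, seq(38, 72, 0.1), 1.2)
    det <- detectTransitions(fp, nStates = length(tr@midpoints))
    expect_equal(det$cv50, tr@midpoints, tolerance = 1 / min(tr@midpoints))
    expect_true(all(det$postCentroid > det$preCentroid))
  }
})

test_that("BIC model selection finds the three-step profile under mild noise", {
  tr <- unboundCIUTruth()
  hits <- vapply(1:5, function(s) {
    fp <- simulateCIUFingerprint(tr, 10:80, seq(38, 70, 0.1), 1.2,
                                 noiseLevel = 0.02, seed = s)
    nrow(detectTransitions(fp, nStates = "auto"))
  }, numeric(1))
  expect_true(all(hits == 3))
})

test_that("initial compaction is detected when present and not hallucinated", {
  trC <- CIUGroundTruth(c(51, 56, 62), c(59, 70), widths = 2,
                        compaction = 0.8)
  fpC <- simulateCIUFingerprint(trC, 10:90, seq(45, 75, 0.1), 1.2)
  resC <- detectCompaction(fpC, firstCv50 = 55)
  expect_true(resC$present)
  # the ramp completes only at the first midpoint, so the observable dip
  # in the pre-transition window undershoots the generating 0.8 nm^2
  expect_gt(resC$magnitude, 0.4)
  expect_lte(resC$magnitude, 0.8 + 1e-9)

  trN <- CIUGroundTruth(c(51, 56, 62), c(59, 70), widths = 2)
  fpN <- simulateCIUFingerprint(trN, 10:90, seq(45, 75, 0.1), 1.2)
  resN <- detectCompaction(fpN, firstCv50 = 55)
  expect_false(resN$present)
  expect_error(
    detectCompaction(fpN, firstCv50 = min(cvAxis(fpN)) + 1), ">= 3")
})

test_that("stability shift is zero on itself and matches generated midpoint offsets", {
  trU <- unboundCIUTruth()
  fpU <- simulateCIUFingerprint(trU, 10:90, seq(38, 72, 0.1), 1.2)
  expect_equal(stabilityShift(fpU, fpU), 0, tolerance = 0.01)

  trB <- CIUGroundTruth(c(51, 56, 62), c(59, 70), widths = 2)
  fpB <- simulateCIUFingerprint(trB, 10:90, seq(45, 75, 0.1), 1.2)
  expect_equal(stabilityShift(fpU, fpB), 19, tolerance = 1 / 19)

  # invariant to a common rescaling of both mobility axes
  rescale <- function(fp, k) CIUFingerprint(cvAxis(fp), k * mobilityAxis(fp),
                                            intensity(fp),
                                            fp@normalization)
  expect_equal(stabilityShift(rescale(fpU, 1.7), rescale(fpB, 1.7)),
               stabilityShift(fpU, fpB), tolerance = 0.05)
})

test_that("fingerprints with identical terminal conformers share the final plateau", {
  a <- CIUGroundTruth(c(44.3, 50, 61), c(40, 48), widths = 2)
  b <- CIUGroundTruth(c(51, 61), 59, widths = 2)
  fpA <- simulateCIUFingerprint(a, 10:95, seq(38, 72, 0.1), 1.2)
  fpB <- simulateCIUFingerprint(b, 10:95, seq(38, 72, 0.1), 1.2)
  endA <- tail(centroidTrace(fpA)$centroid, 3)
  endB <- tail(centroidTrace(fpB)$centroid, 3)
  expect_equal(mean(endA), mean(endB), tolerance = 0.01)
})

test_that("centroid trace errors on an all-zero voltage column", {
  m <- matrix(1, 3, 4); m[2, ] <- 0
  fp <- CIUFingerprint(1:3, 1:4, m)
  expect_error(centroidTrace(fp), "all-zero")
})
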