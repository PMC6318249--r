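# shared fixtures and small independent oracles

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# integrate a spectrum over a +/- 5 sigma window around a centre
peakAreaByIntegration <- function(ms, centre, sigma) {
  x <- mz(ms); y <- intensity(ms)
  sel <- x >= centre - 5 * sigma & x <= centre + 5 * sigma
  trapz(x[sel], y[sel])
}

# the observed charge-state windows: monomer 11-13+, dimer 16-19+
monomerDimerCandidates <- function(monomerMass = 37000) {
  data.frame(label = c("monomer", "dimer"),
             mass = c(monomerMass, 2 * monomerMass),
             zmin = c(10, 15), zmax = c(14, 20))
}

wtLikeSpectrum <- function(monomerPercent = 10.5, peakSigma = 2,
                           noiseLevel = 0, seed = 1L) {
  simulateMassSpectrum(homodimerSpecies(monomerPercent),
                       mzRange = c(2500, 5200), peakSigma = peakSigma,
                       noiseLevel = noiseLevel, seed = seed)
}

# three-step unfolding truth shaped like the unbound dimer profile
unboundCIUTruth <- function(widths = 2, compaction = 0)
  CIUGroundTruth(c(44.3, 50, 55, 61), c(40, 48, 58), widths = widths,
                 compaction = compaction)

# WT-design titration: p0 = 3 uM, ligand 0.2-6 uM
wtTitrationL0 <- function(n = 8) exp(seq(log(0.2), log(6), length.out = n))

randomCluster <- function(n = 50, spread = 6, seed = 1) {
  set.seed(seed)
  AtomicStructure(matrix(rnorm(3 * n) * spread, ncol = 3), radii = 1.7)
}

# open hollow hemisphere: a deep concave cavity for EHSS > PA checks
hollowHemisphere <- function(n = 120, radius = 10, atomRadius = 1.5,
                             seed = 9) {
  set.seed(seed)
  v <- matrix(rnorm(3 * n), ncol = 3)
  v <- radius * v / sqrt(rowSums(v^2))
  AtomicStructure(v[v[, 3] < 0.2 * radius, , drop = FALSE],
                  radii = atomRadius)
}
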