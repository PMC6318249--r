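# nativeIMMS

Native mass spectrometry lets a protein complex survive electrospray
intact, so a single experiment can report how a transcription-factor
homodimer partitions between monomer and dimer, how tightly it binds its
cognate DNA, how its collision cross section (CCS) and conformational
spread respond to modification, and how much collisional activation it
withstands before unfolding. nativeIMMS is an R package for the full
analysis chain of such a study — aimed at structural mass spectrometrists
who have (or want to simulate) travelling-wave ion mobility (TW-IMS)
data on protein and protein–DNA complexes.

The package implements:

- **Charge-state-envelope deconvolution** — multi-Gaussian fitting of
  native spectra (`fitMultiGaussian()`), charge/species assignment
  within observed charge windows, intact-mass proteoform resolution
  (±79.966 Da phosphorylation ladders) and per-species abundance tables
  (`quantifySpecies()`).
- **TW-IMS CCS calibration** — the empirical power law
  Ω = (q/√μ)·t′ᵐ·exp(C) fitted log–log over calibrant proteins
  (`fitCalibration()`), corrected drift times, CCS distributions, the
  CCSD spread (FWHM, `ccsd()`) and Gaussian conformer decomposition.
- **Dissociation constants from titration** — the closed-form 1:1
  binding ratio I(PL)/I(P) as a function of [P]₀, [L]₀ and K_D
  (`bindingRatio()`), nonlinear K_D fitting in log space (`fitKd()`),
  and relative-affinity arithmetic.
- **Collision-induced unfolding (CIU)** — fingerprint assembly,
  centroid-trace logistic transition detection with BIC model selection
  (`detectTransitions()`), compaction detection and stability shifts.
- **Theoretical CCS** — seeded Monte Carlo projection approximation
  (`paCCS()`) and exact hard sphere scattering (`ehssCCS()`) engines on
  PDB/XYZ structures, Kabsch superposition RMSD, and experiment-versus-
  theory contraction.
- **Synthetic data with ground truth** — generators for every input
  class (spectra, titrations, CIU fingerprints, CCS distributions, toy
  structures), so the whole pipeline is testable without an instrument.

## Worked example

Simulate a reference homodimer spectrum in which 10.5% of the signal is
monomer (11+–13+) and 89.5% dimer (16+–19+), deconvolute it back, fit a
dissociation constant from a noiseless titration generated at 37 nM,
and detect the three-step unfolding profile:

```r
library(nativeIMMS)

species <- homodimerSpecies(monomerPercent = 10.5)   # 37 kDa monomer, 74 kDa dimer
ms <- simulateMassSpectrum(species, mzRange = c(2500, 5200), peakSigma = 2)
cand <- data.frame(label = c("monomer", "dimer"), mass = c(37000, 74000),
                   zmin = c(10, 15), zmax = c(14, 20))
dec <- deconvoluteSpectrum(ms, cand, labels = c("monomer", "dimer"))
dec$abundance
#>   species  area fraction
#> 1 monomer 0.105    0.105
#> 2   dimer 0.895    0.895

ts <- simulateTitrationSeries(kdNM = 37, p0 = 3,
                              l0 = exp(seq(log(0.2), log(6), length.out = 8)))
fitKd(ts)
#> BindingFit: K_D = 37 +/- 1.3e-15 nM (n = 8, residual norm 7.94e-15)
relativeAffinity(37, 111)
#> [1] 33.33333

tr <- CIUGroundTruth(c(44.3, 50, 55, 61), midpoints = c(40, 48, 58), widths = 2)
fp <- simulateCIUFingerprint(tr, seq(10, 90, 1), seq(38, 72, 0.1), peakSigma = 1.2)
detectTransitions(fp, nStates = 3)
#>   cv50 width preCentroid postCentroid
#> 1   40     2       44.57        51.09
#> 2   48     2       48.71        55.47
#> 3   58     2       54.67        60.71
```

The abundance table recovers the generated monomer fraction exactly; the
K_D refit is the identity on noiseless data; the detector returns the
three generating transition midpoints (40/48/58 V) to machine precision
on this noiseless 1-V grid.

A batch surface with the same capabilities is available through
`runSubcommand()` (subcommands `simulate`, `fit-spectrum`, `calibrate`,
`ccs-dist`, `kd-fit`, `ciu`, `ccs-calc`, `report`) and a thin CLI
wrapper in `inst/scripts/nativeimms`.

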