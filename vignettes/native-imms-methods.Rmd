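---
title: "Models and methods behind nativeIMMS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nativeIMMS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nativeIMMS)
```

nativeIMMS implements the complete analysis chain of a native ion
mobility-mass spectrometry (IM-MS) study of a protein-DNA system: intact
charge-state-envelope deconvolution with species quantification,
travelling-wave ion mobility (TW-IMS) collision cross section (CCS)
calibration, titration-based dissociation-constant determination,
collision-induced unfolding (CIU) fingerprint analysis, and hard-sphere
theoretical CCS computation from atomic coordinates. Because no
instrument is attached, a first-class synthetic-data module emulates
every input with known ground truth; every downstream stage is validated
against that ground truth or against closed-form oracles.

## Spectrum model and deconvolution

A native electrospray spectrum of a species of neutral mass $M$ at
charge $z$ shows a peak at $m/z = (M + z\,m_p)/z$ with $m_p = 1.00728$
Da. The generator (`simulateMassSpectrum()`) sums Gaussian peaks over
species, charge states and proteoforms; within a species the envelope
area is split equally across its charge states, and across proteoforms
by the stated fractions, so a species' integrated envelope is exactly
proportional to its relative abundance. Only protonation is modelled —
these are positive-mode native spectra — and noise is additive Gaussian
on intensity with a floor at zero, the simplest model sufficient for
fitting-robustness studies. Isotope structure, salt adduction and
detector saturation are deliberately out of scope.

Deconvolution mirrors standard practice: local-maximum peak picking,
then full-spectrum nonlinear least squares of a sum of Gaussians plus a
single constant baseline (`fitMultiGaussian()`, Levenberg-Marquardt via
minpack.lm), with peak areas $a\sigma\sqrt{2\pi}$. Initialization takes
centres from the peak picker and sigmas from each maximum's half-height
width; up to five restarts with jittered sigmas guard against bad
starts, and a fit that still fails is returned flagged rather than
dropped. Charge-state assignment minimizes the $m/z$ residual over
candidate (species, charge) hypotheses inside per-species charge
windows. The windows matter: a homodimer sits at exactly twice the
monomer mass, so every even-charge dimer peak coincides with a monomer
peak at half the charge, and only the observed charge-state windows
(here 11+ to 13+ for the monomer, 16+ to 19+ for the dimer) disambiguate
them — exactly as an analyst assigns envelopes by eye. Residual ties
break deterministically: smaller $|\Delta m/z|$, then lower charge.

Species fractions sum fitted areas over all assigned charge states; the
monomer:dimer contrast excludes DNA-bound species, and DNA occupancy is
a separate contrast, matching how such panels are reported. Intact
neutral masses come from averaging $z \cdot (m/z) - z\,m_p$ over a
ladder; a +79.966 Da spacing between ladders resolves phosphorylated
proteoforms.

## TW-IMS CCS calibration

Travelling-wave drift times lack a first-principles CCS relation, so
calibrant proteins of known helium-reference CCS anchor an empirical
power law. After removing the mass-dependent time-of-flight residence
($t' = t_d - c_{EDC}\sqrt{m/z}$), the reduced CCS
$\Omega' = \Omega\sqrt{\mu}/q$ is regressed log-log on $t'$, and
unknowns are converted with

$$\Omega = \frac{q}{\sqrt{\mu}}\, t'^{\,m} e^{C},$$

where $\mu = M m_{gas}/(M + m_{gas})$. Two conventions deserve note.
The gas mass entering $\mu$ defaults to helium (4.0026 Da) because the
calibrant reference values are helium CCS values; it is configurable.
The EDC coefficient is instrument-specific and must be supplied; the
synthetic round trips use the same value on both sides. Arrival-time
distributions map to CCS sample-by-sample without Jacobian reweighting
(the common TWIMS convention); a `jacobian = TRUE` switch applies the
change-of-variable weight for users who want it.

The spread of a CCS distribution (CCSD) is its full width at half
maximum, measured between the *outermost* crossings of half the global
maximum with linear interpolation — a convention that remains meaningful
for the asymmetric profiles of partially resolved conformer mixtures.
Overlapping conformer families are separated by least-squares Gaussian
mixture fitting (`decomposeConformers()`), initialized from
intensity-weighted quantiles and reported sorted by mean.

## Titration model for the dissociation constant

For 1:1 binding at total protein concentration $[P]_0$ and ligand
$[L]_0$, the mass-balance quadratic yields the bound/unbound intensity
ratio in closed form:

$$\frac{I(PL)}{I(P)} = \frac{1}{2}\left(-1 - \frac{[P]_0}{K_D} +
\frac{[L]_0}{K_D} + \sqrt{4\frac{[L]_0}{K_D} +
\left(\frac{[L]_0}{K_D} - \frac{[P]_0}{K_D} - 1\right)^2}\,\right).$$

The $I(P)$ denominator is the unbound *dimer* area only — monomer
signal never enters the ratio. All concentrations are converted to nM
before division, since these experiments mix micromolar protein and
ligand with nanomolar $K_D$. `fitKd()` optimizes $\log K_D$ (so the
optimizer cannot reach negative constants) by Levenberg-Marquardt;
damping matters here because in the saturated low-$K_D$ limit the ratio
approaches $[L]_0/([P]_0 - [L]_0)$ independently of $K_D$ and a plain
Gauss-Newton step becomes singular. The default start is the geometric
mean of $[P]_0$ and the smallest nonzero $[L]_0$. Because the provenance
of published uncertainty values of this kind is typically unstated,
the fit reports both the asymptotic (delta-method) standard error and an
optional seeded bootstrap over titration points; neither is asserted
against any published value. Relative affinity of a variant versus a
reference is $100\,K_D^{ref}/K_D^{test}$, rounded only at presentation.

## CIU fingerprints and transition detection

A CIU experiment isolates one charge state and steps the collision
voltage, recording a mobility profile at each step. The generator
models $K$ transitions among $K+1$ conformers whose occupancies hand
over via logistic functions of voltage; each voltage column is a
Gaussian centred on the occupancy-weighted conformer centroid and
normalized to unit sum. An optional initial compaction lowers the
native centroid, ramped linearly from the lowest voltage to the first
midpoint — mimicking the slight contraction some complexes show before
unfolding. Note the occupancy algebra makes the exact centroid trace a
constant plus a sum of logistic steps, which is precisely the model the
detector fits.

`detectTransitions()` is the package's method of record: it fits the
column-centroid trace with a constant plus rising logistic steps, one
step per transition, the midpoint being the CV50. This
centroid-logistic statistic was chosen over basis-vector CIU50 fitting
because it is simpler, fully specified, and sufficient to recover
transition voltages on the synthetic conditions used here. The number
of steps is chosen by BIC between one and four states when automatic.
Two numerical guards keep the selection honest: the RSS entering BIC is
floored at a $10^{-6}$ fraction of the trace rise (otherwise
machine-precision residue on noiseless traces rewards overfitting), and
steps whose fitted amplitude is below 2% of the trace rise are treated
as parking positions of a redundant model order and dropped.
Compaction is called present when the pre-transition centroid dip
exceeds twice the local centroid noise — a package choice, since the
underlying effect is only ever described qualitatively as marginal.
Synthetic tests use 1-V collision-voltage grids and quote recovered
voltages to within one grid step. Stability comparisons subtract first-
transition CV50s (`stabilityShift()`).

## Hard-sphere theoretical CCS

Two classical estimators connect atomic structures to measurable cross
sections. The projection approximation (PA) is the orientation-averaged
shadow area of the union of atom spheres inflated by the buffer-gas
radius, estimated by rejection sampling in each projection's bounding
box. Exact hard sphere scattering (EHSS) launches parallel trajectories
at each orientation, follows specular reflections (up to a 100-reflection
cap; capped trajectories are discarded and counted), and accumulates the
momentum-transfer weight $1 - \cos\theta$ of the total deflection. For
a convex body EHSS equals PA; concave pockets can only add momentum
transfer, so EHSS $\ge$ PA — a property the tests check on random
clusters and on a hollow-hemisphere cavity body. Both engines report
the between-orientation Monte Carlo standard error and are seeded. One
numerical detail: reflected directions and sphere normals are explicitly
renormalized each bounce, because grazing hits otherwise accumulate
floating-point drift that compounds exponentially for trajectories
trapped in deep cavities.

Atom radii default to the Bondi van der Waals table with a configurable
helium gas radius of 1.0 Å; these are package conventions, since
hard-sphere parameter sets vary between implementations. Default
budgets (PA 300 orientations × 2000 hits, EHSS 100 × 500) resolve a
50-atom body to well under 1% on a single CPU in seconds.

Structural comparison uses least-squares rigid-body superposition
(Kabsch, via bio3d) and reports RMSD in Å. A percent mode divides by
the reference radius of gyration; percent RMSD has no standard
definition, so the absolute value is primary and the normalization is
documented as a package convention.

## Synthetic study conditions

The default scenarios encode the study design the package is built
around: a partially dissociating homodimer (monomer 11+ to 13+, dimer
16+ to 19+, with a DNA-bound dimer at 18+ to 20+ where relevant),
reference and variant monomer percentages of 10.5 and 25.2, a titration
of 3 µM protein against 0.2-6 µM duplex DNA at dissociation constants
between 37 and 424 nM, CCS distribution widths of 2.9-5.0 nm², a
three-step unfolding profile at 40/48/58 V for the unbound dimer and a
first transition at 59 V for the DNA-bound complex. Construct masses
are not part of that design, so generators take the neutral mass as a
free parameter; the scenario default of 37 kDa is representative of a
~330-residue DNA-binding construct, and the dimer is exactly twice it.
The DNA ligand is likewise configuration — the κB-type oligomer can be
supplied as a 20- or 21-mer, annealed or single-stranded, and nothing
is hard-coded. Ground truth is always the parameter actually passed,
never a literature value.

What the generators do *not* emulate bounds what passing tests show
about real data: no isotope fine structure, no salt adducts, no
detector saturation, no realistic TWIMS field physics, and Gaussian
noise only. Recovery of ground truth here demonstrates correctness of
the estimators, not robustness to every instrumental artefact.

## Problem sizes and reproducibility

Test and acceptance runs use deliberately modest sizes chosen as
realistic desk-scale analyses: spectra of ~8000 grid points (peak σ = 2
Da/e), 8-point titrations, 81-voltage × 321-bin fingerprints, Monte
Carlo CCS budgets of order $10^5$ samples. Every stochastic routine
takes an explicit seed and is bit-reproducible given it; zero-noise
generator paths are deterministic regardless of seed. The
`runSubcommand()` pipeline serializes each run's configuration and seed
beside its outputs, so identical configs give byte-identical artifacts.

## Known limitations

Single-constant baselines suffice for the synthetic conditions but not
for sloping chemical backgrounds; the binding model is strict 1:1 with
no ESI response-factor correction between bound and free species; CIU
detection assumes the trace plateaus at both ends and flags partial
profiles rather than extrapolating; the trajectory method and
higher-order CCS models (PSA, SEDI) are intentionally absent; and
nitrogen-to-helium CCS conversion beyond the calibration transform is
out of scope.
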