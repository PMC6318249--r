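Package: nativeIMMS
Title: Native Ion Mobility-Mass Spectrometry Analysis of Protein-DNA Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for native ion mobility-mass spectrometry (IM-MS) studies of
    protein complexes and their ligand interactions: multi-Gaussian deconvolution
    of native electrospray charge-state envelopes with species quantification and
    intact-mass proteoform resolution; travelling-wave ion mobility (TW-IMS)
    collision cross section (CCS) calibration via the empirical power law,
    CCS distributions, CCSD (FWHM) and conformer decomposition; dissociation
    constant determination from bound/unbound peak-area titrations; collision-
    induced unfolding (CIU) fingerprint construction, transition detection and
    stability comparison; theoretical CCS from atomic coordinates by the
    projection approximation and exact hard sphere scattering; and a synthetic
    data module that emulates every input class with known ground truth so the
    full pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    minpack.lm,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
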