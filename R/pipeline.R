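#' Run a named pipeline stage from a configuration list
#'
#' The package's batch surface: each subcommand is a thin recipe over the
#' exported functions, reading and writing the CSV/JSON formats the
#' modules define. Every stochastic stage takes a `seed`, and the full
#' configuration (with the seed) is serialized next to each output, so a
#' run is reproducible from its artifacts alone. A stage that ends with a
#' flagged non-convergence raises an error unless `permissive = TRUE` in
#' the config.
#'
#' Subcommands and their main config fields:
#' \describe{
#'   \item{simulate}{`what` ("spectrum", "titration", "ciu"), generator
#'     parameters, `out` prefix. Writes data CSV + ground-truth JSON.}
#'   \item{fit-spectrum}{`spectrum` CSV, `species` data.frame (label,
#'     mass, zmin, zmax), optional `labels`; writes an abundance table.}
#'   \item{calibrate}{`calibrants` CSV, `edcCoefficient`, `gasMass`;
#'     writes a calibration JSON.}
#'   \item{ccs-dist}{`atd` CSV (driftMs,intensity), `calibration` JSON,
#'     `charge`, `mass`; writes the CCS distribution + its CCSD.}
#'   \item{kd-fit}{`titration` CSV, `p0`; writes the K_D fit report.}
#'   \item{ciu}{`ciu` CSV, optional `nStates`; writes detected
#'     transitions.}
#'   \item{ccs-calc}{`structure` (PDB or XYZ), `method` ("PA"/"EHSS"),
#'     engine budgets; writes the Monte Carlo CCS estimate.}
#'   \item{report}{end-to-end synthetic scenario: simulates reference and
#'     variant spectra plus titrations, deconvolutes and fits both, and
#'     writes one JSON with monomer/dimer percentages, K_D values and
#'     relative affinity.}
#' }
#'
#' @param name subcommand name (see above).
#' @param config named list of parameters; `out` is the output path
#'   prefix (default "nativeimms_run").
#' @return List of result objects, invisibly for file-writing commands;
#'   the written paths are in `$files`.
#' @export
runSubcommand <- function(name, config = list()) {
  name <- match.arg(name, c("simulate", "fit-spectrum", "calibrate",
                            "ccs-dist", "kd-fit", "ciu", "ccs-calc",
                            "report"))
  out <- config$out %||% "nativeimms_run"
  seed <- as.integer(config$seed %||% 1L)
  permissive <- isTRUE(config$permissive)
  message("[nativeIMMS] ", name, " (seed ", seed, ")")

  files <- character(0)
  sidecar <- function(x, suffix) {
    p <- paste0(out, suffix)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
    files <<- c(files, p)
    p
  }
  checkConverged <- function(flag, what) {
    if (!flag && !permissive)
      stop(what, " did not converge (rerun with permissive = TRUE ",
           "to keep the flagged result)")
    if (!flag) message("[nativeIMMS] WARNING: ", what, " flagged non-converged")
  }

  result <- switch(name,
    "simulate" = {
      what <- match.arg(config$what, c("spectrum", "titration", "ciu"))
      if (what == "spectrum") {
        species <- config$species %||%
          homodimerSpecies(config$monomerPercent %||% 10.5)
        ms <- simulateMassSpectrum(
          species,
          mzRange = config$mzRange %||% c(2500, 5200),
          peakSigma = config$peakSigma %||% 2,
          noiseLevel = config$noiseLevel %||% 0, seed = seed)
        files <- c(files, writeSpectrumCSV(ms, paste0(out, "_spectrum.csv")))
        sidecar(ms@metadata["abundanceFractions"], "_truth.json")
        ms
      } else if (what == "titration") {
        ts <- simulateTitrationSeries(
          kdNM = config$kdNM %||% 37, p0 = config$p0 %||% 3,
          l0 = config$l0 %||% c(0.2, 0.5, 1, 2, 3, 4, 5, 6),
          noiseSd = config$noiseSd %||% 0, seed = seed)
        files <- c(files, writeTitrationCSV(ts, paste0(out, "_titration.csv")))
        sidecar(list(kdNM = config$kdNM %||% 37, p0 = ts@p0), "_truth.json")
        ts
      } else {
        truth <- config$truth %||%
          CIUGroundTruth(c(44.3, 50, 55, 61), c(40, 48, 58), widths = 2)
        fp <- simulateCIUFingerprint(
          truth, cv = config$cv %||% seq(10, 80, 1),
          ccsAxis = config$ccsAxis %||% seq(38, 70, 0.1),
          peakSigma = config$peakSigma %||% 1.2,
          noiseLevel = config$noiseLevel %||% 0, seed = seed)
        files <- c(files, writeCIUCSV(fp, paste0(out, "_ciu.csv")))
        sidecar(list(midpoints = truth@midpoints,
                     centroids = truth@centroids), "_truth.json")
        fp
      }
    },
    "fit-spectrum" = {
      ms <- readSpectrumCSV(config$spectrum)
      dec <- deconvoluteSpectrum(
        ms, candidateMasses = config$species,
        minRelHeight = config$minRelHeight %||% 0.02,
        minSeparation = config$minSeparation %||% 5,
        tolerance = config$tolerance %||% 2,
        labels = config$labels)
      checkConverged(attr(dec$peaks, "converged"), "multi-Gaussian fit")
      utils::write.csv(dec$abundance, paste0(out, "_abundance.csv"),
                       row.names = FALSE)
      files <- c(files, paste0(out, "_abundance.csv"))
      sidecar(dec$abundance, "_abundance.json")
      dec
    },
    "calibrate" = {
      tab <- readCalibrantsCSV(config$calibrants)
      cal <- fitCalibration(tab, edcCoefficient = config$edcCoefficient,
                            gasMass = config$gasMass %||% 4.0026)
      files <- c(files, writeCalibrationJSON(cal, paste0(out, "_calibration.json")))
      cal
    },
    "ccs-dist" = {
      atd <- readDelim(config$atd, c("driftMs", "intensity"))
      cal <- readCalibrationJSON(config$calibration)
      d <- ccsDistributionFromATD(atd$driftMs, atd$intensity,
                                  q = config$charge, neutralMass = config$mass,
                                  cal = cal)
      utils::write.csv(data.frame(ccs = d@ccs, intensity = d@intensity),
                       paste0(out, "_ccsdist.csv"), row.names = FALSE)
      files <- c(files, paste0(out, "_ccsdist.csv"))
      width <- tryCatch(ccsd(d), error = function(e) NA_real_)
      sidecar(list(charge = config$charge,
                   meanCCS = sum(d@ccs * d@intensity) / sum(d@intensity),
                   ccsd = width), "_ccsd.json")
      d
    },
    "kd-fit" = {
      ts <- readTitrationCSV(config$titration, p0 = config$p0)
      fit <- fitKd(ts, kdInit = config$kdInit,
                   bootstrap = config$bootstrap %||% 0, seed = seed)
      checkConverged(fit@converged, "K_D fit")
      sidecar(list(kd_nM = fit@kd, kd_se_nM = fit@kdSe,
                   residual_norm = fit@residualNorm,
                   n_points = fit@nPoints), "_kdfit.json")
      fit
    },
    "ciu" = {
      fp <- readCIUCSV(config$ciu)
      tr <- detectTransitions(fp, nStates = config$nStates %||% "auto")
      checkConverged(attr(tr, "converged"), "transition fit")
      sidecar(tr, "_transitions.json")
      tr
    },
    "ccs-calc" = {
      st <- if (grepl("\\.pdb$", config$structure, ignore.case = TRUE))
        readPDBStructure(config$structure)
      else readXYZStructure(config$structure)
      method <- match.arg(toupper(config$method %||% "EHSS"), c("PA", "EHSS"))
      res <- if (method == "PA")
        paCCS(st, gasRadius = config$gasRadius %||% 1.0,
              nOrientations = config$nOrientations %||% 300,
              nHits = config$nHits %||% 2000, seed = seed)
      else
        ehssCCS(st, gasRadius = config$gasRadius %||% 1.0,
                nOrientations = config$nOrientations %||% 100,
                nPerOrientation = config$nPerOrientation %||% 500,
                seed = seed)
      sidecar(list(method = res@method, ccs_nm2 = res@value,
                   se_nm2 = res@se, nOrientations = res@nOrientations,
                   nSamples = res@nSamples, gasRadius = res@gasRadius,
                   seed = res@seed), "_ccs.json")
      res
    },
    "report" = {
      scenarioReport(config, seed, checkConverged, sidecar)
    })

  sidecar(c(list(subcommand = name, seed = seed),
            config[!vapply(config, is.object, logical(1))]), "_config.json")
  message("[nativeIMMS] wrote: ", paste(files, collapse = ", "))
  invisible(list(result = result, files = files))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# end-to-end synthetic scenario: reference vs variant monomer/dimer
# spectra and titrations, deconvoluted and fitted back
scenarioReport <- function(config, seed, checkConverged, sidecar) {
  monomerMass <- config$monomerMass %||% 37000
  scen <- config$scenarios %||% list(
    WT = list(monomerPercent = 10.5, kdNM = 37),
    variant = list(monomerPercent = 25.2, kdNM = 111))
  candidates <- data.frame(
    label = c("monomer", "dimer"), mass = c(monomerMass, 2 * monomerMass),
    zmin = c(10, 15), zmax = c(14, 20))
  l0 <- config$l0 %||% c(0.2, 0.5, 1, 2, 3, 4, 5, 6)

  rows <- lapply(names(scen), function(nm) {
    s <- scen[[nm]]
    ms <- simulateMassSpectrum(
      homodimerSpecies(s$monomerPercent, monomerMass = monomerMass),
      mzRange = c(2500, 5200), peakSigma = 2,
      noiseLevel = config$noiseLevel %||% 0, seed = seed)
    dec <- deconvoluteSpectrum(ms, candidates, labels = c("monomer", "dimer"))
    checkConverged(attr(dec$peaks, "converged"),
                   paste0(nm, " spectrum fit"))
    ts <- simulateTitrationSeries(s$kdNM, p0 = config$p0 %||% 3, l0 = l0,
                                  noiseSd = config$noiseSd %||% 0,
                                  seed = seed)
    fit <- fitKd(ts)
    checkConverged(fit@converged, paste0(nm, " K_D fit"))
    ab <- dec$abundance
    list(scenario = nm,
         monomer_percent = 100 * ab$fraction[ab$species == "monomer"],
         dimer_percent = 100 * ab$fraction[ab$species == "dimer"],
         kd_nM = fit@kd, kd_se_nM = fit@kdSe)
  })
  kdRef <- rows[[1]]$kd_nM
  rows <- lapply(rows, function(r) {
    r$relative_affinity_percent <- relativeAffinity(kdRef, r$kd_nM)
    r
  })
  sidecar(rows, "_report.json")
  rows
}
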