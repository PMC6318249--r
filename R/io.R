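#' Read an atomic structure from a PDB file
#'
#' First model only, ATOM/HETATM records, alternate locations other than
#' "A" dropped; hydrogens are kept if present, never added. Collision
#' radii come from the element table (see [elementRadii()]).
#'
#' @param path PDB file path.
#' @param label structure label; defaults to the file name.
#' @return An [AtomicStructure-class].
#' @export
readPDBStructure <- function(path, label = basename(path)) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  keep <- is.na(at$alt) | at$alt %in% c("", "A")
  at <- at[keep, , drop = FALSE]
  el <- at$elesy
  missing <- is.na(el) | !nzchar(trimws(el))
  # fall back to the first letter of the atom name when the element
  # column is absent (common in minimal files)
  el[missing] <- substr(trimws(at$elety[missing]), 1, 1)
  AtomicStructure(cbind(at$x, at$y, at$z), elements = el, label = label)
}

#' Read an atomic structure from an XYZ file
#'
#' Plain XYZ: atom count line, comment line, then `element x y z` rows.
#'
#' @param path XYZ file path.
#' @param label structure label; defaults to the file name.
#' @return An [AtomicStructure-class].
#' @export
readXYZStructure <- function(path, label = basename(path)) {
  lines <- readLines(path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("malformed XYZ: first line must be the atom count")
  if (length(lines) < n + 2)
    stop("malformed XYZ: expected ", n, " atom rows, found ",
         length(lines) - 2)
  rows <- strsplit(trimws(lines[3:(n + 2)]), "\\s+")
  bad <- which(vapply(rows, length, integer(1)) < 4)
  if (length(bad))
    stop("malformed XYZ at line(s) ", paste(bad + 2, collapse = ", "))
  el <- vapply(rows, `[`, character(1), 1)
  xyz <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
  if (any(!is.finite(xyz))) stop("non-numeric coordinates in XYZ file")
  AtomicStructure(xyz, elements = el, label = label)
}

#' Write an atomic structure to an XYZ file
#'
#' @param structure an [AtomicStructure-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeXYZStructure <- function(structure, path) {
  stopifnot(is(structure, "AtomicStructure"))
  xyz <- structure@coords
  lines <- c(
    as.character(nrow(xyz)),
    structure@label,
    sprintf("%s %.6f %.6f %.6f", structure@elements,
            xyz[, 1], xyz[, 2], xyz[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column spectrum CSV
#'
#' Columns `mz`, `intensity` (header required); any further columns are
#' kept as metadata.
#'
#' @param path CSV/TSV path (separator sniffed from the header line).
#' @return A [MassSpectrum-class].
#' @export
readSpectrumCSV <- function(path) {
  tab <- readDelim(path, c("mz", "intensity"))
  o <- order(tab$mz)
  MassSpectrum(tab$mz[o], tab$intensity[o],
               metadata = list(source = path))
}

#' Write a spectrum to a two-column CSV
#' @param spectrum a [MassSpectrum-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSpectrumCSV <- function(spectrum, path) {
  utils::write.csv(data.frame(mz = spectrum@mz,
                              intensity = spectrum@intensity),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a calibrant table CSV
#'
#' Columns: `label`, `mass` (Da), `charge`, `ccsRef` (nm^2, helium
#' reference), `driftMs` (measured drift time, ms).
#'
#' @param path CSV path.
#' @return data.frame suitable for [fitCalibration()].
#' @export
readCalibrantsCSV <- function(path) {
  readDelim(path, c("label", "mass", "charge", "ccsRef", "driftMs"))
}

#' Read a titration CSV
#'
#' Columns `l0_uM` and `ratio`; the protein concentration is a parameter
#' because it is constant across the series.
#'
#' @param path CSV path.
#' @param p0 protein concentration, uM.
#' @return A [TitrationSeries-class].
#' @export
readTitrationCSV <- function(path, p0) {
  tab <- readDelim(path, c("l0_uM", "ratio"))
  TitrationSeries(p0, tab$l0_uM, tab$ratio)
}

#' Write a titration series CSV
#' @param series a [TitrationSeries-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTitrationCSV <- function(series, path) {
  utils::write.csv(data.frame(l0_uM = series@l0, ratio = series@ratio),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a long-format CIU CSV
#'
#' Columns `cv`, `mobility` (or `ccs`), `intensity`; one row per grid
#' cell. Ragged mobility grids per voltage are allowed and re-gridded.
#'
#' @param path CSV path.
#' @param normalize normalization applied after assembly (see
#'   [buildFingerprint()]).
#' @return A [CIUFingerprint-class].
#' @export
readCIUCSV <- function(path, normalize = "max") {
  tab <- utils::read.csv(path, check.names = FALSE)
  if ("ccs" %in% names(tab) && !"mobility" %in% names(tab))
    names(tab)[names(tab) == "ccs"] <- "mobility"
  need <- c("cv", "mobility", "intensity")
  if (!all(need %in% names(tab)))
    stop("CIU CSV needs columns cv, mobility (or ccs), intensity")
  profiles <- lapply(split(tab, tab$cv), function(d) {
    d <- d[order(d$mobility), ]
    list(cv = d$cv[1], mobility = d$mobility, intensity = d$intensity)
  })
  buildFingerprint(profiles, normalize = normalize)
}

#' Write a CIU fingerprint as long-format CSV
#' @param fp a [CIUFingerprint-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCIUCSV <- function(fp, path) {
  long <- expand.grid(mobility = fp@mobility, cv = fp@cv,
                      KEEP.OUT.ATTRS = FALSE)[, c("cv", "mobility")]
  long$intensity <- as.vector(t(fp@intensity))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Store / reload a calibration as JSON
#'
#' @param cal a [Calibration-class].
#' @param path JSON path.
#' @return `writeCalibrationJSON`: `path` invisibly;
#'   `readCalibrationJSON`: the [Calibration-class].
#' @export
writeCalibrationJSON <- function(cal, path) {
  jsonlite::write_json(list(
    slope = cal@slope, intercept = cal@intercept,
    edcCoefficient = cal@edcCoefficient, gasMass = cal@gasMass,
    rSquared = cal@rSquared, nCalibrants = cal@nCalibrants),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCalibrationJSON
#' @export
readCalibrationJSON <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  Calibration(x$slope, x$intercept, x$edcCoefficient, x$gasMass,
              x$rSquared, as.integer(x$nCalibrants))
}

# header-sniffing delimited reader with a line-numbered error surface
readDelim <- function(path, required) {
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                      stringsAsFactors = FALSE),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e)))
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop(path, " (line 1): missing column(s) ",
         paste(missing, collapse = ", "))
  for (col in setdiff(required, "label")) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(tab[[col]]))))
    if (length(bad))
      stop(path, ": non-numeric '", col, "' at data line(s) ",
           paste(bad + 1, collapse = ", "))
    tab[[col]] <- as.numeric(tab[[col]])
  }
  tab
}
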