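#' Construct a Spectrum
#'
#' A `Spectrum` is a centroided peak list plus its acquisition header. Peaks
#' are stored canonically: sorted ascending by m/z, with ties at identical
#' m/z summed on construction, no NA/NaN values, intensities >= 0.
#'
#' Scan numbers are 1-based and strictly increasing in acquisition order
#' within a run. `precursor_charge = 0` denotes an unknown charge (common in
#' MGF), to be resolved later by precursor correction. MS3 scans carry the
#' list of SPS notch m/z values that were co-isolated, and a `parent_scan`
#' pointing at the fragmented spectrum (MS3 -> its MS2; MS2 -> its MS1).
#'
#' @param scan_number positive integer scan identifier, unique per run.
#' @param ms_level 1, 2 or 3.
#' @param mz numeric vector of peak m/z values (Th), all > 0.
#' @param intensity numeric vector of peak intensities, all >= 0.
#' @param retention_time retention time in seconds.
#' @param precursor_mz precursor m/z (Th) for ms_level >= 2.
#' @param precursor_charge integer precursor charge; 0 if unknown.
#' @param isolation_width isolation window width (Th).
#' @param parent_scan scan number of the parent spectrum, NA if unknown.
#' @param sps_mz numeric vector of SPS notch m/z values (MS3 only).
#' @return An object of class `Spectrum`.
#' @export
spectrum <- function(scan_number, ms_level, mz = numeric(), intensity = numeric(),
                     retention_time = 0, precursor_mz = NA_real_,
                     precursor_charge = 0L, isolation_width = 1.6,
                     parent_scan = NA_integer_, sps_mz = numeric()) {
  scan_number <- as.integer(scan_number)
  ms_level <- as.integer(ms_level)
  stopifnot(length(scan_number) == 1L, scan_number >= 1L,
            ms_level %in% 1:3, length(mz) == length(intensity))
  if (anyNA(mz) || anyNA(intensity))
    stop("Spectrum (scan ", scan_number, "): NA/NaN peak values")
  if (length(mz) && (any(mz <= 0) || any(intensity < 0)))
    stop("Spectrum (scan ", scan_number, "): mz must be > 0, intensity >= 0")
  if (!is.na(parent_scan) && as.integer(parent_scan) >= scan_number)
    stop("Spectrum (scan ", scan_number, "): parent_scan must precede scan_number")
  if (ms_level == 3L && length(sps_mz) == 0L)
    stop("Spectrum (scan ", scan_number, "): MS3 scan requires a non-empty SPS notch list")
  # canonicalize: sort, sum exact-duplicate m/z
  if (length(mz)) {
    o <- order(mz)
    mz <- mz[o]; intensity <- intensity[o]
    if (anyDuplicated(mz)) {
      grp <- cumsum(!duplicated(mz))
      intensity <- as.numeric(tapply(intensity, grp, sum))
      mz <- mz[!duplicated(mz)]
    }
  }
  structure(list(
    scan_number = scan_number, ms_level = ms_level,
    retention_time = as.numeric(retention_time),
    precursor_mz = as.numeric(precursor_mz),
    precursor_charge = as.integer(precursor_charge),
    isolation_width = as.numeric(isolation_width),
    parent_scan = as.integer(parent_scan),
    sps_mz = as.numeric(sps_mz),
    mz = as.numeric(mz), intensity = as.numeric(intensity)
  ), class = "Spectrum")
}

#' @export
print.Spectrum <- function(x, ...) {
  cat(sprintf("<Spectrum> scan %d MS%d, %d peaks", x$scan_number,
              x$ms_level, length(x$mz)))
  if (!is.na(x$precursor_mz))
    cat(sprintf(", precursor %.4f (%d+)", x$precursor_mz, x$precursor_charge))
  cat("\n")
  invisible(x)
}

#' Total-ion-current normalization
#'
#' Divides every peak intensity by the spectrum's total ion current so the
#' intensities sum to one. Used when comparing fragment-class yields across
#' spectra acquired at different collision energies.
#'
#' @param spec a [spectrum()].
#' @return A `Spectrum` with normalized intensities; m/z unchanged.
#' @export
tic_normalize <- function(spec) {
  stopifnot(inherits(spec, "Spectrum"))
  tic <- sum(spec$intensity)
  if (!length(spec$intensity) || tic <= 0)
    stop("tic_normalize: degenerate spectrum (scan ", spec$scan_number,
         "): total ion current is zero")
  spec$intensity <- spec$intensity / tic
  spec
}

#' Construct a scan hierarchy
#'
#' A `ScanHierarchy` holds all spectra of a run keyed by scan number, plus
#' the MS3 -> parent-MS2 link table that drives pseudo-spectrum merging.
#' The linkage is derived from each MS3 spectrum's `parent_scan` field and
#' validated: every MS3 scan must resolve to an existing MS2 scan.
#'
#' @param spectra list of [spectrum()] objects.
#' @return An object of class `ScanHierarchy` with elements `spectra`
#'   (named list, names = scan numbers) and `ms3_parent` (named integer
#'   vector, names = MS3 scan numbers).
#' @export
scan_hierarchy <- function(spectra) {
  stopifnot(is.list(spectra))
  if (length(spectra)) {
    stopifnot(all(vapply(spectra, inherits, TRUE, "Spectrum")))
    sn <- vapply(spectra, `[[`, 1L, "scan_number")
    if (anyDuplicated(sn))
      stop("scan_hierarchy: duplicated scan numbers: ",
           paste(sn[duplicated(sn)], collapse = ", "))
    spectra <- spectra[order(sn)]
    sn <- sort(sn)
    names(spectra) <- as.character(sn)
  }
  lvl <- vapply(spectra, `[[`, 1L, "ms_level")
  ms3 <- spectra[lvl == 3L]
  parent <- vapply(ms3, `[[`, 1L, "parent_scan")
  bad <- vapply(ms3, function(s) {
    p <- s$parent_scan
    is.na(p) || !(as.character(p) %in% names(spectra)) ||
      spectra[[as.character(p)]]$ms_level != 2L
  }, TRUE)
  if (any(bad))
    stop("scan_hierarchy: MS3 scans with unresolvable MS2 parent: ",
         paste(vapply(ms3[bad], `[[`, 1L, "scan_number"), collapse = ", "))
  ms3_parent <- as.integer(parent)
  names(ms3_parent) <- names(ms3)
  structure(list(spectra = spectra, ms3_parent = ms3_parent),
            class = "ScanHierarchy")
}

#' @export
print.ScanHierarchy <- function(x, ...) {
  lvl <- vapply(x$spectra, `[[`, 1L, "ms_level")
  cat(sprintf("<ScanHierarchy> %d scans (MS1 %d / MS2 %d / MS3 %d)\n",
              length(x$spectra), sum(lvl == 1), sum(lvl == 2), sum(lvl == 3)))
  invisible(x)
}

#' MS3 -> MS2 scan link table
#'
#' One row per MS3 scan, listing the scan number of its parent MS2 scan,
#' sorted ascending by MS3 scan number. Equivalent to the external link
#' table produced by raw-file metadata extractors in instrument pipelines.
#'
#' @param run a [scan_hierarchy()].
#' @return A `data.table` with integer columns `ms3_scan`, `ms2_scan`.
#' @export
build_scan_link_table <- function(run) {
  stopifnot(inherits(run, "ScanHierarchy"))
  dt <- data.table::data.table(
    ms3_scan = as.integer(names(run$ms3_parent)),
    ms2_scan = as.integer(run$ms3_parent)
  )
  data.table::setorder(dt, ms3_scan)
  dt[]
}

#' Write a scan link table as TSV
#'
#' @param run a [scan_hierarchy()].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_scan_link_table <- function(run, path) {
  data.table::fwrite(build_scan_link_table(run), path, sep = "\t")
  invisible(path)
}

#' @noRd
.spectra_by_level <- function(run, level) {
  run$spectra[vapply(run$spectra, `[[`, 1L, "ms_level") == level]
}
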