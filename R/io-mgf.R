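# MGF dialect: standard BEGIN IONS blocks extended with MSLEVEL=, PARENTSCAN=,
# SPSMZ= (comma-separated notch m/z), and for pseudo-spectra MERGED=,
# SOURCEMS3=, ISOTOPEOFFSET=. MGF has no standard MS3 linkage, so the link
# lives in the header lines rather than an external table.

#' Read a run from MGF or mzML
#'
#' Parses a mass-spectrometry run into a [scan_hierarchy()]. The MGF dialect
#' must carry the scan number (`SCANS=`), MS level (`MSLEVEL=`, defaulting
#' to 2 when absent), precursor (`PEPMASS=`, `CHARGE=`), and, for MS3
#' scans, the parent scan (`PARENTSCAN=`) and SPS notch list (`SPSMZ=`).
#' mzML input is parsed via standard CV terms (see [read_mzml()]).
#'
#' @param path input file.
#' @param format `"mgf"` or `"mzml"`; default guessed from the extension.
#' @return A [scan_hierarchy()] with peaks sorted and MS3 scans linked.
#' @export
read_run <- function(path, format = c("auto", "mgf", "mzml")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mgf = "mgf", mzml = "mzml",
                     stop("read_run: cannot guess format from extension '",
                          ext, "'; pass format="))
  }
  if (!file.exists(path)) stop("read_run: file not found: ", path)
  switch(format, mgf = read_mgf(path), mzml = read_mzml(path))
}

#' @rdname read_run
#' @export
read_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends) || any(ends < begins))
    stop("read_mgf: malformed file (unbalanced BEGIN/END IONS): ", path)
  spectra <- vector("list", length(begins))
  for (i in seq_along(begins)) {
    block <- lines[(begins[i] + 1L):(ends[i] - 1L)]
    is_hdr <- grepl("^[A-Z]+=", block)
    hdr <- block[is_hdr]
    key <- sub("=.*$", "", hdr)
    val <- sub("^[A-Z]+=", "", hdr)
    names(val) <- key
    get <- function(k, default = NA) if (k %in% key) unname(val[[k]]) else default
    scan <- get("SCANS")
    if (is.na(scan))
      stop("read_mgf: spectrum block ", i, " lacks SCANS= header")
    peak_lines <- block[!is_hdr & nzchar(block)]
    if (length(peak_lines)) {
      pk <- utils::read.table(text = peak_lines, col.names = c("mz", "intensity"),
                              colClasses = "numeric")
    } else pk <- data.frame(mz = numeric(), intensity = numeric())
    pepmass <- get("PEPMASS")
    prec_mz <- if (is.na(pepmass)) NA_real_ else
      as.numeric(strsplit(pepmass, "[ \t]+")[[1]][1])
    charge <- get("CHARGE")
    z <- if (is.na(charge)) 0L else as.integer(sub("[+-]$", "", charge))
    sps <- get("SPSMZ")
    sps_mz <- if (is.na(sps) || !nzchar(sps)) numeric() else
      as.numeric(strsplit(sps, ",")[[1]])
    spectra[[i]] <- tryCatch(
      spectrum(
        scan_number = as.integer(scan),
        ms_level = as.integer(get("MSLEVEL", 2L)),
        mz = pk$mz, intensity = pk$intensity,
        retention_time = as.numeric(get("RTINSECONDS", 0)),
        precursor_mz = prec_mz, precursor_charge = z,
        isolation_width = as.numeric(get("ISOLATIONWIDTH", 1.6)),
        parent_scan = as.integer(get("PARENTSCAN", NA)),
        sps_mz = sps_mz
      ),
      error = function(e) stop("read_mgf: scan ", scan, ": ",
                               conditionMessage(e), call. = FALSE))
    if ("MERGED" %in% key) attr(spectra[[i]], "merged") <- val[["MERGED"]] == "1"
    if ("SOURCEMS3" %in% key && nzchar(val[["SOURCEMS3"]]))
      attr(spectra[[i]], "source_ms3") <- as.integer(strsplit(val[["SOURCEMS3"]], ",")[[1]])
  }
  scan_hierarchy(spectra)
}

#' @noRd
.format_mgf_block <- function(s) {
  out <- c("BEGIN IONS",
           sprintf("TITLE=scan=%d", s$scan_number),
           sprintf("SCANS=%d", s$scan_number),
           sprintf("RTINSECONDS=%.4f", s$retention_time),
           sprintf("MSLEVEL=%d", s$ms_level))
  if (!is.na(s$precursor_mz)) {
    out <- c(out, sprintf("PEPMASS=%.6f", s$precursor_mz))
    if (s$precursor_charge > 0L)
      out <- c(out, sprintf("CHARGE=%d+", s$precursor_charge))
    out <- c(out, sprintf("ISOLATIONWIDTH=%.3f", s$isolation_width))
  }
  if (!is.na(s$parent_scan))
    out <- c(out, sprintf("PARENTSCAN=%d", s$parent_scan))
  if (length(s$sps_mz))
    out <- c(out, paste0("SPSMZ=", paste(sprintf("%.6f", s$sps_mz), collapse = ",")))
  if (!is.null(attr(s, "merged")))
    out <- c(out, paste0("MERGED=", as.integer(attr(s, "merged"))))
  if (!is.null(attr(s, "source_ms3")))
    out <- c(out, paste0("SOURCEMS3=", paste(attr(s, "source_ms3"), collapse = ",")))
  if (length(s$mz))
    out <- c(out, sprintf("%.6f %.6f", s$mz, s$intensity))
  c(out, "END IONS", "")
}

#' Write a run or pseudo-spectrum list as MGF
#'
#' Round-trip contract: `read_run(write_mgf(x))` reproduces all header
#' fields exactly and peak values within formatting precision (m/z printed
#' at 1e-6 Th). Pseudo-spectra are written with `MERGED=` and `SOURCEMS3=`
#' headers so merge provenance survives the round trip.
#'
#' @param x a [scan_hierarchy()] or a list of [pseudo_spectrum()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(x, path) {
  if (inherits(x, "ScanHierarchy")) {
    blocks <- lapply(x$spectra, .format_mgf_block)
  } else if (is.list(x) && (length(x) == 0L ||
             all(vapply(x, inherits, TRUE, "PseudoSpectrum")))) {
    blocks <- lapply(x, function(p) .format_mgf_block(.pseudo_as_spectrum(p)))
  } else stop("write_mgf: x must be a ScanHierarchy or list of PseudoSpectrum")
  text <- unlist(blocks)
  if (is.null(text)) text <- character()
  ok <- tryCatch({
    writeLines(text, path); TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("write_mgf: cannot write to ", path)
  invisible(path)
}
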