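# Minimal mzML reader: enough of the PSI standard to recover the scan
# hierarchy — MS levels (MS:1000511), scan times (MS:1000016), precursor
# selected ions (MS:1000744/MS:1000041), isolation windows (MS:1000827),
# SPS notches (one <precursor> per notch on MS3 spectra), parent scans
# (spectrumRef), and 32/64-bit float peak arrays, plain or zlib-compressed.

#' @noRd
.decode_binary <- function(b64, precision, compressed) {
  if (!nzchar(b64)) return(numeric())
  raw <- jsonlite::base64_dec(gsub("[\r\n ]", "", b64))
  if (compressed) raw <- memDecompress(raw, type = "gzip")
  readBin(raw, what = "double", size = precision / 8,
          n = length(raw) / (precision / 8), endian = "little")
}

#' @noRd
.scan_from_id <- function(id) {
  m <- regmatches(id, regexpr("scan=([0-9]+)", id))
  if (!length(m)) return(NA_integer_)
  as.integer(sub("scan=", "", m))
}

#' Read an mzML file into a scan hierarchy
#'
#' @param path mzML file path.
#' @return A [scan_hierarchy()].
#' @export
read_mzml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  nodes <- xml2::xml_find_all(doc, ".//spectrumList/spectrum")
  if (!length(nodes)) stop("read_mzml: no spectra found in ", path)
  spectra <- lapply(nodes, function(nd) {
    id <- xml2::xml_attr(nd, "id")
    scan <- .scan_from_id(id)
    if (is.na(scan)) scan <- as.integer(xml2::xml_attr(nd, "index")) + 1L
    cv <- function(node, acc)
      xml2::xml_attr(xml2::xml_find_first(
        node, sprintf(".//cvParam[@accession='%s']", acc)), "value")
    ms_level <- as.integer(cv(nd, "MS:1000511"))
    if (is.na(ms_level))
      stop("read_mzml: spectrum '", id, "': missing ms level cvParam")
    rt_node <- xml2::xml_find_first(nd, ".//scanList/scan/cvParam[@accession='MS:1000016']")
    rt <- as.numeric(xml2::xml_attr(rt_node, "value"))
    if (!is.na(rt) && identical(xml2::xml_attr(rt_node, "unitName"), "minute"))
      rt <- rt * 60
    precursors <- xml2::xml_find_all(nd, ".//precursorList/precursor")
    prec_mz <- NA_real_; z <- 0L; parent <- NA_integer_
    iso_w <- 1.6; sps <- numeric()
    if (length(precursors)) {
      p1 <- precursors[[1]]
      prec_mz <- as.numeric(cv(p1, "MS:1000744"))
      zv <- cv(p1, "MS:1000041")
      if (!is.na(zv)) z <- as.integer(zv)
      ref <- xml2::xml_attr(p1, "spectrumRef")
      if (!is.na(ref)) parent <- .scan_from_id(ref)
      off <- as.numeric(cv(p1, "MS:1000828"))
      if (!is.na(off)) iso_w <- 2 * off
      if (ms_level == 3L) {
        sps <- vapply(precursors, function(p) {
          t <- as.numeric(cv(p, "MS:1000827"))
          if (is.na(t)) as.numeric(cv(p, "MS:1000744")) else t
        }, 0)
        sps <- sps[!is.na(sps)]
      }
    }
    arrays <- xml2::xml_find_all(nd, ".//binaryDataArrayList/binaryDataArray")
    mz <- intensity <- numeric()
    for (arr in arrays) {
      has <- function(acc) !is.na(xml2::xml_attr(xml2::xml_find_first(
        arr, sprintf(".//cvParam[@accession='%s']", acc)), "name"))
      precision <- if (has("MS:1000521")) 32L else 64L
      compressed <- has("MS:1000574")
      vals <- .decode_binary(xml2::xml_text(
        xml2::xml_find_first(arr, ".//binary")), precision, compressed)
      if (has("MS:1000514")) mz <- vals
      if (has("MS:1000515")) intensity <- vals
    }
    tryCatch(
      spectrum(scan_number = scan, ms_level = ms_level, mz = mz,
               intensity = intensity,
               retention_time = if (is.na(rt)) 0 else rt,
               precursor_mz = prec_mz, precursor_charge = z,
               isolation_width = iso_w, parent_scan = parent, sps_mz = sps),
      error = function(e) stop("read_mzml: scan ", scan, ": ",
                               conditionMessage(e), call. = FALSE))
  })
  scan_hierarchy(spectra)
}
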