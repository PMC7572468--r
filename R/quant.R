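#' Reporter channel definitions
#'
#' Standard monoisotopic reporter-ion m/z values for the 6-plex isobaric
#' tag (channels 126-131). The table is editable for other plexes.
#'
#' @param plex currently `"tmt6"`.
#' @return A `data.table` with columns `channel` (character label) and
#'   `mz`.
#' @export
reporter_channels <- function(plex = "tmt6") {
  switch(plex,
    tmt6 = data.table::data.table(
      channel = c("126", "127", "128", "129", "130", "131"),
      mz = c(126.12773, 127.13108, 128.13444, 129.13779, 130.14114, 131.14450)),
    stop("reporter_channels: unknown plex '", plex, "'"))
}

#' Extract reporter-ion intensities from a spectrum
#'
#' Per channel, the most intense peak within `tol` Th of the channel m/z;
#' 0 when no peak lies in the window. Channel windows must not overlap.
#'
#' @param spec a [spectrum()] (normally an MS3 scan).
#' @param channels a [reporter_channels()] table.
#' @param tol half-window in Th (default 0.003).
#' @return Named numeric vector of intensities, one per channel.
#' @export
extract_reporters <- function(spec, channels = reporter_channels(),
                              tol = 0.003) {
  mzs <- sort(channels$mz)
  if (any(diff(mzs) < 2 * tol))
    stop("extract_reporters: channel windows overlap at tol = ", tol)
  out <- vapply(seq_len(nrow(channels)), function(i) {
    w <- which(abs(spec$mz - channels$mz[i]) <= tol)
    if (!length(w)) 0 else max(spec$intensity[w])
  }, 0)
  stats::setNames(out, channels$channel)
}

#' Attach reporter intensities to accepted GPSMs
#'
#' Each GPSM receives the reporters of the MS3 scan(s) linked to its
#' source MS2 scan, summed channel-wise when several MS3 scans exist.
#' When the MS2 scan has no MS3 partner (plain-MS2 acquisition) the
#' reporters are read from the MS2 scan itself.
#'
#' @param gpsms GPSM `data.table` (with a `scan` column of MS2 scan
#'   numbers).
#' @param run the [scan_hierarchy()] the GPSMs came from.
#' @param channels a [reporter_channels()] table.
#' @param tol extraction half-window (Th).
#' @return The GPSM table with one intensity column per channel
#'   (`I<channel>`).
#' @export
attach_quant <- function(gpsms, run, channels = reporter_channels(),
                         tol = 0.003) {
  link <- build_scan_link_table(run)
  cols <- paste0("I", channels$channel)
  mat <- matrix(0, nrow(gpsms), nrow(channels), dimnames = list(NULL, cols))
  for (i in seq_len(nrow(gpsms))) {
    ms2 <- gpsms$scan[i]
    kids <- link$ms3_scan[link$ms2_scan == ms2]
    src <- if (length(kids)) as.character(kids) else as.character(ms2)
    for (s in src)
      mat[i, ] <- mat[i, ] + extract_reporters(run$spectra[[s]], channels, tol)
  }
  out <- data.table::copy(gpsms)
  out[, (cols) := data.table::as.data.table(mat)]
  out[]
}

#' Propagate GPSM quantification to glycoform, glycosite, and glycan levels
#'
#' A glycoform is the unique combination protein-site-glycan; all its
#' GPSMs (missed cleavages, modification and charge variants) have their
#' channel intensities summed. Glycosite tables sum over the glycoforms
#' of each protein site; glycan tables sum over all glycoforms carrying a
#' given composition. Channel sums are conserved exactly at every level.
#'
#' @param gpsms accepted GPSMs with reporter columns (see
#'   [attach_quant()]); decoys must already be excluded.
#' @param channels a [reporter_channels()] table.
#' @return A list of class `QuantTables` with `data.table`s `glycoform`,
#'   `glycosite`, `glycan`. All-zero-reporter GPSMs are included, counted
#'   in `n_gpsms`, and flagged via `n_zero_gpsms`.
#' @export
propagate <- function(gpsms, channels = reporter_channels()) {
  cols <- paste0("I", channels$channel)
  stopifnot(all(cols %in% names(gpsms)))
  if (any(gpsms$decoy_class != "target"))
    stop("propagate: decoy GPSMs present; filter to accepted targets first")
  g <- data.table::copy(gpsms)
  g[, .zero := rowSums(as.matrix(g[, cols, with = FALSE])) == 0]
  glycoform <- g[, c(lapply(.SD, sum), .(n_gpsms = .N, n_zero_gpsms = sum(.zero))),
                 by = .(protein, site_protein, glycan, hex, hexnac, neuac, fuc),
                 .SDcols = cols]
  data.table::setorder(glycoform, protein, site_protein, glycan)
  glycosite <- glycoform[, c(lapply(.SD, sum), .(n_glycoforms = .N)),
                         by = .(protein, site_protein), .SDcols = cols]
  data.table::setorder(glycosite, protein, site_protein)
  glycan <- glycoform[, c(lapply(.SD, sum), .(n_glycoforms = .N)),
                      by = .(glycan, hex, hexnac, neuac, fuc), .SDcols = cols]
  data.table::setorder(glycan, glycan)
  structure(list(glycoform = glycoform, glycosite = glycosite,
                 glycan = glycan, channels = channels),
            class = "QuantTables")
}

#' @export
print.QuantTables <- function(x, ...) {
  cat(sprintf("<QuantTables> %d glycoforms, %d glycosites, %d glycans\n",
              nrow(x$glycoform), nrow(x$glycosite), nrow(x$glycan)))
  invisible(x)
}

#' Reference-channel ratios
#'
#' Adds per-channel ratio columns `R<channel>` = intensity / intensity of
#' the reference channel.
#'
#' @param tab a quant `data.table` with `I<channel>` columns.
#' @param channels a [reporter_channels()] table.
#' @param reference reference channel label (default `"126"`).
#' @return The table with ratio columns added.
#' @export
channel_ratios <- function(tab, channels = reporter_channels(),
                           reference = "126") {
  stopifnot(reference %in% channels$channel)
  out <- data.table::copy(tab)
  ref <- out[[paste0("I", reference)]]
  for (ch in channels$channel)
    out[, (paste0("R", ch)) := ifelse(ref > 0, get(paste0("I", ch)) / ref, NA_real_)]
  out[]
}

#' Normalize glyco ratios by proteome medians
#'
#' Divides each channel's ratio by the median ratio of the matching
#' channel in a reference proteomics analysis, removing labeling- and
#' loading-induced offsets shared with the proteome.
#'
#' @param tab quant table with `R<channel>` ratio columns.
#' @param proteome_ratios `data.table` with columns `channel`, `ratio`
#'   (one or more rows per channel).
#' @param channels a [reporter_channels()] table.
#' @return The table with `N<channel>` normalized-ratio columns added.
#' @export
normalize_ratios <- function(tab, proteome_ratios,
                             channels = reporter_channels()) {
  out <- data.table::copy(tab)
  med <- proteome_ratios[, .(m = stats::median(ratio)), by = channel]
  for (ch in channels$channel) {
    m <- med$m[med$channel == ch]
    if (!length(m) || !is.finite(m) || m == 0)
      stop("normalize_ratios: no usable proteome median for channel ", ch)
    out[, (paste0("N", ch)) := get(paste0("R", ch)) / m]
  }
  out[]
}

#' Z-score regulation calls
#'
#' Within each condition channel, z = (log2 ratio - mean log2 ratio) / SD
#' across entries; an entry is called regulated when z > 2 or z < -2.
#' Conditions with fewer than 3 finite entries, or zero SD, are flagged
#' and produce NA z-scores.
#'
#' @param tab quant table with normalized-ratio columns `N<channel>` (or
#'   raw `R<channel>` if normalization is skipped).
#' @param condition_channels character vector of channel labels to call.
#' @param ratio_prefix `"N"` (normalized) or `"R"` (raw).
#' @return A `data.table`: one row per (entry, channel) with `z_score`,
#'   `regulated`, `flag`.
#' @export
call_regulation <- function(tab, condition_channels, ratio_prefix = "N") {
  rows <- lapply(condition_channels, function(ch) {
    r <- tab[[paste0(ratio_prefix, ch)]]
    lr <- log2(r)
    ok <- is.finite(lr)
    out <- data.table::data.table(row = seq_len(nrow(tab)), channel = ch,
                                  z_score = NA_real_, regulated = FALSE,
                                  flag = "")
    if (sum(ok) < 3L) { out[, flag := "insufficient"]; return(out) }
    s <- stats::sd(lr[ok])
    if (!is.finite(s) || s == 0) { out[, flag := "zero_sd"]; return(out) }
    z <- (lr - mean(lr[ok])) / s
    out[, z_score := z]
    out[, regulated := is.finite(z) & abs(z) > 2]
    out
  })
  data.table::rbindlist(rows)
}

#' Write the three quant tables as TSV
#'
#' @param qt a `QuantTables` object from [propagate()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Named character vector of paths, invisibly.
#' @export
write_quant_tables <- function(qt, dir, prefix = "quant") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(glycoform = file.path(dir, paste0(prefix, "_glycoform.tsv")),
             glycosite = file.path(dir, paste0(prefix, "_glycosite.tsv")),
             glycan = file.path(dir, paste0(prefix, "_glycan.tsv")))
  for (nm in names(paths)) data.table::fwrite(qt[[nm]], paths[[nm]], sep = "\t")
  invisible(paths)
}
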