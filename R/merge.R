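#' Merge configuration
#'
#' Controls MS2/MS3 fragment merging and monoisotopic precursor correction.
#' The default 1 ppm merge tolerance reflects high-resolution Orbitrap
#' detection of both scan levels; peaks of the same fragment observed in
#' MS2 and MS3 fall well inside it.
#'
#' @param merge_tol_ppm tolerance (ppm) under which peaks are combined.
#' @param combine_rule `"sum"` (MS2 and MS3 sample the same fragment
#'   population) or `"max"` (for sensitivity analyses).
#' @param isotope_search_range integer isotope offsets searched during
#'   precursor correction, default `-2:2` (13C units).
#' @return A list of class `MergeConfig`.
#' @export
merge_config <- function(merge_tol_ppm = 1, combine_rule = c("sum", "max"),
                         isotope_search_range = -2:2) {
  combine_rule <- match.arg(combine_rule)
  stopifnot(merge_tol_ppm > 0)
  structure(list(merge_tol_ppm = merge_tol_ppm, combine_rule = combine_rule,
                 isotope_search_range = as.integer(isotope_search_range)),
            class = "MergeConfig")
}

#' Construct a pseudo-spectrum
#'
#' The merged MS2+MS3 fragment list of one precursor, with corrected
#' precursor m/z. `is_reporter` flags peaks in the reporter-ion region
#' (m/z < 135): they are carried along for quantification but excluded
#' from identification scoring and SPS selection.
#'
#' @param precursor_mz corrected precursor m/z (Th), > 0.
#' @param precursor_charge integer charge (0 = unknown).
#' @param source_ms2 scan number of the MS2 scan.
#' @param source_ms3 integer vector of contributing MS3 scan numbers.
#' @param mz,intensity merged peak vectors, sorted by m/z.
#' @param merged_flag TRUE if any MS3 contributed.
#' @param isotope_offset_applied integer 13C offsets removed from the
#'   reported precursor.
#' @return An object of class `PseudoSpectrum`.
#' @export
pseudo_spectrum <- function(precursor_mz, precursor_charge, source_ms2,
                            source_ms3 = integer(), mz = numeric(),
                            intensity = numeric(), merged_flag = FALSE,
                            isotope_offset_applied = 0L) {
  stopifnot(is.na(precursor_mz) || precursor_mz > 0,
            length(mz) == length(intensity))
  o <- order(mz)
  structure(list(
    precursor_mz = as.numeric(precursor_mz),
    precursor_charge = as.integer(precursor_charge),
    source_ms2 = as.integer(source_ms2),
    source_ms3 = as.integer(source_ms3),
    mz = as.numeric(mz[o]), intensity = as.numeric(intensity[o]),
    is_reporter = as.numeric(mz[o]) < 135,
    merged_flag = isTRUE(merged_flag),
    isotope_offset_applied = as.integer(isotope_offset_applied)
  ), class = "PseudoSpectrum")
}

#' @export
print.PseudoSpectrum <- function(x, ...) {
  cat(sprintf("<PseudoSpectrum> MS2 %d (+%d MS3), %d peaks, precursor %.4f (%d+), offset %d\n",
              x$source_ms2, length(x$source_ms3), length(x$mz),
              x$precursor_mz, x$precursor_charge, x$isotope_offset_applied))
  invisible(x)
}

#' @noRd
.pseudo_as_spectrum <- function(p) {
  s <- spectrum(scan_number = p$source_ms2, ms_level = 2L, mz = p$mz,
                intensity = p$intensity, precursor_mz = p$precursor_mz,
                precursor_charge = p$precursor_charge)
  attr(s, "merged") <- p$merged_flag
  attr(s, "source_ms3") <- p$source_ms3
  s
}

# Single-linkage clustering of pooled, sorted peaks on the ppm graph:
# adjacent peaks whose gap is within tol (relative to the lower m/z) join a
# cluster; each cluster becomes one peak at the intensity-weighted mean m/z.
# Deterministic for pathological near-tolerance chains and independent of
# input order (the pool is sorted first).
#' @noRd
.cluster_peaks <- function(mz, intensity, tol_ppm, rule) {
  if (!length(mz)) return(list(mz = numeric(), intensity = numeric()))
  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]
  gap_ok <- diff(mz) / mz[-length(mz)] * 1e6 <= tol_ppm
  grp <- cumsum(c(TRUE, !gap_ok))
  w <- intensity
  # weighted mean falls back to plain mean for all-zero clusters
  sw <- tapply(w, grp, sum)
  num <- tapply(mz * w, grp, sum)
  cm <- ifelse(sw > 0, num / sw, tapply(mz, grp, mean))
  ci <- if (rule == "sum") tapply(intensity, grp, sum) else tapply(intensity, grp, max)
  list(mz = as.numeric(cm), intensity = as.numeric(ci))
}

#' Merge MS2 and MS3 fragments into a pseudo-spectrum
#'
#' Pools the MS2 peaks with all linked MS3 peaks and combines peaks within
#' the merge tolerance into one (m/z = intensity-weighted mean; intensity
#' summed by default). Under `"sum"` the total intensity of the output
#' equals the total of the inputs, and the result does not depend on the
#' order of `ms3_list`.
#'
#' @param ms2 the MS2 [spectrum()].
#' @param ms3_list list of linked MS3 spectra (may be empty).
#' @param cfg a [merge_config()].
#' @return A [pseudo_spectrum()]; `merged_flag` is TRUE iff `ms3_list` is
#'   non-empty.
#' @export
merge_fragments <- function(ms2, ms3_list = list(), cfg = merge_config()) {
  stopifnot(inherits(ms2, "Spectrum"), ms2$ms_level == 2L)
  for (s in ms3_list)
    if (is.na(s$parent_scan) || s$parent_scan != ms2$scan_number)
      stop("merge_fragments: MS3 scan ", s$scan_number,
           " is not linked to MS2 scan ", ms2$scan_number)
  mz <- c(ms2$mz, unlist(lapply(ms3_list, `[[`, "mz"), use.names = FALSE))
  intensity <- c(ms2$intensity,
                 unlist(lapply(ms3_list, `[[`, "intensity"), use.names = FALSE))
  cl <- .cluster_peaks(mz, intensity, cfg$merge_tol_ppm, cfg$combine_rule)
  pseudo_spectrum(
    precursor_mz = ms2$precursor_mz, precursor_charge = ms2$precursor_charge,
    source_ms2 = ms2$scan_number,
    source_ms3 = vapply(ms3_list, `[[`, 1L, "scan_number"),
    mz = cl$mz, intensity = cl$intensity,
    merged_flag = length(ms3_list) > 0L
  )
}

# Walk an isotope chain in the MS1 context. The monoisotopic peak is the
# leftmost chain member whose left neighbour (one 13C spacing down) is
# absent or below 20% of its intensity — the envelope must rise then fall
# from the monoisotope.
#' @noRd
.find_envelope_start <- function(ms1, center_mz, z, search_range,
                                 match_tol_ppm = 10) {
  spacing <- mass_table()$c13 / z
  near <- function(target) {
    i <- which(abs(ms1$mz - target) / target * 1e6 <= match_tol_ppm)
    if (!length(i)) return(NA_integer_)
    i[which.max(ms1$intensity[i])]
  }
  offs <- sort(search_range)
  cand <- vapply(offs, function(k) near(center_mz + k * spacing), 0L)
  ok <- !is.na(cand)
  if (!any(ok)) return(NULL)
  for (j in seq_along(offs)[ok]) {
    i <- cand[j]
    left <- near(ms1$mz[i] - spacing)
    left_small <- is.na(left) || ms1$intensity[left] < 0.2 * ms1$intensity[i]
    right <- near(ms1$mz[i] + spacing)
    if (left_small && !is.na(right)) {
      return(list(mono_mz = ms1$mz[i], offset = offs[j]))
    }
  }
  NULL
}

#' Re-assign the monoisotopic precursor peak
#'
#' Instruments often isolate a higher isotope of the precursor; the
#' reported m/z is then one or more 13C spacings (1.0033548/z) above the
#' monoisotopic peak. This walks the isotope envelope in the preceding MS1
#' scan within `cfg$isotope_search_range` offsets of the reported
#' precursor, requiring the envelope to rise then fall from the
#' monoisotope, and shifts the precursor to the envelope start. If the
#' charge is unknown (0), it is inferred from the isotope spacing first.
#' With no resolvable envelope the precursor is left unchanged (offset 0)
#' and a warning attribute recorded.
#'
#' @param pseudo a [pseudo_spectrum()].
#' @param ms1_context the MS1 [spectrum()] preceding the source MS2.
#' @param cfg a [merge_config()].
#' @param charge_range charges tried when the precursor charge is unknown.
#' @return The pseudo-spectrum with `precursor_mz`, `precursor_charge`,
#'   and `isotope_offset_applied` updated.
#' @export
correct_precursor <- function(pseudo, ms1_context, cfg = merge_config(),
                              charge_range = 2:6) {
  stopifnot(inherits(pseudo, "PseudoSpectrum"),
            inherits(ms1_context, "Spectrum"))
  if (is.na(pseudo$precursor_mz)) return(pseudo)
  z <- pseudo$precursor_charge
  if (z < 1L) {
    # infer charge: the spacing whose chain around the precursor is longest
    spacing_hits <- vapply(charge_range, function(zz) {
      sp <- mass_table()$c13 / zz
      sum(vapply(-2:2, function(k) {
        t <- pseudo$precursor_mz + k * sp
        any(abs(ms1_context$mz - t) / t * 1e6 <= 10)
      }, TRUE))
    }, 0L)
    if (max(spacing_hits) >= 2L) {
      z <- charge_range[which.max(spacing_hits)]
      pseudo$precursor_charge <- as.integer(z)
    } else {
      attr(pseudo, "warning") <- "charge could not be inferred; precursor unchanged"
      return(pseudo)
    }
  }
  env <- .find_envelope_start(ms1_context, pseudo$precursor_mz, z,
                              cfg$isotope_search_range)
  if (is.null(env)) {
    attr(pseudo, "warning") <- "no isotopic envelope found; precursor unchanged"
    pseudo$isotope_offset_applied <- 0L
    return(pseudo)
  }
  pseudo$precursor_mz <- env$mono_mz
  pseudo$isotope_offset_applied <- as.integer(env$offset)
  pseudo
}

#' Build pseudo-spectra for a whole run
#'
#' One pseudo-spectrum per MS2 scan: fragments of all linked MS3 scans are
#' merged in, and the precursor corrected against the nearest preceding
#' MS1 scan (when one exists). MS2 scans without MS3 partners pass through
#' unmerged with `merged_flag = FALSE` and are searched identically
#' downstream, which is what supports plain-MS2 acquisitions.
#'
#' @param run a [scan_hierarchy()].
#' @param cfg a [merge_config()].
#' @return List of [pseudo_spectrum()] ordered by source MS2 scan number,
#'   with a `merge_report` attribute (`data.table`: ms2_scan, n_ms3,
#'   peaks_in, peaks_out, isotope_offset).
#' @export
build_pseudo_spectra <- function(run, cfg = merge_config()) {
  stopifnot(inherits(run, "ScanHierarchy"))
  ms2 <- .spectra_by_level(run, 2L)
  ms1 <- .spectra_by_level(run, 1L)
  ms1_scans <- as.integer(names(ms1))
  link <- build_scan_link_table(run)
  out <- vector("list", length(ms2))
  rep_rows <- vector("list", length(ms2))
  for (i in seq_along(ms2)) {
    s2 <- ms2[[i]]
    kids <- link$ms3_scan[link$ms2_scan == s2$scan_number]
    ms3_list <- run$spectra[as.character(kids)]
    p <- merge_fragments(s2, ms3_list, cfg)
    prev1 <- ms1_scans[ms1_scans < s2$scan_number]
    if (length(prev1)) {
      p <- correct_precursor(p, ms1[[as.character(max(prev1))]], cfg)
    }
    out[[i]] <- p
    rep_rows[[i]] <- data.table::data.table(
      ms2_scan = s2$scan_number, n_ms3 = length(kids),
      peaks_in = length(s2$mz) + sum(vapply(ms3_list, function(s) length(s$mz), 0L)),
      peaks_out = length(p$mz), isotope_offset = p$isotope_offset_applied)
  }
  ord <- order(vapply(out, `[[`, 1L, "source_ms2"))
  out <- out[ord]
  attr(out, "merge_report") <- data.table::rbindlist(rep_rows[ord])
  out
}

#' Write the per-scan merge report as TSV
#'
#' @param pseudo_list output of [build_pseudo_spectra()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_merge_report <- function(pseudo_list, path) {
  rep <- attr(pseudo_list, "merge_report")
  if (is.null(rep)) stop("write_merge_report: no merge_report attribute")
  data.table::fwrite(rep, path, sep = "\t")
  invisible(path)
}
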