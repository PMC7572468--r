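#' Search configuration
#'
#' Defaults follow common high-resolution practice for intact
#' glycopeptides: 10 ppm precursor and 20 ppm fragment tolerance, 2% total
#' FDR across both decoy levels, equal weights for the peptide and glycan
#' subscores. The `"igm"` preset additionally requires PepScore > 7 and
#' GlyScore > 8 (small-database regime where score floors replace
#' FDR-only filtering); the `"dg75"` preset is the plain 2% total-FDR
#' regime.
#'
#' @param precursor_tol_ppm precursor mass tolerance (ppm).
#' @param fragment_tol_ppm fragment mass tolerance (ppm).
#' @param total_fdr total FDR threshold in (0, 1).
#' @param w_pep,w_gly TotalScore weights.
#' @param min_pep_score,min_gly_score optional score floors (NA = none).
#' @param charge_range precursor charges considered.
#' @param scan_range instrument fragment m/z range; theoretical ions
#'   outside it are not counted as observable.
#' @param preset `"none"`, `"igm"` or `"dg75"`.
#' @return A list of class `SearchConfig`.
#' @export
search_config <- function(precursor_tol_ppm = 10, fragment_tol_ppm = 20,
                          total_fdr = 0.02, w_pep = 1, w_gly = 1,
                          min_pep_score = NA_real_, min_gly_score = NA_real_,
                          charge_range = 2:6, scan_range = c(120, 2000),
                          preset = c("none", "igm", "dg75")) {
  preset <- match.arg(preset)
  if (preset == "igm") { min_pep_score <- 7; min_gly_score <- 8 }
  stopifnot(precursor_tol_ppm > 0, fragment_tol_ppm > 0,
            total_fdr > 0, total_fdr < 1, length(scan_range) == 2L,
            scan_range[1] < scan_range[2])
  structure(list(precursor_tol_ppm = precursor_tol_ppm,
                 fragment_tol_ppm = fragment_tol_ppm, total_fdr = total_fdr,
                 w_pep = w_pep, w_gly = w_gly,
                 min_pep_score = min_pep_score, min_gly_score = min_gly_score,
                 charge_range = as.integer(charge_range),
                 scan_range = as.numeric(scan_range), preset = preset),
            class = "SearchConfig")
}

#' Match theoretical ions to spectrum peaks
#'
#' Each theoretical m/z is matched to the nearest peak within the
#' fragment tolerance; one peak may satisfy several ions when it lies
#' within tolerance of each. Reporter-region peaks are excluded.
#'
#' @param mz,intensity spectrum peak vectors (sorted by m/z).
#' @param theo_mz theoretical ion m/z values.
#' @param tol_ppm fragment tolerance (ppm, relative to the theoretical
#'   m/z).
#' @return Logical vector: which theoretical ions found a peak.
#' @export
match_ions <- function(mz, intensity, theo_mz, tol_ppm) {
  if (!length(mz) || !length(theo_mz)) return(rep(FALSE, length(theo_mz)))
  i <- findInterval(theo_mz, mz)
  lo <- pmax(i, 1L); hi <- pmin(i + 1L, length(mz))
  d <- pmin(abs(mz[lo] - theo_mz), abs(mz[hi] - theo_mz))
  d / theo_mz * 1e6 <= tol_ppm
}

#' Binomial-surprisal fragment score
#'
#' Score = -log10 P(X >= k) with X ~ Binomial(n, p-hat), where n is the
#' theoretical ion count, k the matched count, and p-hat the chance that a
#' random peak position falls in one of the n tolerance windows: the
#' summed window widths (2 * tol per ion, in Th) divided by the m/z span
#' of the scored peaks. p-hat is floored at 1e-6 (degenerate spans) and
#' capped at 0.5. A score of 0 is returned when k = 0; the score is
#' strictly increasing in k at fixed n, p-hat.
#'
#' @param k matched ion count.
#' @param n theoretical ion count (> 0).
#' @param p_hat per-ion match probability under the null.
#' @return Non-negative score.
#' @export
binomial_score <- function(k, n, p_hat) {
  stopifnot(n > 0)
  p_hat <- min(max(p_hat, 1e-6), 0.5)
  if (k <= 0) return(0)
  k <- min(k, n)
  -stats::pbinom(k - 1, n, p_hat, lower.tail = FALSE, log.p = TRUE) / log(10)
}

#' @noRd
.null_p <- function(theo_mz, tol_ppm, span) {
  if (!length(theo_mz) || span <= 0) return(1e-6)
  sum(2 * theo_mz * tol_ppm * 1e-6) / span / length(theo_mz)
}

# Theoretical ion table for one candidate against one spectrum.
# b/y ions are considered at 1+ and 2+ (bounded by the precursor charge);
# Y ions, being large, at 1+ .. precursor charge.
#' @noRd
.theoretical_ions <- function(cand, z, masses, label, ion_cache = NULL) {
  key <- paste0(cand$peptide, "|", cand$n_ox, "|", cand$glycan, "|",
                cand$gly_shift, "|", z)
  if (!is.null(ion_cache) && !is.null(ion_cache[[key]])) return(ion_cache[[key]])
  by <- enumerate_by_ions(cand$peptide, masses, label, cand$n_ox)
  yy <- enumerate_y_ions(cand$pep_mass,
                         c(hex = cand$hex, hexnac = cand$hexnac,
                           neuac = cand$neuac, fuc = cand$fuc),
                         masses, decoy_shift = cand$gly_shift)
  zs_by <- seq_len(max(1L, min(z, 2L)))
  zs_y <- seq_len(max(1L, z))
  ions <- data.table::rbindlist(list(
    data.table::CJ(i = seq_len(nrow(by)), z = zs_by)[
      , .(kind = "pep", neutral = by$neutral[i], z = z)],
    data.table::CJ(i = seq_len(nrow(yy)), z = zs_y)[
      , .(kind = "gly", neutral = yy$neutral[i], z = z)]
  ))
  ions[, mz := neutral / z + masses$proton]
  if (!is.null(ion_cache)) ion_cache[[key]] <- ions
  ions
}

#' @noRd
.in_scan_range <- function(ions, scan_range) {
  ions[mz >= scan_range[1] & mz <= scan_range[2]]
}

#' Score one pseudo-spectrum against one candidate
#'
#' @param pseudo a [pseudo_spectrum()].
#' @param cand one candidate row from [build_search_space()].
#' @param cfg a [search_config()].
#' @param masses a [mass_table()].
#' @param label isobaric label used when the space was built.
#' @param ion_cache optional environment reusing theoretical-ion tables.
#' @return A one-row `data.table` of scores (ScoreSet fields).
#' @export
score_candidate <- function(pseudo, cand, cfg = search_config(),
                            masses = mass_table(), label = "TMT6",
                            ion_cache = NULL) {
  keep <- !pseudo$is_reporter
  mzv <- pseudo$mz[keep]; inv <- pseudo$intensity[keep]
  z <- max(1L, pseudo$precursor_charge)
  ions <- .in_scan_range(.theoretical_ions(cand, z, masses, label, ion_cache),
                         cfg$scan_range)
  span <- if (length(mzv) > 1L) max(mzv) - min(mzv) else 0
  hit <- match_ions(mzv, inv, ions$mz, cfg$fragment_tol_ppm)
  pep_idx <- ions$kind == "pep"
  n_pep <- sum(pep_idx); n_gly <- sum(!pep_idx)
  k_pep <- sum(hit[pep_idx]); k_gly <- sum(hit[!pep_idx])
  p_pep <- .null_p(ions$mz[pep_idx], cfg$fragment_tol_ppm, span)
  p_gly <- .null_p(ions$mz[!pep_idx], cfg$fragment_tol_ppm, span)
  ps <- if (n_pep) binomial_score(k_pep, n_pep, p_pep) else 0
  gs <- if (n_gly) binomial_score(k_gly, n_gly, p_gly) else 0
  data.table::data.table(
    pep_score = ps, gly_score = gs,
    total_score = total_score(ps, gs, cfg),
    pep_ion_ratio = if (n_pep) k_pep / n_pep else 0,
    gly_ion_ratio = if (n_gly) k_gly / n_gly else 0,
    n_matched_by = k_pep, n_matched_y = k_gly)
}

#' Weighted total score
#'
#' @param pep_score,gly_score subscores.
#' @param cfg a [search_config()] carrying the weights.
#' @return `w_pep * pep_score + w_gly * gly_score`.
#' @export
total_score <- function(pep_score, gly_score, cfg = search_config()) {
  cfg$w_pep * pep_score + cfg$w_gly * gly_score
}

#' Two-level target-decoy FDR estimation
#'
#' At every score threshold s: peptide-level FDR_p(s) = #(peptide-decoy
#' GPSMs >= s) / #(target GPSMs >= s), glycan-level FDR_g(s) analogously
#' with glycan decoys (GPSMs whose candidate carries both decoy flags
#' count in both numerators), and total FDR(s) = FDR_p + FDR_g -
#' FDR_p * FDR_g. q-values are the running minimum of total FDR over
#' descending score, hence monotone non-increasing in score.
#'
#' @param gpsms `data.table` with `total_score`, `decoy_class`.
#' @return The table with columns `fdr_pep`, `fdr_gly`, `fdr_total`,
#'   `q_value` added, sorted by descending score.
#' @export
estimate_fdr <- function(gpsms) {
  if (!nrow(gpsms)) return(gpsms)
  g <- data.table::copy(gpsms)
  data.table::setorder(g, -total_score)
  is_t <- g$decoy_class == "target"
  is_p <- g$decoy_class %in% c("pep_decoy", "both")
  is_g <- g$decoy_class %in% c("gly_decoy", "both")
  n_t <- cumsum(is_t); n_p <- cumsum(is_p); n_g <- cumsum(is_g)
  # tied scores share the cumulative counts at the end of their group
  g[, .grp_idx := max(.I), by = total_score]
  idx <- g$.grp_idx
  g[, .grp_idx := NULL]
  fp <- ifelse(n_t[idx] > 0, n_p[idx] / n_t[idx], 1)
  fg <- ifelse(n_t[idx] > 0, n_g[idx] / n_t[idx], 1)
  g[, fdr_pep := fp]
  g[, fdr_gly := fg]
  g[, fdr_total := fdr_pep + fdr_gly - fdr_pep * fdr_gly]
  g[, q_value := rev(cummin(rev(fdr_total)))]
  g[]
}

#' Search a run of pseudo-spectra
#'
#' For every pseudo-spectrum, candidates within the precursor tolerance
#' of the spectrum's neutral mass are scored and the best one kept
#' (rank-1 only; ties broken by smaller neutral-mass delta, then by
#' candidate id). q-values are then assigned over all GPSMs and the
#' accepted set filtered at the total-FDR threshold plus any score
#' floors. Decoy GPSMs are never accepted.
#'
#' @param pseudo_list list of [pseudo_spectrum()].
#' @param index a [build_candidate_index()] over targets + decoys.
#' @param cfg a [search_config()].
#' @param masses a [mass_table()].
#' @param label isobaric label.
#' @return A list of class `SearchResult`: `gpsms` (all rank-1 matches
#'   with q-values), `accepted` (targets passing the filter), `db_round`.
#' @export
search_run <- function(pseudo_list, index, cfg = search_config(),
                       masses = mass_table(), label = "TMT6") {
  if (!inherits(index, "CandidateIndex") || is.null(index$candidates) ||
      !nrow(index$candidates))
    stop("search_run: empty candidate index")
  cand <- index$candidates
  pep_cache <- new.env(parent = emptyenv())   # peptide|n_ox -> b/y neutrals
  gly_cache <- new.env(parent = emptyenv())   # glycan string -> Y deltas
  by_neutrals <- function(pep, n_ox) {
    key <- paste0(pep, "|", n_ox)
    v <- pep_cache[[key]]
    if (is.null(v)) {
      v <- enumerate_by_ions(pep, masses, label, n_ox)$neutral
      pep_cache[[key]] <- v
    }
    v
  }
  y_deltas <- function(glycan, hex, hexnac, neuac, fuc) {
    v <- gly_cache[[glycan]]
    if (is.null(v)) {
      sub <- .sub_compositions(c(hex = hex, hexnac = hexnac,
                                 neuac = neuac, fuc = fuc))
      v <- sort(unique(sub$hex * masses$mono[["hex"]] +
                         sub$hexnac * masses$mono[["hexnac"]] +
                         sub$neuac * masses$mono[["neuac"]] +
                         sub$fuc * masses$mono[["fuc"]]))
      gly_cache[[glycan]] <- v
    }
    v
  }
  rows <- vector("list", length(pseudo_list))
  for (i in seq_along(pseudo_list)) {
    p <- pseudo_list[[i]]
    if (is.na(p$precursor_mz) || p$precursor_charge < 1L) next
    neutral <- p$precursor_charge * (p$precursor_mz - masses$proton)
    r <- .mass_window(index$mass, neutral, cfg$precursor_tol_ppm)
    if (r[2] < r[1]) next
    j_all <- r[1]:r[2]
    mzv <- p$mz[!p$is_reporter]
    span <- if (length(mzv) > 1L) max(mzv) - min(mzv) else 0
    z <- p$precursor_charge
    zs_by <- seq_len(min(z, 2L)); zs_y <- seq_len(z)
    # candidates identical in (peptide, n_ox, glycan, shift) score equally;
    # score once per group, rank-1 tie-break picks the lowest cand_id
    key <- paste0(cand$peptide[j_all], "|", cand$n_ox[j_all], "|",
                  cand$glycan[j_all], "|", cand$gly_shift[j_all])
    first <- !duplicated(key)
    grp <- match(key, key[first])
    ju <- j_all[first]
    nsc <- length(ju)
    ps <- gs <- pr <- gr <- numeric(nsc)
    kp <- ky <- integer(nsc)
    for (u in seq_len(nsc)) {
      j <- ju[u]
      by <- by_neutrals(cand$peptide[j], cand$n_ox[j])
      dl <- y_deltas(cand$glycan[j], cand$hex[j], cand$hexnac[j],
                     cand$neuac[j], cand$fuc[j])
      sh <- cand$gly_shift[j]
      yn <- cand$pep_mass[j] + dl + ifelse(dl == 0, 0, sh)
      pep_mz <- rep(by, length(zs_by)) / rep(zs_by, each = length(by)) + masses$proton
      gly_mz <- rep(yn, length(zs_y)) / rep(zs_y, each = length(yn)) + masses$proton
      pep_mz <- pep_mz[pep_mz >= cfg$scan_range[1] & pep_mz <= cfg$scan_range[2]]
      gly_mz <- gly_mz[gly_mz >= cfg$scan_range[1] & gly_mz <= cfg$scan_range[2]]
      if (!length(pep_mz) && !length(gly_mz)) next
      hit_p <- match_ions(mzv, NULL, pep_mz, cfg$fragment_tol_ppm)
      hit_g <- match_ions(mzv, NULL, gly_mz, cfg$fragment_tol_ppm)
      kp[u] <- sum(hit_p); ky[u] <- sum(hit_g)
      if (length(pep_mz)) {
        ps[u] <- binomial_score(kp[u], length(pep_mz),
                                .null_p(pep_mz, cfg$fragment_tol_ppm, span))
        pr[u] <- kp[u] / length(pep_mz)
      }
      if (length(gly_mz)) {
        gs[u] <- binomial_score(ky[u], length(gly_mz),
                                .null_p(gly_mz, cfg$fragment_tol_ppm, span))
        gr[u] <- ky[u] / length(gly_mz)
      }
    }
    ts <- cfg$w_pep * ps + cfg$w_gly * gs
    dm <- abs(cand$neutral_mass[j_all] - neutral)
    best <- order(-ts[grp], dm, cand$cand_id[j_all])[1L]
    ub <- grp[best]; jb <- j_all[best]
    rows[[i]] <- data.table::data.table(
      scan = p$source_ms2, precursor_mz = p$precursor_mz, charge = z,
      merged = p$merged_flag, cand_id = cand$cand_id[jb],
      peptide = cand$peptide[jb], protein = cand$protein[jb],
      site = cand$site[jb], site_protein = cand$site_protein[jb],
      n_ox = cand$n_ox[jb], glycan = cand$glycan[jb], hex = cand$hex[jb],
      hexnac = cand$hexnac[jb], neuac = cand$neuac[jb], fuc = cand$fuc[jb],
      neutral_mass = cand$neutral_mass[jb], decoy_class = cand$decoy_class[jb],
      pep_score = ps[ub], gly_score = gs[ub], total_score = ts[ub],
      pep_ion_ratio = pr[ub], gly_ion_ratio = gr[ub],
      n_matched_by = kp[ub], n_matched_y = ky[ub])
  }
  gpsms <- data.table::rbindlist(rows)
  if (nrow(gpsms)) gpsms <- estimate_fdr(gpsms)
  accepted <- .accept_gpsms(gpsms, cfg)
  structure(list(gpsms = gpsms, accepted = accepted, db_round = 1L),
            class = "SearchResult")
}

#' @noRd
.accept_gpsms <- function(gpsms, cfg) {
  if (!nrow(gpsms)) return(gpsms)
  acc <- gpsms[decoy_class == "target" & q_value <= cfg$total_fdr]
  if (!is.na(cfg$min_pep_score)) acc <- acc[pep_score > cfg$min_pep_score]
  if (!is.na(cfg$min_gly_score)) acc <- acc[gly_score > cfg$min_gly_score]
  acc
}

#' @export
print.SearchResult <- function(x, ...) {
  cat(sprintf("<SearchResult> round %d: %d GPSMs, %d accepted\n",
              x$db_round, nrow(x$gpsms), nrow(x$accepted)))
  invisible(x)
}

#' Two-step database search
#'
#' Round 1 searches all pseudo-spectra against the full database at the
#' configured total FDR. The round-2 database consists of exactly the
#' proteins with at least one accepted round-1 GPSM; all spectra are then
#' re-searched against this reduced space (FDR controlled per round).
#' The smaller decoy space of round 2 rescues low-stoichiometry
#' glycoforms on proteins already identified that fell just beyond the
#' round-1 threshold.
#'
#' @param pseudo_list list of [pseudo_spectrum()].
#' @param proteins full protein database (`data.table` with `accession`,
#'   `sequence`).
#' @param glycans glycan library.
#' @param cfg a [search_config()].
#' @param masses a [mass_table()].
#' @param label isobaric label.
#' @return A `SearchResult` with `db_round = 2`, plus `round1` (the
#'   round-1 result) and `gained`/`lost` glycoform key sets.
#' @export
two_step_search <- function(pseudo_list, proteins,
                            glycans = default_glycan_library(),
                            cfg = search_config(), masses = mass_table(),
                            label = "TMT6") {
  if (!nrow(proteins)) stop("two_step_search: empty database")
  space1 <- build_search_space(proteins, glycans, masses, label)
  res1 <- search_run(pseudo_list, build_candidate_index(space1), cfg,
                     masses, label)
  if (!nrow(res1$accepted)) {
    warning("two_step_search: round 1 accepted nothing; final result empty")
    out <- res1
    out$db_round <- 2L
    out$round1 <- res1
    out$gained <- out$lost <- character()
    return(out)
  }
  keep <- unique(res1$accepted$protein)
  prot2 <- proteins[accession %in% keep]
  space2 <- build_search_space(prot2, glycans, masses, label)
  res2 <- search_run(pseudo_list, build_candidate_index(space2), cfg,
                     masses, label)
  res2$db_round <- 2L
  key <- function(a) if (nrow(a)) unique(paste(a$protein, a$site_protein, a$glycan, sep = "|")) else character()
  res2$round1 <- res1
  res2$gained <- setdiff(key(res2$accepted), key(res1$accepted))
  res2$lost <- setdiff(key(res1$accepted), key(res2$accepted))
  res2
}

#' Write a GPSM table as TSV
#'
#' @param result a `SearchResult` (accepted set is written by default).
#' @param path output TSV path.
#' @param what `"accepted"` or `"all"`.
#' @return `path`, invisibly.
#' @export
write_gpsm_table <- function(result, path, what = c("accepted", "all")) {
  what <- match.arg(what)
  data.table::fwrite(if (what == "accepted") result$accepted else result$gpsms,
                     path, sep = "\t")
  invisible(path)
}
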