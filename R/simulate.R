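#' Simulation configuration
#'
#' Describes a synthetic multi-notch SPS-MS3 acquisition. Defaults encode
#' the conditions of the six-channel interference mixture design: analyte
#' channel mixing 10:4:1:1:4:10 across channels 126-131, contaminant
#' mixing 1:1:1:0:0:0 (interference confined to the first three
#' channels), contaminant total signal matched 1:1 to the analyte,
#' 10 SPS notches in the 700-2000 m/z window, 10% multiplicative CV on
#' reporter intensities and a mild SPS carry-through (`sps_attenuation`
#' 0.2, i.e. MS3 purification removes 80% of co-isolated contaminant
#' signal). Every random draw flows from `seed`, so a fixed seed gives
#' byte-identical output files.
#'
#' @param seed integer RNG seed.
#' @param n_glycopeptides number of distinct true glycoforms simulated.
#' @param spectra_per_glycoform redundant GPSMs (charge/cleavage
#'   variants) acquired per glycoform (default 6).
#' @param n_impostors number of impostor spectra (shuffled peptides with
#'   mass-shifted glycans, absent from any database) appended for
#'   FDR benchmarking.
#' @param proteins optional protein pool (`data.table` accession,
#'   sequence); generated with [generate_protein_pool()] when NULL.
#' @param n_proteins,protein_length,sequons_per_protein pool generation
#'   parameters used when `proteins` is NULL.
#' @param glycans glycan library to draw analyte glycans from.
#' @param channel_design analyte channel mixing vector (6-plex order).
#' @param contaminant_design contaminant channel mixing vector.
#' @param interference_fraction f between 0 and 1: fraction of
#'   spectrum-level precursor current contributed by the contaminant.
#' @param contaminated_fraction fraction of spectra affected when f > 0.
#' @param sps_attenuation alpha between 0 and 1: contaminant
#'   carry-through into MS3 (1 = MS2-like, 0 = perfect SPS purification).
#' @param noise_cv multiplicative coefficient of variation on reporter
#'   intensities (0 = noise off).
#' @param noise_floor additive uniform noise ceiling on reporter
#'   intensities (0 = off).
#' @param isotope_error_rate fraction of precursors reported one 13C
#'   isotope above the monoisotopic peak.
#' @param n_sps_notches,sps_window SPS notch count and m/z window.
#' @param scan_range instrument fragment m/z range; fragments outside it
#'   are not recorded.
#' @param precursor_window precursor m/z range eligible for isolation;
#'   the charge state is drawn among those that place the precursor
#'   inside it.
#' @param max_peptide_length longest tryptic peptide simulated as a true
#'   analyte (HILIC-enriched glycopeptides are typically below ~30
#'   residues).
#' @param ms2_mode when TRUE, emulate a plain MS2 acquisition: no MS3
#'   scans, reporter ions placed in MS2 with full interference.
#' @param label isobaric label.
#' @return A list of class `SimConfig`.
#' @export
sim_config <- function(seed = 1L, n_glycopeptides = 50L,
                       spectra_per_glycoform = 6L, n_impostors = 0L,
                       proteins = NULL, n_proteins = 30L,
                       protein_length = 240L, sequons_per_protein = 4L,
                       glycans = default_glycan_library(),
                       channel_design = c(10, 4, 1, 1, 4, 10),
                       contaminant_design = c(1, 1, 1, 0, 0, 0),
                       interference_fraction = 0,
                       contaminated_fraction = 1,
                       sps_attenuation = 0.2,
                       noise_cv = 0.1, noise_floor = 0,
                       isotope_error_rate = 0.2,
                       n_sps_notches = 10L, sps_window = c(700, 2000),
                       scan_range = c(120, 2000),
                       precursor_window = c(400, 1950),
                       max_peptide_length = 30L,
                       ms2_mode = FALSE, label = "TMT6") {
  stopifnot(all(channel_design >= 0), all(contaminant_design >= 0),
            interference_fraction >= 0, interference_fraction <= 1,
            sps_attenuation >= 0, sps_attenuation <= 1,
            n_glycopeptides >= 1 || n_impostors >= 1)
  structure(as.list(environment()), class = "SimConfig")
}

#' Generate a synthetic protein pool
#'
#' Random protein sequences drawn from typical amino-acid frequencies
#' (K/R at tryptic abundance), with N-X-S/T sequons written in at random
#' interior positions. Uses the current RNG state.
#'
#' @param n number of proteins.
#' @param length residues per protein.
#' @param n_sequons sequons written into each protein.
#' @param prefix accession prefix.
#' @return A `data.table` with `accession`, `sequence`.
#' @export
generate_protein_pool <- function(n = 30L, length = 240L, n_sequons = 4L,
                                  prefix = "SYN") {
  aa <- c("A","R","N","D","C","E","Q","G","H","I","L","K","M","F","P","S",
          "T","W","Y","V")
  w <- c(8.3, 5.7, 4.0, 5.5, 1.4, 6.8, 3.9, 7.1, 2.3, 6.0, 9.7, 5.8, 2.4,
         3.9, 4.7, 6.6, 5.4, 1.1, 2.9, 6.9)
  seqs <- vapply(seq_len(n), function(i) {
    s <- sample(aa, length, replace = TRUE, prob = w)
    pos <- sample(seq(5L, length - 5L), n_sequons)
    for (p in pos) {
      s[p] <- "N"
      s[p + 1L] <- sample(setdiff(aa, "P"), 1L)
      s[p + 2L] <- sample(c("S", "T"), 1L)
    }
    paste(s, collapse = "")
  }, "")
  data.table::data.table(accession = sprintf("%s%03d", prefix, seq_len(n)),
                         sequence = seqs)
}

#' Select SPS notches from an MS2 spectrum
#'
#' The `n` most intense peaks inside the SPS m/z window, in descending
#' intensity order. Reporter-region peaks (m/z < 135) are never selected.
#'
#' @param ms2 an MS2 [spectrum()].
#' @param n_sps_notches maximum notch count (default 10).
#' @param sps_window numeric length-2 m/z window (default 700-2000).
#' @return Numeric vector of notch m/z values (possibly shorter than
#'   `n_sps_notches`).
#' @export
select_sps <- function(ms2, n_sps_notches = 10L, sps_window = c(700, 2000)) {
  ok <- ms2$mz >= sps_window[1] & ms2$mz <= sps_window[2] & ms2$mz >= 135
  mz <- ms2$mz[ok]; int <- ms2$intensity[ok]
  if (!length(mz)) return(numeric())
  o <- order(-int, mz)
  mz[o][seq_len(min(n_sps_notches, length(mz)))]
}

#' @noRd
.lognoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

#' @noRd
.shuffle_interior <- function(pep, targets) {
  n <- nchar(pep)
  if (n <= 2L) return(pep)
  for (try in 1:20) {
    body <- sample(strsplit(substr(pep, 1L, n - 1L), "")[[1]])
    dec <- paste0(paste(body, collapse = ""), substr(pep, n, n))
    if (!(dec %in% targets)) return(dec)
  }
  pep
}

# Observed Y series of a glycopeptide MS2 scan: the stepwise trimming
# ladder from the bare peptide (Y0) through the chitobiose/trimannosyl
# core up to the full composition — one remnant per lost monosaccharide,
# not the combinatorial sub-composition lattice. Residues are added in
# biosynthetic order (core HexNAc2, core Hex3, remaining HexNAc/Hex
# branches, NeuAc caps, Fuc last), so every rung satisfies the
# attachment rules used by the theoretical series.
#' @noRd
.y_ladder <- function(g) {
  steps <- c(rep("hexnac", min(2L, g[["hexnac"]])),
             rep("hex", min(3L, g[["hex"]])),
             rep("hexnac", max(0L, g[["hexnac"]] - 2L)),
             rep("hex", max(0L, g[["hex"]] - 3L)),
             rep("neuac", g[["neuac"]]),
             rep("fuc", g[["fuc"]]))
  cur <- c(hex = 0L, hexnac = 0L, neuac = 0L, fuc = 0L)
  out <- matrix(0L, nrow = length(steps) + 1L, ncol = 4L,
                dimnames = list(NULL, names(cur)))
  for (i in seq_along(steps)) {
    cur[steps[i]] <- cur[steps[i]] + 1L
    out[i + 1L, ] <- cur
  }
  out
}

# Fragment-ion m/z for a Y series: each Y ion takes the smallest charge
# (up to the precursor charge) that brings it at or below the upper SPS
# bound, mimicking the large multiply-charged glycopeptide fragments
# observed at low collision energy.
# b/y fragments appear singly charged unless that puts them beyond the
# scan range, in which case they appear at 2+; still-out-of-range ions
# are not recorded.
#' @noRd
.frag_mz <- function(neutral, scan_range, proton) {
  mz <- neutral + proton
  hi <- mz > scan_range[2]
  mz[hi] <- neutral[hi] / 2 + proton
  mz[mz >= scan_range[1] & mz <= scan_range[2]]
}

#' @noRd
.y_ion_mz <- function(neutral, z_prec, upper, proton) {
  z <- rep(1L, length(neutral))
  for (zz in seq_len(max(1L, z_prec))) {
    need <- neutral / z + proton > upper & z < z_prec
    if (!any(need)) break
    z[need] <- z[need] + 1L
  }
  neutral / z + proton
}

#' Simulate a multi-notch SPS-MS3 run with ground truth
#'
#' For every simulated glycopeptide spectrum: an MS1 context scan with an
#' isotope envelope (sometimes mis-reported one isotope up), an MS2 scan
#' dominated by glycan Y-series ions at low collision energy (plus
#' contaminant fragments when interference is on), SPS notch selection,
#' and an MS3 scan carrying peptide b/y ions and the reporter-ion
#' cluster. Reporter channel c of a contaminated spectrum receives
#' `A*r_c + f*alpha*B*s_c` (A, B analyte/contaminant total signal; r, s
#' the normalized channel designs; alpha = 1 in MS2 mode where reporters
#' sit in the MS2 scan). Multiplicative CV and additive floor noise are
#' applied to reporter intensities afterwards.
#'
#' @param cfg a [sim_config()].
#' @return A list of class `SimResult`: `run` (a [scan_hierarchy()]),
#'   `truth` (`data.table`, one row per MS2 scan: candidate key, true
#'   pre-noise channel intensities `T<channel>`, `contaminated`,
#'   `is_true`), `proteins` (the pool, for searching), `cfg`.
#' @export
simulate_run <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  masses <- mass_table()
  channels <- reporter_channels()
  proteins <- if (is.null(cfg$proteins)) {
    generate_protein_pool(cfg$n_proteins, cfg$protein_length,
                          cfg$sequons_per_protein)
  } else cfg$proteins
  entries <- digest_proteome(proteins, masses = masses, label = cfg$label)
  entries <- entries[n_ox == 0L]
  if (!nrow(entries)) stop("simulate_run: protein pool yields no glycopeptides")
  # restrict true analytes to single-sequon peptides so the rank-1 answer
  # is unambiguous (multi-sequon peptides stay in the search space)
  nsite <- entries[, .(ns = data.table::uniqueN(site)), by = peptide]
  pool <- entries[peptide %in% nsite$peptide[nsite$ns == 1L] &
                    nchar(peptide) <= cfg$max_peptide_length]
  glycans <- cfg$glycans
  n_gf <- cfg$n_glycopeptides
  combos <- data.table::data.table(
    pi = sample(nrow(pool), n_gf, replace = nrow(pool) < n_gf),
    gi = sample(nrow(glycans), n_gf, replace = TRUE))
  combos <- unique(combos)
  r <- cfg$channel_design / sum(cfg$channel_design)
  s_design <- if (sum(cfg$contaminant_design) > 0)
    cfg$contaminant_design / sum(cfg$contaminant_design) else rep(0, 6)

  specs <- list(); truth_rows <- list(); scan <- 0L
  emit_analyte <- function(pep_row, gly_row, is_true, gf_abundance) {
    M <- pep_row$pep_mass + gly_row$gly_mass + gly_row$shift
    zopt <- 2:4
    mzs <- M / zopt + masses$proton
    ok <- mzs >= cfg$precursor_window[1] & mzs <= cfg$precursor_window[2]
    z <- if (any(ok)) zopt[ok][sample.int(sum(ok), 1L)] else
      zopt[which.min(abs(mzs - mean(cfg$precursor_window)))]
    mono_mz <- M / z + masses$proton
    k_iso <- if (stats::runif(1) < cfg$isotope_error_rate) 1L else 0L
    spacing <- masses$c13 / z
    # MS1 context: averagine-like envelope, rise-then-fall from the mono peak
    lam <- M / 1800
    env_w <- stats::dpois(0:3, lam)
    ms1 <- spectrum(scan + 1L, 1L, mz = mono_mz + (0:3) * spacing,
                    intensity = env_w / max(env_w) * 1e7,
                    retention_time = (scan + 1L) * 0.5)
    # MS2: glycan Y-series trimming ladder (low collision energy),
    # core remnants dominant
    lad <- .y_ladder(c(hex = gly_row$hex, hexnac = gly_row$hexnac,
                       neuac = gly_row$neuac, fuc = gly_row$fuc))
    delta <- lad %*% masses$mono[c("hex", "hexnac", "neuac", "fuc")]
    y_neutral <- pep_row$pep_mass + as.numeric(delta) +
      ifelse(delta == 0, 0, gly_row$shift)
    nres <- rowSums(lad)
    y_mz <- .y_ion_mz(y_neutral, z, cfg$sps_window[2], masses$proton)
    y_int <- 1e5 * exp(-0.15 * nres) * .lognoise(length(y_neutral), 0.3)
    in_scan <- y_mz >= cfg$scan_range[1] & y_mz <= cfg$scan_range[2]
    y_mz <- y_mz[in_scan]; y_int <- y_int[in_scan]
    contaminated <- cfg$interference_fraction > 0 &&
      stats::runif(1) < cfg$contaminated_fraction
    A <- gf_abundance * stats::rlnorm(1, 0, 0.5)
    B <- A  # contaminant total matched 1:1 to analyte
    f <- if (contaminated) cfg$interference_fraction else 0
    mz2 <- y_mz; int2 <- y_int
    if (contaminated) {
      n_c <- 20L
      mz2 <- c(mz2, stats::runif(n_c, 200, 1400))
      int2 <- c(int2, 2e4 * f * .lognoise(n_c, 0.5))
    }
    rep_scale <- 1e-2  # reporter intensities on the instrument's MS scale
    if (cfg$ms2_mode) {
      # plain-MS2 acquisition: moderate b/y coverage from the single
      # (stepped-energy) scan, reporters read from MS2 at full interference
      by <- enumerate_by_ions(pep_row$peptide, masses, cfg$label, 0L)
      cov <- stats::runif(1, 0.4, 0.8)
      keep_by <- sort(sample(nrow(by), max(1L, round(cov * nrow(by)))))
      by_mz <- .frag_mz(by$neutral[keep_by], cfg$scan_range, masses$proton)
      mz2 <- c(mz2, by_mz)
      int2 <- c(int2, 1e4 * .lognoise(length(by_mz), 0.4))
      rep_int <- (A * r + f * B * s_design) * rep_scale
      rep_int <- rep_int * .lognoise(6, cfg$noise_cv) +
        stats::runif(6, 0, cfg$noise_floor)
      keep <- rep_int > 0
      mz2 <- c(channels$mz[keep], mz2)
      int2 <- c(rep_int[keep], int2)
    }
    ms2 <- spectrum(scan + 2L, 2L, mz = mz2, intensity = int2,
                    retention_time = (scan + 2L) * 0.5,
                    precursor_mz = mono_mz + k_iso * spacing,
                    precursor_charge = z, parent_scan = scan + 1L)
    out <- list(ms1, ms2)
    if (!cfg$ms2_mode) {
      notches <- select_sps(ms2, cfg$n_sps_notches, cfg$sps_window)
      if (!length(notches)) notches <- mono_mz
      by <- enumerate_by_ions(pep_row$peptide, masses, cfg$label, 0L)
      cov <- stats::runif(1, 0.6, 0.95)
      keep_by <- sort(sample(nrow(by), max(1L, round(cov * nrow(by)))))
      by_mz <- .frag_mz(by$neutral[keep_by], cfg$scan_range, masses$proton)
      by_int <- 3e4 * .lognoise(length(by_mz), 0.4)
      rep_int <- (A * r + f * cfg$sps_attenuation * B * s_design) * rep_scale
      rep_int <- rep_int * .lognoise(6, cfg$noise_cv) +
        stats::runif(6, 0, cfg$noise_floor)
      keep <- rep_int > 0
      ms3 <- spectrum(scan + 3L, 3L,
                      mz = c(channels$mz[keep], by_mz),
                      intensity = c(rep_int[keep], by_int),
                      retention_time = (scan + 3L) * 0.5,
                      precursor_mz = mono_mz, precursor_charge = z,
                      parent_scan = scan + 2L, sps_mz = notches)
      out <- c(out, list(ms3))
    }
    truth_rows[[length(truth_rows) + 1L]] <<- data.table::data.table(
      ms2_scan = scan + 2L, peptide = pep_row$peptide,
      protein = pep_row$protein, site_protein = pep_row$site_protein,
      glycan = gly_row$glycan, charge = z, is_true = is_true,
      contaminated = contaminated, abundance = A,
      data.table::as.data.table(as.list(stats::setNames(
        A * r * rep_scale, paste0("T", channels$channel)))))
    specs[c(length(specs) + seq_along(out))] <<- out
    scan <<- scan + length(out)
    invisible(NULL)
  }

  for (i in seq_len(nrow(combos))) {
    pep_row <- pool[combos$pi[i]]
    gly_row <- glycans[combos$gi[i], .(hex, hexnac, neuac, fuc, glycan, gly_mass)]
    gly_row[, shift := 0]
    gf_abundance <- stats::rlnorm(1, log(2e6), 1)
    for (k in seq_len(cfg$spectra_per_glycoform))
      emit_analyte(pep_row, gly_row, TRUE, gf_abundance)
  }
  if (cfg$n_impostors > 0L) {
    targets <- unique(pool$peptide)
    for (i in seq_len(cfg$n_impostors)) {
      src <- pool[sample(nrow(pool), 1L)]
      dec <- .shuffle_interior(src$peptide, targets)
      gi <- sample(nrow(glycans), 1L)
      gly_row <- glycans[gi, .(hex, hexnac, neuac, fuc, glycan, gly_mass)]
      gly_row[, shift := stats::runif(1, 5, 50)]
      gly_row[, glycan := paste0("IMPOSTOR:", glycan)]
      fake <- data.table::data.table(
        peptide = dec, protein = paste0("IMPOSTOR_", src$protein),
        site_protein = src$site_protein,
        pep_mass = peptide_mass(dec, masses, cfg$label, 0L))
      emit_analyte(fake, gly_row, FALSE, stats::rlnorm(1, log(2e6), 1))
    }
  }
  truth <- data.table::rbindlist(truth_rows)
  structure(list(run = scan_hierarchy(specs), truth = truth,
                 proteins = proteins, cfg = cfg),
            class = "SimResult")
}

#' Simulate the six-channel interference mixture experiment
#'
#' Preset emulating the co-isolation interference design: glycopeptide
#' analytes from a small two-protein database mixed 10:4:1:1:4:10 across
#' the six channels, a non-glycosylated contaminant background labelled
#' 1:1:1 in the first three channels only and spiked 1:1 in total signal.
#' Channels 129-131 are interference-free by design. Two runs are
#' emitted over the same analytes: an SPS-MS3 run (contaminant reporter
#' carry-through attenuated by `sps_attenuation`) and a plain-MS2 run
#' (reporters read from MS2, full interference), for side-by-side
#' quantification accuracy comparison.
#'
#' @param seed RNG seed.
#' @param n_glycopeptides distinct glycoforms (default 12, two IgM-like
#'   proteins' worth of sequon peptides).
#' @param interference_fraction,sps_attenuation,noise_cv,noise_floor see
#'   [sim_config()].
#' @param ... further [sim_config()] overrides.
#' @return A list of class `InterferenceSim`: `sps` and `ms2`
#'   (`SimResult`s sharing analytes), `proteins`, `design`,
#'   `contaminant_design`.
#' @export
simulate_interference_mixture <- function(seed = 1L, n_glycopeptides = 12L,
                                          interference_fraction = 0.5,
                                          sps_attenuation = 0.2,
                                          noise_cv = 0.1, noise_floor = 0,
                                          ...) {
  set.seed(seed)
  proteins <- generate_protein_pool(2L, 320L, 8L, prefix = "IGMLIKE")
  base <- list(seed = seed, n_glycopeptides = n_glycopeptides,
               proteins = proteins,
               channel_design = c(10, 4, 1, 1, 4, 10),
               contaminant_design = c(1, 1, 1, 0, 0, 0),
               interference_fraction = interference_fraction,
               sps_attenuation = sps_attenuation,
               noise_cv = noise_cv, noise_floor = noise_floor, ...)
  sps <- simulate_run(do.call(sim_config, c(base, list(ms2_mode = FALSE))))
  ms2 <- simulate_run(do.call(sim_config, c(base, list(ms2_mode = TRUE))))
  structure(list(sps = sps, ms2 = ms2, proteins = proteins,
                 design = c(10, 4, 1, 1, 4, 10),
                 contaminant_design = c(1, 1, 1, 0, 0, 0)),
            class = "InterferenceSim")
}

#' Export a simulation configuration as JSON
#'
#' Scalar fields only; the protein pool and glycan library travel as
#' their own artifacts (FASTA / TSV).
#'
#' @param cfg a [sim_config()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
export_sim_config <- function(cfg, path) {
  scalars <- Filter(function(x) is.atomic(x) && length(x) <= 6, cfg)
  scalars$proteins <- NULL
  jsonlite::write_json(scalars, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export ground truth as TSV
#'
#' One row per simulated MS2 scan; joins to GPSM tables on the scan
#' number.
#'
#' @param sim a `SimResult` (or its `truth` table).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
export_ground_truth <- function(sim, path) {
  truth <- if (inherits(sim, "SimResult")) sim$truth else sim
  data.table::fwrite(truth, path, sep = "\t")
  invisible(path)
}
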