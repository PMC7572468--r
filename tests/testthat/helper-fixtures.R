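# shared fixtures, built in code at test time

# a minimal two-precursor SPS-MS3 run: MS1 + MS2 + MS3 per precursor
tiny_run <- function() {
  scan_hierarchy(list(
    spectrum(1, 1, mz = c(500.0, 500.5017, 501.0034),
             intensity = c(80, 100, 60)),
    spectrum(2, 2, mz = c(300.1, 800.2, 900.3, 1200.4),
             intensity = c(10, 50, 40, 30),
             precursor_mz = 500.0, precursor_charge = 2, parent_scan = 1),
    spectrum(3, 3, mz = c(126.12773, 127.13108, 200.5, 300.1001),
             intensity = c(500, 250, 20, 12),
             precursor_mz = 500.0, precursor_charge = 2, parent_scan = 2,
             sps_mz = c(800.2, 900.3)),
    spectrum(4, 1, mz = c(600.0, 600.5017), intensity = c(100, 70)),
    spectrum(5, 2, mz = c(700.1, 1100.2), intensity = c(25, 35),
             precursor_mz = 600.0, precursor_charge = 2, parent_scan = 4),
    spectrum(6, 3, mz = c(126.12773, 131.14450, 450.7),
             intensity = c(300, 150, 40),
             precursor_mz = 600.0, precursor_charge = 2, parent_scan = 5,
             sps_mz = 1100.2)
  ))
}

# deterministic small protein set with known digestion behaviour
fixture_proteins <- function() {
  data.table::data.table(
    accession = c("P1", "P2", "P3"),
    sequence = c("MKANSTRPKGFEDNKSWLR",  # sequon at protein pos 4 (ANSTRPK)
                 "AAAKNGTLLRCCKPNWSSR",
                 "MKNGTSGNKAAAR")        # reversal decoy keeps a sequon
  )
}

small_glycans <- function() {
  lib <- data.table::CJ(hex = 3:5, hexnac = 2:3, neuac = 0:1, fuc = 0:1)
  glycoquant:::.finish_glycan_library(lib)
}

# brute-force tryptic cleavage oracle: enumerate segments between cut
# sites directly from the cleavage rule
oracle_digest <- function(sequence, max_missed = 2L, min_len = 4L) {
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  cut_after <- which(aa %in% c("K", "R"))
  cut_after <- cut_after[cut_after == n | aa[pmin(cut_after + 1L, n)] != "P"]
  bounds <- sort(unique(c(0L, cut_after[cut_after < n], n)))
  out <- list()
  for (i in seq_len(length(bounds) - 1L)) {
    for (j in i:min(i + max_missed, length(bounds) - 1L)) {
      s <- bounds[i] + 1L; e <- bounds[j + 1L]
      if (e - s + 1L >= min_len)
        out[[length(out) + 1L]] <- data.frame(
          peptide = substr(sequence, s, e), start_pos = s,
          missed_cleavages = j - i)
    }
  }
  do.call(rbind, out)
}

# independent residue-mass summation oracle (per-letter loop, no reuse of
# peptide_mass internals)
oracle_peptide_mass <- function(pep, label = "TMT6", n_ox = 0L) {
  mt <- mass_table()
  total <- mt$water
  n_k <- 0L
  for (ch in strsplit(pep, "")[[1]]) {
    total <- total + mt$residues[[ch]]
    if (ch == "C") total <- total + mt$mods[["carbamidomethyl"]]
    if (ch == "K") n_k <- n_k + 1L
  }
  total + n_ox * mt$mods[["oxidation"]] + mt$labels[[label]] * (1 + n_k)
}

# exhaustive Y-ion sub-composition oracle
oracle_y_count <- function(g) {
  n <- 0L
  masses <- numeric()
  for (h in 0:g[["hex"]]) for (x in 0:g[["hexnac"]])
    for (s in 0:g[["neuac"]]) for (f in 0:g[["fuc"]]) {
      if (!(x >= 1 || (h == 0 && s == 0 && f == 0))) next
      if (s > 0 && h < 1) next
      masses <- c(masses, h * 162.05282 + x * 203.07937 +
                    s * 291.09542 + f * 146.05791)
    }
  length(unique(signif(masses, 12)))
}
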