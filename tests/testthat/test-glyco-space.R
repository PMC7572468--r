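test_that("tryptic digestion matches the cleavage-rule oracle", {
  # worked example: no cleavage after R when P follows
  d <- tryptic_digest("MKANSTRPK", max_missed = 1, min_len = 2)
  expect_setequal(d$peptide, c("MK", "ANSTRPK", "MKANSTRPK"))
  # protein with no K/R: whole sequence, zero missed cleavages
  d2 <- tryptic_digest("AAANGTWL")
  expect_equal(d2$peptide, "AAANGTWL")
  expect_equal(d2$missed_cleavages, 0L)
  # concatenating the fully cleaved peptides reconstructs the protein
  set.seed(11)
  for (rep in 1:5) {
    seqn <- paste(sample(c("A","G","K","R","P","N","S","T","L","F"), 60,
                         replace = TRUE), collapse = "")
    d0 <- tryptic_digest(seqn, max_missed = 0, min_len = 1)
    expect_equal(paste(d0$peptide[order(d0$start_pos)], collapse = ""), seqn)
  }
  # 50 random proteins against the brute-force oracle
  set.seed(12)
  pool <- generate_protein_pool(50, 120, 2)
  for (i in seq_len(nrow(pool))) {
    got <- tryptic_digest(pool$sequence[i])
    want <- oracle_digest(pool$sequence[i])
    expect_equal(nrow(got), nrow(want))
    expect_setequal(paste(got$peptide, got$start_pos, got$missed_cleavages),
                    paste(want$peptide, want$start_pos, want$missed_cleavages))
  }
  expect_error(tryptic_digest("AB1"), "non-standard")
})

test_that("sequon detection applies N-X-S/T with X != P across boundaries", {
  expect_equal(find_sequons("ANSTRPK", "MKANSTRPKGF", 3L), 2L)
  expect_equal(find_sequons("ANPTK", "ANPTK", 1L), integer())
  # C-terminal N with the S/T beyond the peptide boundary
  expect_equal(find_sequons("AAKN", "AAKNGTLL", 1L), 4L)
  # X = P across the boundary kills the motif
  expect_equal(find_sequons("AAKN", "AAKNPTLL", 1L), integer())
  expect_error(find_sequons("WWWW", "AAKNGTLL"), "not found")
})

test_that("peptide and fragment masses agree with the summation oracle", {
  cases <- data.frame(
    pep = c("ACK", "G", "ANSTK", "MMKNGTR", "WEDNKSWLR"),
    label = c("TMT6", "none", "TMT0", "TMT6", "TMT6"),
    n_ox = c(0L, 0L, 0L, 2L, 0L), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    expect_equal(
      peptide_mass(cases$pep[i], label = cases$label[i], n_ox = cases$n_ox[i]),
      oracle_peptide_mass(cases$pep[i], cases$label[i], cases$n_ox[i]),
      tolerance = 1e-6)
  }
  expect_equal(peptide_mass("G", label = "none"),
               57.02146372 + 18.010564684, tolerance = 1e-6)
  # oxidation shifts the mass by exactly its defined delta
  expect_equal(peptide_mass("AMK", n_ox = 1) - peptide_mass("AMK", n_ox = 0),
               15.99492, tolerance = 1e-9)
  expect_error(peptide_mass("AXK"), "unknown")
  expect_error(peptide_mass("AGK", n_ox = 1), "methionine")
})

test_that("b/y ions satisfy the additivity identity and label placement", {
  ions <- enumerate_by_ions("AG", label = "none")
  expect_equal(nrow(ions), 2L)
  # b_k + y_{n-k} = neutral peptide mass, 20 random peptides
  set.seed(13)
  aa <- names(mass_table()$residues)
  for (r in 1:20) {
    pep <- paste(sample(aa, sample(4:15, 1), replace = TRUE), collapse = "")
    M <- peptide_mass(pep, label = "TMT6")
    ions <- enumerate_by_ions(pep, label = "TMT6")
    n <- nchar(pep)
    b <- ions$neutral[match(paste0("b", 1:(n - 1)), ions$ion)]
    y <- ions$neutral[match(paste0("y", 1:(n - 1)), ions$ion)]
    expect_equal(b + rev(y), rep(M, n - 1), tolerance = 1e-9)
  }
  # the K-containing y1 of ACK carries exactly one label
  ions <- enumerate_by_ions("ACK", label = "TMT6")
  y1 <- ions$neutral[ions$ion == "y1"]
  mt <- mass_table()
  expect_equal(y1, mt$residues[["K"]] + mt$water + mt$labels[["TMT6"]],
               tolerance = 1e-9)
  expect_error(enumerate_by_ions("A"), "length")
})

test_that("Y-ion series equals the exhaustive sub-composition oracle", {
  # smallest case: HexNAc(1) -> Y0 plus Y0+HexNAc
  y <- enumerate_y_ions(1000, c(hex = 0L, hexnac = 1L, neuac = 0L, fuc = 0L))
  expect_equal(nrow(y), 2L)
  expect_equal(y$neutral, c(1000, 1203.07937), tolerance = 1e-9)
  glycans <- list(c(hex = 1L, hexnac = 2L, neuac = 0L, fuc = 1L),
                  c(hex = 5L, hexnac = 4L, neuac = 2L, fuc = 1L),
                  c(hex = 3L, hexnac = 2L, neuac = 0L, fuc = 0L))
  mt <- mass_table()
  for (g in glycans) {
    y <- enumerate_y_ions(2000, g, mt)
    expect_equal(nrow(y), oracle_y_count(g))
    # every Y mass is peptide mass plus a component-wise valid glycan sum
    deltas <- y$neutral - 2000
    expect_true(all(deltas >= 0))
    expect_equal(y$neutral[1], 2000)                   # Y0 present
    expect_equal(max(deltas), sum(mt$mono * g), tolerance = 1e-9)
    expect_false(is.unsorted(y$neutral))
  }
})

test_that("peptide decoys reverse keeping the C-terminus, mass-neutral", {
  expect_equal(glycoquant:::.reverse_keep_cterm("ANSTK"), "TSNAK")
  entries <- digest_proteome(fixture_proteins())
  dec <- make_peptide_decoys(entries)
  expect_true(all(dec$pep_decoy))
  expect_true(all(startsWith(dec$protein, "DECOY_")))
  # decoy sequences never collide with targets
  expect_length(intersect(dec$peptide, entries$peptide), 0L)
  # reversal preserves mass
  for (p in unique(dec$peptide)) {
    orig <- unique(entries$peptide[vapply(entries$peptide, function(t)
      glycoquant:::.reverse_keep_cterm(t) == p, TRUE)])
    expect_equal(peptide_mass(p), peptide_mass(orig[1]), tolerance = 1e-9)
  }
  # a palindromic decoy ("ANAK" reverses onto itself) is dropped
  pal <- data.table::data.table(
    peptide = "ANAK", protein = "X", start_pos = 1L, missed_cleavages = 0L,
    site = 1L, site_protein = 1L, n_ox = 0L, pep_mass = 1,
    pep_decoy = FALSE)
  expect_equal(nrow(make_peptide_decoys(pal)), 0L)
})

test_that("glycan decoys shift composition mass but never Y0", {
  lib <- small_glycans()
  dec <- make_glycan_decoys(lib)
  expect_equal(dec$gly_mass - lib$gly_mass, rep(17.00274, nrow(lib)))
  g <- c(hex = 3L, hexnac = 2L, neuac = 0L, fuc = 1L)
  yt <- enumerate_y_ions(1500, g)
  yd <- enumerate_y_ions(1500, g, decoy_shift = 17.00274)
  expect_equal(nrow(yd), nrow(yt))              # same ion count
  expect_equal(yd$neutral[1], 1500)             # Y0 unshifted
  expect_equal(sort(yd$neutral[-1]), sort(yt$neutral[-1]) + 17.00274,
               tolerance = 1e-9)
})

test_that("candidate index returns exactly the linear-scan result set", {
  space <- build_search_space(fixture_proteins(), small_glycans())
  idx <- build_candidate_index(space)
  masses <- space$neutral_mass
  set.seed(14)
  queries <- c(sample(masses, 400, replace = TRUE) * (1 + runif(400, -2e-5, 2e-5)),
               runif(600, min(masses) - 10, max(masses) + 10))
  for (q in queries) {
    got <- sort(query_candidates(idx, q, 10)$cand_id)
    want <- sort(space$cand_id[abs(space$neutral_mass - q) <= q * 10e-6])
    expect_identical(got, want)
  }
  # far-away query is empty; exact-mass query contains that candidate
  expect_equal(nrow(query_candidates(idx, max(masses) + 1000, 10)), 0L)
  hit <- query_candidates(idx, masses[5], 10)
  expect_true(space$cand_id[5] %in% hit$cand_id)
})

test_that("search space crosses peptides and glycans with all decoy classes", {
  space <- build_search_space(fixture_proteins(), small_glycans())
  expect_setequal(unique(space$decoy_class),
                  c("target", "pep_decoy", "gly_decoy", "both"))
  expect_false(is.unsorted(space$neutral_mass))
  t0 <- space[decoy_class == "target"]
  expect_equal(t0$neutral_mass, t0$pep_mass + t0$gly_mass, tolerance = 1e-6)
  # glycan library round-trip through its TSV interface
  path <- withr::local_tempfile(fileext = ".tsv")
  write_glycan_library(small_glycans(), path)
  back <- read_glycan_library(path)
  expect_equal(back$gly_mass, small_glycans()$gly_mass)
})
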