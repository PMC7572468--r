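test_that("the same seed reproduces byte-identical output", {
  cfg <- sim_config(seed = 41, n_glycopeptides = 5, spectra_per_glycoform = 2)
  s1 <- simulate_run(cfg)
  s2 <- simulate_run(cfg)
  p1 <- withr::local_tempfile(fileext = ".mgf")
  p2 <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(s1$run, p1); write_mgf(s2$run, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(s1$truth, s2$truth)
  # a different seed changes the run
  s3 <- simulate_run(sim_config(seed = 42, n_glycopeptides = 5,
                                spectra_per_glycoform = 2))
  expect_false(identical(s1$truth, s3$truth))
})

test_that("SPS selection takes the documented notch count inside the window", {
  set.seed(43)
  # 15 in-window candidates plus out-of-window and reporter-region peaks
  mz <- c(sort(runif(15, 700, 2000)), 650, 2050, 126.13, 500)
  int <- c(runif(15, 100, 1000), 1e6, 1e6, 1e7, 50)
  ms2 <- spectrum(1, 2, mz = mz, intensity = int, precursor_mz = 900)
  sel <- select_sps(ms2)
  expect_length(sel, 10L)
  expect_true(all(sel >= 700 & sel <= 2000))   # 650/2050 excluded
  expect_false(any(abs(sel - 126.13) < 1e-6))
  # fewer candidates than notches
  ms2b <- spectrum(2, 2, mz = c(800, 900, 1000, 1100, 1200, 1300),
                   intensity = 6:1, precursor_mz = 900)
  expect_length(select_sps(ms2b), 6L)
  expect_equal(select_sps(ms2b)[1], 800)       # descending intensity
  expect_length(select_sps(spectrum(3, 2, mz = 300, intensity = 1,
                                    precursor_mz = 900)), 0L)
})

test_that("reporter intensities follow the channel design exactly when clean", {
  sim <- simulate_run(sim_config(seed = 44, n_glycopeptides = 6,
                                 spectra_per_glycoform = 1,
                                 interference_fraction = 0, noise_cv = 0,
                                 noise_floor = 0))
  link <- build_scan_link_table(sim$run)
  r <- c(10, 4, 1, 1, 4, 10) / 30
  for (i in seq_len(nrow(link))) {
    rep <- extract_reporters(sim$run$spectra[[as.character(link$ms3_scan[i])]])
    expect_equal(unname(rep / sum(rep)), r, tolerance = 1e-12)
    # pre-noise ground truth stores exactly these intensities
    tr <- sim$truth[ms2_scan == link$ms2_scan[i]]
    expect_equal(unname(rep),
                 unlist(tr[, paste0("T", reporter_channels()$channel),
                           with = FALSE], use.names = FALSE),
                 tolerance = 1e-9)
  }
})

test_that("contaminated reporters equal the closed-form mixture", {
  f <- 0.5; alpha <- 1
  sim <- simulate_run(sim_config(seed = 45, n_glycopeptides = 6,
                                 spectra_per_glycoform = 1,
                                 interference_fraction = f,
                                 contaminated_fraction = 1,
                                 sps_attenuation = alpha, noise_cv = 0,
                                 noise_floor = 0))
  link <- build_scan_link_table(sim$run)
  r <- c(10, 4, 1, 1, 4, 10) / 30
  s <- c(1, 1, 1, 0, 0, 0) / 3
  for (i in seq_len(nrow(link))) {
    tr <- sim$truth[ms2_scan == link$ms2_scan[i]]
    A <- unlist(tr[, paste0("T", reporter_channels()$channel), with = FALSE],
                use.names = FALSE) / r   # recover A*rep_scale per channel
    A <- A[1]
    rep <- extract_reporters(sim$run$spectra[[as.character(link$ms3_scan[i])]])
    expect_equal(unname(rep), A * r + f * alpha * A * s, tolerance = 1e-9)
    expect_true(tr$contaminated)
  }
})

test_that("interference bias grows with f and alpha and SPS beats MS2", {
  # closed-form on the reporter model: measured ratio of channel 126 to
  # 129 is (r1 + f*a*s1/ (r4)) -- bias strictly increasing in f and alpha
  r <- c(10, 4, 1, 1, 4, 10) / 30
  s <- c(1, 1, 1, 0, 0, 0) / 3
  ratio126 <- function(f, a) (r[1] + f * a * s[1]) / r[4]
  fs <- seq(0, 1, by = 0.25)
  expect_true(all(diff(vapply(fs, ratio126, 0, a = 0.5)) > 0))
  expect_true(all(diff(vapply(fs, ratio126, 0, a = 1)) > 0))
  expect_true(all(diff(vapply(c(0, 0.3, 0.7, 1), function(a)
    ratio126(0.5, a), 0)) > 0))
  # end-to-end: SPS-MS3 mode biases interfered ratios less than MS2 mode
  mix <- simulate_interference_mixture(seed = 46, n_glycopeptides = 8,
                                       interference_fraction = 0.5,
                                       sps_attenuation = 0.2, noise_cv = 0)
  err <- function(sim) {
    res <- search_run(build_pseudo_spectra(sim$run),
                      build_candidate_index(build_search_space(sim$proteins)),
                      search_config(preset = "igm"))
    gf <- channel_ratios(propagate(attach_quant(res$accepted, sim$run))$glycoform,
                         reference = "129")
    abs(median(gf$R126) - 10) / 10
  }
  expect_lt(err(mix$sps), err(mix$ms2))
})

test_that("ladder remnants satisfy the Y-ion attachment rules", {
  for (g in list(c(hex = 5L, hexnac = 4L, neuac = 2L, fuc = 1L),
                 c(hex = 3L, hexnac = 2L, neuac = 0L, fuc = 0L),
                 c(hex = 9L, hexnac = 2L, neuac = 0L, fuc = 3L))) {
    lad <- glycoquant:::.y_ladder(g)
    expect_equal(nrow(lad), sum(g) + 1L)
    expect_equal(unname(lad[nrow(lad), ]), unname(g))  # reaches the full glycan
    for (i in seq_len(nrow(lad))) {
      row <- lad[i, ]
      expect_true(row[["hexnac"]] >= 1 ||
                    (row[["hex"]] == 0 && row[["neuac"]] == 0 && row[["fuc"]] == 0))
      expect_true(row[["neuac"]] == 0 || row[["hex"]] >= 1)
    }
  }
})

test_that("ground truth joins GPSMs on scan number and round-trips", {
  sim <- simulate_run(sim_config(seed = 47, n_glycopeptides = 10,
                                 spectra_per_glycoform = 1))
  expect_equal(nrow(sim$truth), 10L)
  path <- withr::local_tempfile(fileext = ".tsv")
  export_ground_truth(sim, path)
  back <- data.table::fread(path)
  expect_equal(back$ms2_scan, sim$truth$ms2_scan)
  expect_equal(back$peptide, sim$truth$peptide)
  # FDP computed from a joined toy table equals the hand count
  toy_gpsms <- data.table::data.table(scan = sim$truth$ms2_scan[1:6])
  toy_truth <- data.table::copy(sim$truth)[, is_true := rep(c(TRUE, FALSE),
                                                            c(7, 3))]
  j <- merge(toy_gpsms, toy_truth, by.x = "scan", by.y = "ms2_scan")
  expect_equal(sum(!j$is_true), 0L)   # first six rows are all true here
  toy_gpsms2 <- data.table::data.table(scan = sim$truth$ms2_scan[c(1, 8, 9)])
  j2 <- merge(toy_gpsms2, toy_truth, by.x = "scan", by.y = "ms2_scan")
  expect_equal(mean(!j2$is_true), 2 / 3)
})

test_that("impostor spectra carry shuffled peptides absent from the pool", {
  sim <- simulate_run(sim_config(seed = 48, n_glycopeptides = 10,
                                 spectra_per_glycoform = 1, n_impostors = 10))
  imp <- sim$truth[is_true == FALSE]
  expect_equal(nrow(imp), 10L)
  entries <- digest_proteome(sim$proteins)
  expect_length(intersect(imp$peptide, entries$peptide), 0L)
  expect_true(all(startsWith(imp$protein, "IMPOSTOR_")))
})
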