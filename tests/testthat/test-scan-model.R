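test_that("spectrum canonicalizes peaks and enforces invariants", {
  s <- spectrum(5, 2, mz = c(300, 100, 200, 200), intensity = c(3, 1, 2, 4),
                precursor_mz = 500, parent_scan = 1)
  expect_equal(s$mz, c(100, 200, 300))        # sorted, duplicate mz summed
  expect_equal(s$intensity, c(1, 6, 3))
  expect_error(spectrum(1, 2, mz = c(1, NA), intensity = c(1, 1)), "NaN|NA")
  expect_error(spectrum(1, 2, mz = -1, intensity = 1), "mz")
  expect_error(spectrum(2, 3, mz = 1, intensity = 1, parent_scan = 1,
                        sps_mz = numeric()), "SPS")
  expect_error(spectrum(2, 2, mz = 1, intensity = 1, parent_scan = 5),
               "parent_scan")
})

test_that("tic_normalize sums to one, is idempotent, rejects empty TIC", {
  s <- spectrum(1, 2, mz = c(100, 200, 300), intensity = c(2, 3, 5))
  n1 <- tic_normalize(s)
  expect_equal(n1$intensity, c(0.2, 0.3, 0.5))
  expect_equal(n1$mz, s$mz)
  set.seed(42)
  big <- spectrum(2, 2, mz = sort(runif(100, 100, 2000)),
                  intensity = runif(100, 0, 1e6))
  expect_equal(sum(tic_normalize(big)$intensity), 1, tolerance = 1e-9)
  expect_equal(tic_normalize(tic_normalize(big))$intensity,
               tic_normalize(big)$intensity, tolerance = 1e-9)
  expect_error(tic_normalize(spectrum(1, 2, mz = 100, intensity = 0)),
               "degenerate")
})

test_that("scan hierarchy links MS3 to MS2 parents and validates", {
  run <- tiny_run()
  expect_equal(run$ms3_parent, c("3" = 2L, "6" = 5L))
  # MS3 referencing an absent parent
  expect_error(scan_hierarchy(list(
    spectrum(10, 2, mz = 500, intensity = 1, precursor_mz = 400),
    spectrum(11, 3, mz = 500, intensity = 1, precursor_mz = 400,
             parent_scan = 9, sps_mz = 500))), "unresolvable.*11")
  expect_error(scan_hierarchy(list(
    spectrum(7, 2, mz = 1, intensity = 1),
    spectrum(7, 2, mz = 1, intensity = 1))), "duplicated")
})

test_that("link table enumerates all MS3 scans in order", {
  lt <- build_scan_link_table(tiny_run())
  expect_equal(lt$ms3_scan, c(3L, 6L))
  expect_equal(lt$ms2_scan, c(2L, 5L))
  expect_equal(nrow(build_scan_link_table(scan_hierarchy(list()))), 0L)
  # three MS3 sharing one MS2 parent; count equals brute-force level scan
  run <- scan_hierarchy(c(list(
    spectrum(1, 2, mz = 500, intensity = 1, precursor_mz = 400)),
    lapply(2:4, function(i) spectrum(i, 3, mz = 500, intensity = 1,
                                     precursor_mz = 400, parent_scan = 1,
                                     sps_mz = 500))))
  lt <- build_scan_link_table(run)
  expect_equal(nrow(lt), sum(vapply(run$spectra, `[[`, 1L, "ms_level") == 3L))
  expect_true(all(lt$ms2_scan == 1L))
})

test_that("MGF round-trip preserves headers exactly and peaks to precision", {
  run <- tiny_run()
  path <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(run, path)
  back <- read_run(path, "mgf")
  expect_equal(names(back$spectra), names(run$spectra))
  expect_equal(back$ms3_parent, run$ms3_parent)
  for (k in names(run$spectra)) {
    a <- run$spectra[[k]]; b <- back$spectra[[k]]
    expect_equal(b$ms_level, a$ms_level)
    expect_equal(b$precursor_charge, a$precursor_charge)
    expect_equal(b$sps_mz, a$sps_mz, tolerance = 1e-6)
    expect_equal(length(b$mz), length(a$mz))
    if (length(a$mz)) expect_lt(max(abs(b$mz - a$mz)), 1e-5)
  }
  # empty run round-trips to a valid empty file
  p2 <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(scan_hierarchy(list()), p2)
  expect_equal(length(read_run(p2, "mgf")$spectra), 0L)
  # 1000-peak spectrum
  set.seed(9)
  big <- scan_hierarchy(list(spectrum(1, 2, mz = sort(runif(1000, 100, 2000)),
                                      intensity = runif(1000, 1, 1e7),
                                      precursor_mz = 900.12345)))
  p3 <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(big, p3)
  expect_lt(max(abs(read_run(p3, "mgf")$spectra[["1"]]$mz -
                      big$spectra[["1"]]$mz)), 1e-5)
  expect_error(write_mgf(run, file.path(tempdir(), "no/such/dir/x.mgf")),
               "write")
})

test_that("unsorted MGF peak lists are sorted on load", {
  path <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "SCANS=1", "MSLEVEL=2", "PEPMASS=500.25",
               "CHARGE=2+", "900.5 10", "300.2 5", "600.1 7", "END IONS"),
             path)
  s <- read_run(path, "mgf")$spectra[["1"]]
  expect_equal(s$mz, c(300.2, 600.1, 900.5))
  expect_equal(s$intensity, c(5, 7, 10))
})

test_that("malformed MGF and missing files raise parse errors", {
  path <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "MSLEVEL=2", "100 1", "END IONS"), path)
  expect_error(read_run(path, "mgf"), "SCANS")
  expect_error(read_run(file.path(tempdir(), "absent.mgf")), "not found")
})

test_that("mzML reader recovers the scan hierarchy via CV terms", {
  b64 <- function(x, compress = FALSE) {
    raw <- writeBin(as.numeric(x), raw(), size = 8, endian = "little")
    if (compress) raw <- memCompress(raw, "gzip")
    jsonlite::base64_enc(raw)
  }
  arr <- function(vals, acc, compress = FALSE) paste0(
    "<binaryDataArray><cvParam accession=\"MS:1000523\" name=\"64-bit float\"/>",
    if (compress) "<cvParam accession=\"MS:1000574\" name=\"zlib compression\"/>" else
      "<cvParam accession=\"MS:1000576\" name=\"no compression\"/>",
    "<cvParam accession=\"", acc, "\" name=\"array\"/>",
    "<binary>", b64(vals, compress), "</binary></binaryDataArray>")
  spec_xml <- function(scan, level, mz, int, extra = "") paste0(
    "<spectrum id=\"scan=", scan, "\" index=\"", scan - 1,
    "\" defaultArrayLength=\"", length(mz), "\">",
    "<cvParam accession=\"MS:1000511\" name=\"ms level\" value=\"", level, "\"/>",
    "<scanList><scan><cvParam accession=\"MS:1000016\" name=\"scan start time\"",
    " value=\"1.5\" unitName=\"minute\"/></scan></scanList>", extra,
    "<binaryDataArrayList count=\"2\">",
    arr(mz, "MS:1000514", compress = scan == 1), arr(int, "MS:1000515"),
    "</binaryDataArrayList></spectrum>")
  prec <- function(ref, mz, z) paste0(
    "<precursorList count=\"1\"><precursor spectrumRef=\"scan=", ref, "\">",
    "<isolationWindow><cvParam accession=\"MS:1000827\" name=\"target\" value=\"",
    mz, "\"/><cvParam accession=\"MS:1000828\" name=\"offset\" value=\"0.8\"/>",
    "</isolationWindow><selectedIonList count=\"1\"><selectedIon>",
    "<cvParam accession=\"MS:1000744\" name=\"selected ion m/z\" value=\"", mz,
    "\"/><cvParam accession=\"MS:1000041\" name=\"charge state\" value=\"", z,
    "\"/></selectedIon></selectedIonList></precursor></precursorList>")
  sps_prec <- function(ref, mzs, prec_mz, z) paste0(
    "<precursorList count=\"", length(mzs), "\">",
    paste0("<precursor spectrumRef=\"scan=", ref, "\"><isolationWindow>",
           "<cvParam accession=\"MS:1000827\" name=\"target\" value=\"", mzs,
           "\"/></isolationWindow><selectedIonList><selectedIon>",
           "<cvParam accession=\"MS:1000744\" name=\"selected ion m/z\" value=\"",
           prec_mz, "\"/><cvParam accession=\"MS:1000041\" name=\"charge state\"",
           " value=\"", z, "\"/></selectedIon></selectedIonList></precursor>",
           collapse = ""),
    "</precursorList>")
  doc <- paste0(
    "<?xml version=\"1.0\"?><mzML xmlns=\"http://psi.hupo.org/ms/mzml\">",
    "<run id=\"r\"><spectrumList count=\"3\">",
    spec_xml(1, 1, c(500.0, 500.5017), c(100, 80)),
    spec_xml(2, 2, c(300.1, 800.2), c(10, 50), prec(1, 500.0, 2)),
    spec_xml(3, 3, c(126.12773, 300.1), c(400, 9), sps_prec(2, c(800.2, 900.3), 500.0, 2)),
    "</spectrumList></run></mzML>")
  path <- withr::local_tempfile(fileext = ".mzML")
  writeLines(doc, path)
  run <- read_run(path, "mzml")
  expect_equal(length(run$spectra), 3L)
  expect_equal(run$spectra[["1"]]$mz, c(500.0, 500.5017))  # zlib array
  expect_equal(run$spectra[["1"]]$retention_time, 90)      # minutes -> s
  s2 <- run$spectra[["2"]]
  expect_equal(s2$ms_level, 2L)
  expect_equal(s2$precursor_mz, 500.0)
  expect_equal(s2$precursor_charge, 2L)
  expect_equal(s2$parent_scan, 1L)
  expect_equal(s2$isolation_width, 1.6)
  s3 <- run$spectra[["3"]]
  expect_equal(s3$sps_mz, c(800.2, 900.3))
  expect_equal(run$ms3_parent, c("3" = 2L))
})
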