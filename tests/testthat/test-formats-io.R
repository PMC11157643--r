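test_that("clone tables round-trip losslessly", {
  tf <- withr::local_tempfile(fileext = ".tsv")

  p3 <- mk_profile(c(46000.123456, 47500.5, 48999.99), c(1000, 500, 20),
                   rt = c(12.345, 14, 16))
  write_clone_table(p3, tf)
  lines <- readLines(tf)
  expect_length(lines, 4L)  # header + 3 data rows
  expect_identical(lines[1], "clone_id\tmass_da\trt_min\tintensity\tn_slices")

  back <- read_clone_table(tf)
  expect_equal(back$mass_da, p3$mass_da, tolerance = 1e-9)
  expect_equal(back$rt_min, p3$rt_min, tolerance = 1e-9)
  expect_equal(back$intensity, p3$intensity, tolerance = 1e-9)

  # donor-scale table: ~820 clones, as in a real serum profile
  big <- withr::with_seed(99, mk_profile(
    sort(runif(820, 45000, 52000)), 10^runif(820, 2, 6),
    rt = runif(820, 10, 50)
  ))
  write_clone_table(big, tf)
  back <- read_clone_table(tf)
  expect_equal(nrow(back), 820L)
  expect_equal(back$mass_da, big$mass_da, tolerance = 1e-9)
})

test_that("malformed clone tables give schema errors naming the problem row", {
  tf <- withr::local_tempfile(fileext = ".tsv")

  neg <- mk_profile(c(46000, 47000), c(100, -5))
  expect_error(write_clone_table(neg, tf), "negative intensity.*row 2")

  writeLines(c("clone_id\tmass_da\trt_min\tintensity\tn_slices",
               "1\t46000\t12\t100\t1",
               "2\t47e00x\t13\t50\t1"), tf)
  expect_error(read_clone_table(tf), "row 2")

  writeLines(c("clone_id\tmass_da\trt_min", "1\t46000\t12"), tf)
  expect_error(read_clone_table(tf), "expected exactly columns")

  writeLines(c("clone_id\tmass_da\trt_min\tintensity\tn_slices",
               "1\t46000\t12\t-3\t1"), tf)
  expect_error(read_clone_table(tf), "negative intensity.*row 1")
})

test_that("similarity matrices round-trip through CSV", {
  profs <- list(a = mk_profile(c(46000, 47000), c(10, 5)),
                b = mk_profile(c(46000.5, 48000), c(8, 2)),
                c = mk_profile(c(50000), c(1)))
  sim <- similarity_matrix(profs)
  tf <- withr::local_tempfile(fileext = ".csv")
  write_similarity(sim, tf)
  back <- read_similarity(tf)
  expect_identical(back$sample_ids, sim$sample_ids)
  expect_equal(back$scores, sim$scores, tolerance = 1e-12)
})

test_that("mzML round-trip preserves scans, retention times and intensities", {
  cfg <- small_config()
  rep1 <- make_repertoire(2, mass_range = c(46200, 47800),
                          rt_window = c(10.1, 10.4), seed = 5)
  run <- render_run(rep1, cfg, rt_range = c(10, 10.5), noise_sigma = 0,
                    baseline_amplitude = 0, mz_spacing = 0.5, seed = 6)
  tf <- withr::local_tempfile(fileext = ".mzML")
  write_mzml(run, tf)
  back <- read_mzml(tf)
  expect_equal(nrow(back$scans), nrow(run$scans))
  expect_equal(back$scans$rt_min, run$scans$rt_min, tolerance = 1e-9)
  expect_gt(min(diff(back$scans$rt_min)), 0)
  i <- 7L
  expect_equal(back$scans$spectrum[[i]]$mz, run$scans$spectrum[[i]]$mz,
               tolerance = 1e-9)
  expect_equal(back$scans$spectrum[[i]]$intensity,
               run$scans$spectrum[[i]]$intensity, tolerance = 1e-6)
})

test_that("reading is insensitive to scan order in the file", {
  mzs <- seq(1000, 1010, by = 0.5)
  mk_pk <- function(scale) cbind(mz = mzs, intensity = scale * seq_along(mzs))
  pks <- lapply(c(3, 1, 2), mk_pk)
  rts <- c(30, 10, 20) * 60  # seconds, deliberately unsorted in the file
  hdr <- data.frame(
    seqNum = 1:3, acquisitionNum = 1:3, msLevel = 1L, polarity = 1L,
    peaksCount = length(mzs), totIonCurrent = 1, retentionTime = rts,
    basePeakMZ = 1000, basePeakIntensity = 1, collisionEnergy = 0,
    ionisationEnergy = 0, lowMZ = 1000, highMZ = 1010,
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", 1:3), centroided = FALSE,
    ionMobilityDriftTime = NA_real_, isolationWindowTargetMZ = NA_real_,
    isolationWindowLowerOffset = NA_real_, isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = 1000, scanWindowUpperLimit = 1010
  )
  tf <- withr::local_tempfile(fileext = ".mzML")
  mzR::writeMSData(pks, tf, header = hdr)
  run <- read_mzml(tf)
  expect_equal(run$scans$rt_min, c(10, 20, 30))
  # the scan now first is the one that was stored second (RT 10, scale 1)
  expect_equal(run$scans$spectrum[[1]]$intensity, 1 * seq_along(mzs),
               tolerance = 1e-6)
})

test_that("files without MS1 spectra and unreadable files are rejected", {
  tf <- withr::local_tempfile(fileext = ".mzML")
  writeLines("this is not an mzML document", tf)
  expect_error(read_mzml(tf), "parse|MS1")

  expect_error(read_mzml(file.path(tempdir(), "absent.mzML")), "not found")

  # a file holding only MS2 spectra is useless to an MS1-only pipeline
  pk <- cbind(mz = c(200, 300, 400), intensity = c(1, 2, 1))
  hdr <- data.frame(
    seqNum = 1L, acquisitionNum = 1L, msLevel = 2L, polarity = 1L,
    peaksCount = 3L, totIonCurrent = 4, retentionTime = 600,
    basePeakMZ = 300, basePeakIntensity = 2, collisionEnergy = 25,
    ionisationEnergy = 0, lowMZ = 200, highMZ = 400,
    precursorScanNum = 0L, precursorMZ = 800, precursorCharge = 2L,
    precursorIntensity = 100, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_, spectrumId = "scan=1",
    centroided = TRUE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = 800, isolationWindowLowerOffset = 1,
    isolationWindowUpperOffset = 1,
    scanWindowLowerLimit = 200, scanWindowUpperLimit = 400
  )
  tf2 <- withr::local_tempfile(fileext = ".mzML")
  mzR::writeMSData(list(pk), tf2, header = hdr)
  expect_error(read_mzml(tf2), "no MS1 spectra")
})
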