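test_that("sliding windows stride, overlap, clip and cover as specified", {
  w <- make_slices(10, 50, 0.3, 0.05)
  expect_equal(nrow(w), 160L)  # ceil((40 - 0.3)/0.25) + 1
  expect_equal(w$rt_start[1], 10)
  expect_equal(w$rt_end[1], 10.3)
  expect_equal(unique(round(diff(w$rt_start), 10)), 0.25)
  expect_equal(w$rt_end[160], 50)
  # every unclipped adjacent pair overlaps by exactly 0.05 min
  ov <- w$rt_end[-160] - w$rt_start[-1]
  expect_true(all(abs(ov[-length(ov)] - 0.05) < 1e-9))
  # exact coverage of the region of interest
  expect_equal(min(w$rt_start), 10)
  expect_equal(max(w$rt_end), 50)
  expect_true(all(w$rt_start[-1] <= w$rt_end[-160]))

  one <- make_slices(0, 0.3, 0.3, 0.05)
  expect_equal(nrow(one), 1L)
  expect_equal(c(one$rt_start, one$rt_end), c(0, 0.3))

  short <- make_slices(0, 0.2, 0.3, 0.05)
  expect_equal(nrow(short), 1L)
  expect_equal(short$rt_end, 0.2)
})

test_that("each in-ROI scan falls in >= 1 window, overlap-strip scans in exactly 2", {
  w <- make_slices(10, 50, 0.3, 0.05)
  rts <- withr::with_seed(31, runif(500, 10, 50 - 1e-9))
  counts <- vapply(rts, function(t) {
    sum(t >= w$rt_start & t < w$rt_end)
  }, 0L)
  expect_true(all(counts >= 1L))
  in_overlap <- vapply(rts, function(t) {
    any(t >= w$rt_start[-1] & t < w$rt_end[-nrow(w)])
  }, TRUE)
  expect_true(all(counts[in_overlap] == 2L))
  expect_true(all(counts[!in_overlap] == 1L))
})

test_that("slice averaging is the point-wise mean and flags empty windows", {
  grid <- seq(1000, 1010, by = 0.5)
  sp1 <- tibble::tibble(mz = grid, intensity = rep(0, length(grid)))
  sp2 <- tibble::tibble(mz = grid, intensity = rep(10, length(grid)))
  run <- fab_run(c(10.0, 10.1), list(sp1, sp2))

  avg <- average_slice(run, 10, 10.2, grid)
  expect_equal(attr(avg, "n_scans"), 2L)
  expect_equal(avg$intensity, rep(5, length(grid)))

  same <- fab_run(c(10.0, 10.1), list(sp2, sp2))
  avg2 <- average_slice(same, 10, 10.2, grid)
  expect_equal(avg2$intensity, sp2$intensity)

  none <- average_slice(run, 20, 20.3, grid)
  expect_equal(attr(none, "n_scans"), 0L)
  expect_true(all(none$intensity == 0))

  # half-open windows: a scan at exactly rt_end is excluded unless closed_end
  edge <- average_slice(run, 9.9, 10.1, grid)
  expect_equal(attr(edge, "n_scans"), 1L)
  edge2 <- average_slice(run, 9.9, 10.1, grid, closed_end = TRUE)
  expect_equal(attr(edge2, "n_scans"), 2L)
})

test_that("averaging is scale-equivariant", {
  cfg <- small_config()
  rep2 <- make_repertoire(2, mass_range = c(46200, 47800),
                          rt_window = c(10.2, 10.8), seed = 12)
  r1 <- render_run(rep2, cfg, rt_range = c(10, 11), noise_sigma = 0,
                   baseline_amplitude = 50, mz_spacing = 0.5)
  r3 <- r1
  r3$scans$spectrum <- lapply(r1$scans$spectrum, function(s) {
    tibble::tibble(mz = s$mz, intensity = 3 * s$intensity)
  })
  grid <- seq(cfg$mz_low, cfg$mz_high, by = 0.5)
  a1 <- average_slice(r1, 10.25, 10.55, grid)
  a3 <- average_slice(r3, 10.25, 10.55, grid)
  expect_equal(a3$intensity, 3 * a1$intensity, tolerance = 1e-12)
})

test_that("baseline subtraction removes flat and broad backgrounds, keeps narrow peaks", {
  grid <- seq(500, 3000, by = 0.1)

  flat <- tibble::tibble(mz = grid, intensity = rep(200, length(grid)))
  out <- subtract_baseline(flat, 0.8)
  expect_true(all(out$intensity < 0.05 * 200))

  zero <- tibble::tibble(mz = grid, intensity = rep(0, length(grid)))
  expect_equal(subtract_baseline(zero, 0.8)$intensity, zero$intensity)

  # narrow Gaussian peak (FWHM 0.2 Th) riding a broad hump (FWHM 800 Th)
  peak <- 1000 * exp(-0.5 * ((grid - 1500) / (0.2 / 2.3548))^2)
  hump <- 500 * exp(-0.5 * ((grid - 1500) / (800 / 2.3548))^2)
  both <- tibble::tibble(mz = grid, intensity = peak + hump)
  sub <- subtract_baseline(both, 0.8)
  apex <- which.max(peak)
  expect_lt(abs(sub$intensity[apex] - peak[apex]) / peak[apex], 0.05)

  expect_error(subtract_baseline(flat, 0), "flatness")
  expect_error(subtract_baseline(flat, 1.2), "flatness")
})

test_that("higher flatness gives a stiffer, flatter baseline estimate", {
  # a stiffer baseline hugs a broad hump less closely, so the intensity it
  # leaves behind grows monotonically with flatness
  grid <- seq(500, 3000, by = 0.1)
  hump <- 500 * exp(-0.5 * ((grid - 1500) / (800 / 2.3548))^2)
  sp <- tibble::tibble(mz = grid, intensity = hump)
  leftover <- vapply(c(0.2, 0.4, 0.6, 0.8, 1.0), function(f) {
    sum(subtract_baseline(sp, f)$intensity)
  }, 0)
  expect_true(all(diff(leftover) > 0))
})

test_that("Gaussian smoothing conserves intensity, is identity at 0 iterations, denoises", {
  grid <- seq(1000, 1100, by = 0.1)
  y <- withr::with_seed(17, abs(rnorm(length(grid), 100, 20)))
  sp <- tibble::tibble(mz = grid, intensity = y)

  expect_equal(smooth_spectrum(sp, 0.2, 0)$intensity, y)

  delta <- tibble::tibble(mz = grid, intensity = rep(0, length(grid)))
  delta$intensity[500] <- 1000
  sm <- smooth_spectrum(delta, 0.2, 1)
  expect_equal(sum(sm$intensity), 1000, tolerance = 1e-3)
  expect_lt(max(sm$intensity), 1000)
  expect_equal(grid[which.max(sm$intensity)], grid[500])

  noisy <- smooth_spectrum(sp, 0.2, 1)
  expect_lt(var(noisy$intensity), var(y))
  # total conserved away from edges
  expect_equal(sum(noisy$intensity[50:950]), sum(y[50:950]), tolerance = 2e-3)
})

test_that("preprocessing applies average -> baseline -> smooth per slice and skips empty ones", {
  cfg <- small_config()
  rep1 <- make_repertoire(1, mass_range = c(46500, 47500),
                          rt_window = c(10.1, 10.3), seed = 13)
  run <- render_run(rep1, cfg, rt_range = c(10, 10.6), noise_sigma = 0,
                    baseline_amplitude = 300, seed = 14)
  sl <- preprocess_run(run, cfg)
  expect_equal(nrow(sl), nrow(make_slices(cfg$roi_start, cfg$roi_end,
                                          cfg$slice_width, cfg$slice_overlap)))
  # scans end at 10.6: later windows are empty and flagged
  expect_true(any(sl$empty))
  expect_true(all(vapply(sl$spectrum[sl$empty],
                         function(s) all(s$intensity == 0), TRUE)))
  active <- which(!sl$empty)[1]
  sp <- sl$spectrum[[active]]
  # identical to applying the stages by hand in the documented order
  grid <- sp$mz
  by_hand <- average_slice(run, sl$rt_start[active], sl$rt_end[active], grid)
  by_hand <- subtract_baseline(by_hand, cfg$baseline_flatness)
  by_hand <- smooth_spectrum(by_hand, cfg$smooth_width, cfg$smooth_iterations)
  expect_equal(sp$intensity, by_hand$intensity, tolerance = 1e-12)
})
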