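# Shared fixtures. Unit tests run on a narrowed configuration (smaller mass
# window and charge range) so forward models build in a couple of seconds;
# the acceptance suite uses the full published settings.

small_config <- function(...) {
  fab_config(
    roi_start = 10, roi_end = 11,
    mz_low = 1000, mz_high = 2500,
    mass_low = 46000, mass_high = 48000,
    charge_min = 22, charge_max = 42,
    ...
  )
}

# Direct forward render of one species' charge envelope onto a uniform m/z
# grid (no chromatography): unit-height Gaussians at mz_of(mass, z), charge
# weights from a truncated discrete Gaussian. Kept independent of render_run.
render_envelope <- function(mass, config, abundance = 1e8,
                            charge_lo = 22, charge_hi = 42,
                            charge_center = 32, charge_sigma = 4,
                            grid_spacing = 0.1, trunc_sigma = 4) {
  grid <- seq(config$mz_low, config$mz_high, by = grid_spacing)
  y <- numeric(length(grid))
  zv <- charge_lo:charge_hi
  w <- dnorm(zv, charge_center, charge_sigma)
  w <- w / sum(w)
  for (k in seq_along(zv)) {
    ctr <- (mass + zv[k] * config$proton_mass) / zv[k]
    if (ctr < config$mz_low || ctr > config$mz_high) next
    sg <- ctr / (config$instrument_resolving_power * 2.3548200450309493)
    j <- which(abs(grid - ctr) <= trunc_sigma * sg)
    y[j] <- y[j] + abundance * w[k] * exp(-0.5 * ((grid[j] - ctr) / sg)^2)
  }
  tibble::tibble(mz = grid, intensity = y)
}

# Oracle-view render: same species, sampled finely enough (and with wide
# enough peak support) that reading intensities off the trace does not alias;
# peak sigma is ~0.07 Th, so 0.02 Th sampling is comfortable.
render_envelope_fine <- function(mass, config, ...) {
  render_envelope(mass, config, grid_spacing = 0.02, trunc_sigma = 6, ...)
}

# Build a clonal profile tibble by hand.
mk_profile <- function(mass, intensity, rt = NULL, sample_id = "p") {
  n <- length(mass)
  rt <- rt %||% rep(15, n)
  structure(
    tibble::tibble(clone_id = seq_len(n), mass_da = mass, rt_min = rt,
                   intensity = intensity, n_slices = rep(1L, n)),
    sample_id = sample_id
  )
}

# Random peak tables for merge property tests.
random_peaks <- function(n, seed, n_slices = 10, mass_range = c(45000, 52000)) {
  withr::with_seed(seed, {
    tibble::tibble(
      mass_da = runif(n, mass_range[1], mass_range[2]),
      intensity = 10^runif(n, 2, 6),
      slice = sample.int(n_slices, n, replace = TRUE),
      slice_rt = NA_real_
    ) |>
      dplyr::mutate(slice_rt = 10 + slice * 0.25)
  })
}

# Three-point log-parabola interpolation of a sampled Gaussian apex: exact
# for noiseless Gaussians, used to read peak centres off a grid.
apex_interpolate <- function(x, y) {
  i <- which.max(y)
  if (i == 1L || i == length(y)) return(x[i])
  ly <- log(y[(i - 1):(i + 1)])
  denom <- ly[1] - 2 * ly[2] + ly[3]
  if (denom >= 0) return(x[i])
  x[i] + (x[2] - x[1]) * 0.5 * (ly[1] - ly[3]) / denom
}
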