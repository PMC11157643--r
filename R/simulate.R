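#' Simulate a clonal Fab repertoire
#'
#' Draws a set of synthetic Fab species emulating the circulating IgG1
#' repertoire of one donor. Masses are uniform over the Fab mass window,
#' abundances log-uniform over `abundance_range` (two orders of magnitude by
#' default), and elution times uniform over `rt_window`. Each clone carries a
#' truncated-Gaussian electrospray charge envelope; the default envelope
#' (centre 32, sd 4, truncated to 22--42) matches the charge range observed
#' for intact denatured Fabs.
#'
#' @param n_clones Number of clones to simulate (may be 0).
#' @param mass_range Mass window, Da.
#' @param rt_window Elution-centre window, minutes.
#' @param rt_sigma Gaussian elution peak sd, minutes.
#' @param abundance_range Abundance limits (log-uniform draw), arbitrary
#'   units; set both ends equal for an equimolar mixture.
#' @param charge_center,charge_sigma Mean and sd of the charge envelope.
#' @param charge_range Integer truncation bounds of the charge envelope.
#' @param min_gap_ppm If > 0, enforce a minimum pairwise mass gap (ppm of the
#'   smaller mass) by per-clone rejection sampling; draws remain
#'   deterministic given `seed`.
#' @param seed Integer seed; identical seeds give identical repertoires.
#' @return A tibble of class `fab_repertoire` with one row per clone:
#'   `clone`, `true_mass` (Da), `rt_center`, `rt_sigma` (min), `abundance`,
#'   `charge_center`, `charge_sigma`, `charge_lo`, `charge_hi`.
#' @export
#' @examples
#' rep3 <- make_repertoire(3, abundance_range = c(1e6, 1e6), seed = 7)
#' rep3$true_mass
make_repertoire <- function(n_clones,
                            mass_range = c(45000, 52000),
                            rt_window = c(10, 20),
                            rt_sigma = 0.1,
                            abundance_range = c(1e6, 1e8),
                            charge_center = 32,
                            charge_sigma = 4,
                            charge_range = c(22, 42),
                            min_gap_ppm = 0,
                            seed = NULL) {
  stopifnot(n_clones >= 0, rt_sigma > 0, min_gap_ppm >= 0,
            mass_range[1] < mass_range[2], rt_window[1] < rt_window[2],
            all(abundance_range > 0), charge_range[1] <= charge_range[2])
  draw <- function() {
    masses <- numeric(n_clones)
    for (i in seq_len(n_clones)) {
      for (attempt in seq_len(10000L)) {
        m <- runif(1, mass_range[1], mass_range[2])
        if (i == 1L ||
            min(abs(masses[seq_len(i - 1L)] - m)) / m * 1e6 >= min_gap_ppm) {
          masses[i] <- m
          break
        }
        if (attempt == 10000L) {
          stop("could not place clone masses with the requested `min_gap_ppm`",
               call. = FALSE)
        }
      }
    }
    tibble::tibble(
      clone = seq_len(n_clones),
      true_mass = masses,
      rt_center = runif(n_clones, rt_window[1], rt_window[2]),
      rt_sigma = rep(rt_sigma, n_clones),
      abundance = exp(runif(n_clones, log(abundance_range[1]),
                            log(abundance_range[2]))),
      charge_center = rep(as.numeric(charge_center), n_clones),
      charge_sigma = rep(as.numeric(charge_sigma), n_clones),
      charge_lo = rep(as.integer(charge_range[1]), n_clones),
      charge_hi = rep(as.integer(charge_range[2]), n_clones)
    )
  }
  out <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  class(out) <- c("fab_repertoire", class(out))
  out
}

#' Render a repertoire to a synthetic LC-MS run
#'
#' Forward model of a denatured-Fab electrospray acquisition. For each scan
#' at time `t` and each clone, signal is added at
#' `m/z(z) = (true_mass + z * proton_mass) / z` for every charge `z` in the
#' clone's truncation bounds, weighted by a truncated discrete Gaussian over
#' `z` and by the clone's Gaussian elution profile
#' `exp(-(t - rt_center)^2 / (2 rt_sigma^2))`. Each charge peak is a Gaussian
#' in m/z with FWHM = (m/z) / `instrument_resolving_power` (isotopes are
#' unresolved at these settings, so average masses and single-Gaussian peaks
#' are used). An optional broad Gaussian baseline hump (the unresolved
#' background elevated in the 1000--2000 Th range) and additive half-normal
#' noise complete the scan.
#'
#' @param repertoire A [make_repertoire()] tibble.
#' @param config A [fab_config()]; supplies the m/z range, resolving power
#'   and proton mass.
#' @param rt_range Scan window, minutes; default covers every clone's
#'   elution centre with a 0.5 min margin.
#' @param scan_rate_hz Scans per second.
#' @param noise_sigma Sd of the additive half-normal noise per grid point
#'   (counts); 0 disables noise.
#' @param baseline_amplitude Apex height of the baseline hump (counts).
#' @param baseline_center,baseline_fwhm Centre and FWHM of the hump, Th.
#' @param mz_spacing Spacing of the rendered uniform m/z grid, Th.
#' @param run_id Identifier of the returned run.
#' @param path Optional path; if given, the run is also written as mzML.
#' @param seed Integer seed; identical parameters and seed give bit-identical
#'   runs.
#' @return A [fab_run()].
#' @export
render_run <- function(repertoire,
                       config = fab_config(),
                       rt_range = NULL,
                       scan_rate_hz = 1,
                       noise_sigma = 1000,
                       baseline_amplitude = 2000,
                       baseline_center = 1500,
                       baseline_fwhm = 800,
                       mz_spacing = 0.1,
                       run_id = "simulated",
                       path = NULL,
                       seed = NULL) {
  stopifnot(inherits(repertoire, "data.frame"), scan_rate_hz > 0,
            noise_sigma >= 0, baseline_amplitude >= 0, mz_spacing > 0)
  grid <- seq(config$mz_low, config$mz_high, by = mz_spacing)
  if (length(grid) < 2L) stop("empty m/z grid", call. = FALSE)
  if (is.null(rt_range)) {
    rt_range <- if (nrow(repertoire)) {
      range(repertoire$rt_center) + c(-0.5, 0.5)
    } else {
      c(0, 1)
    }
  }
  n_scans <- max(1L, floor((rt_range[2] - rt_range[1]) * 60 * scan_rate_hz))
  times <- rt_range[1] + (seq_len(n_scans) - 1L) / (60 * scan_rate_hz)

  render <- function() {
    X <- matrix(0, nrow = length(grid), ncol = n_scans)
    for (i in seq_len(nrow(repertoire))) {
      cl <- repertoire[i, ]
      zv <- seq.int(cl$charge_lo, cl$charge_hi)
      wz <- dnorm(zv, cl$charge_center, cl$charge_sigma)
      wz <- wz / sum(wz)
      prof <- numeric(length(grid))
      hit <- FALSE
      for (k in seq_along(zv)) {
        ctr <- (cl$true_mass + zv[k] * config$proton_mass) / zv[k]
        if (ctr < config$mz_low || ctr > config$mz_high) next
        hit <- TRUE
        sg <- ctr / (config$instrument_resolving_power * 2.3548200450309493)
        jj <- which(abs(grid - ctr) <= 4 * sg)
        prof[jj] <- prof[jj] + wz[k] * exp(-0.5 * ((grid[jj] - ctr) / sg)^2)
      }
      if (!hit) {
        warning(sprintf("clone %d (mass %.1f Da): charge envelope entirely outside the m/z range; skipped",
                        cl$clone, cl$true_mass), call. = FALSE)
        next
      }
      elut <- exp(-0.5 * ((times - cl$rt_center) / cl$rt_sigma)^2)
      active_t <- which(elut > 1e-8)
      supp <- which(prof > 0)
      if (length(active_t) && length(supp)) {
        X[supp, active_t] <- X[supp, active_t] +
          cl$abundance * outer(prof[supp], elut[active_t])
      }
    }
    if (baseline_amplitude > 0) {
      bsg <- baseline_fwhm / 2.3548200450309493
      X <- X + baseline_amplitude * exp(-0.5 * ((grid - baseline_center) / bsg)^2)
    }
    if (noise_sigma > 0) {
      X <- X + abs(rnorm(length(X), 0, noise_sigma))
    }
    X
  }
  X <- if (is.null(seed)) render() else withr::with_seed(seed, render())

  spectra <- lapply(seq_len(n_scans), function(j) {
    tibble::tibble(mz = grid, intensity = X[, j])
  })
  run <- fab_run(
    rt_min = times, spectra = spectra, run_id = run_id,
    metadata = list(mz_low = config$mz_low, mz_high = config$mz_high,
                    scan_rate_hz = scan_rate_hz, centroided = FALSE,
                    source = "synthetic")
  )
  if (!is.null(path)) write_mzml(run, path)
  run
}

#' Ground-truth clone table of a simulated repertoire
#'
#' Passes the simulated species through unchanged as a clonal profile
#' (intensity = simulated abundance), so pipeline output can be scored for
#' recall, precision and mass accuracy against known truth.
#'
#' @param repertoire A [make_repertoire()] tibble.
#' @param sample_id Sample identifier for the profile.
#' @return A `fab_profile` tibble (see [merge_slices()]).
#' @export
ground_truth_table <- function(repertoire, sample_id = "truth") {
  stopifnot(inherits(repertoire, "data.frame"))
  tab <- tibble::tibble(
    mass_da = repertoire$true_mass,
    rt_min = repertoire$rt_center,
    intensity = repertoire$abundance,
    n_slices = 1L
  )
  tab <- dplyr::arrange(tab, dplyr::desc(.data$intensity), .data$mass_da)
  new_fab_profile(
    tibble::tibble(clone_id = seq_len(nrow(tab)), tab),
    sample_id = sample_id, source = "ground truth"
  )
}

#' Add measurement noise to a clonal profile
#'
#' Profile-level emulation of run-to-run variability: clone masses are
#' jittered with Gaussian error, intensities multiplied by log-normal noise,
#' and a small fraction of clones dropped at random. This is a fast stand-in
#' for rendering and re-profiling a run when only the statistical behaviour
#' of profile comparison is under study.
#'
#' @param profile A clonal profile tibble (`clone_id`, `mass_da`, `rt_min`,
#'   `intensity`, `n_slices`).
#' @param mass_sd Sd of the mass jitter, Da.
#' @param intensity_cv Sd of the log-intensity noise.
#' @param dropout Per-clone drop probability.
#' @param seed Integer seed.
#' @return A `fab_profile` tibble, re-sorted by descending intensity.
#' @export
perturb_profile <- function(profile, mass_sd = 0.5, intensity_cv = 0.2,
                            dropout = 0.05, seed = NULL) {
  stopifnot(mass_sd >= 0, intensity_cv >= 0, dropout >= 0, dropout < 1)
  jitter <- function() {
    keep <- runif(nrow(profile)) >= dropout
    out <- tibble::tibble(
      mass_da = profile$mass_da[keep] + rnorm(sum(keep), 0, mass_sd),
      rt_min = profile$rt_min[keep],
      intensity = profile$intensity[keep] *
        exp(rnorm(sum(keep), 0, intensity_cv)),
      n_slices = profile$n_slices[keep]
    )
    dplyr::arrange(out, dplyr::desc(.data$intensity), .data$mass_da)
  }
  out <- if (is.null(seed)) jitter() else withr::with_seed(seed, jitter())
  new_fab_profile(
    tibble::tibble(clone_id = seq_len(nrow(out)), out),
    sample_id = paste0(attr(profile, "sample_id") %||% "profile", "+noise"),
    source = "perturbed"
  )
}
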