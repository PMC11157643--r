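#' Sliding retention-time windows over the region of interest
#'
#' Partitions `[roi_start, roi_end]` into overlapping slices. Window `k`
#' starts at `roi_start + k * (slice_width - slice_overlap)`; generation
#' stops once coverage reaches `roi_end`, and the final window is clipped to
#' end exactly at `roi_end`. The published settings (10--50 min, 0.3 min
#' windows, 0.05 min overlap) give 160 windows.
#'
#' @param roi_start,roi_end Region of interest, minutes.
#' @param slice_width Window width, minutes.
#' @param slice_overlap Overlap of consecutive windows, minutes.
#' @return A tibble with columns `slice`, `rt_start`, `rt_end`.
#' @export
#' @examples
#' nrow(make_slices(10, 50, 0.3, 0.05))
make_slices <- function(roi_start = 10, roi_end = 50,
                        slice_width = 0.3, slice_overlap = 0.05) {
  stopifnot(roi_start < roi_end, slice_overlap > 0,
            slice_overlap < slice_width)
  stride <- slice_width - slice_overlap
  starts <- numeric(0)
  k <- 0L
  repeat {
    s <- roi_start + k * stride
    starts <- c(starts, s)
    if (s + slice_width >= roi_end) break
    k <- k + 1L
  }
  tibble::tibble(
    slice = seq_along(starts),
    rt_start = starts,
    rt_end = pmin(starts + slice_width, roi_end)
  )
}

resample_spectrum <- function(spectrum, grid) {
  if (length(spectrum$mz) == length(grid) &&
      isTRUE(all.equal(spectrum$mz, grid, tolerance = 1e-9))) {
    return(spectrum$intensity)
  }
  if (length(spectrum$mz) < 2L) return(numeric(length(grid)))
  approx(spectrum$mz, spectrum$intensity, xout = grid,
         method = "linear", yleft = 0, yright = 0)$y
}

#' Average the scans of one retention-time window
#'
#' Point-wise arithmetic mean of all scans with retention time in
#' `[rt_start, rt_end)` (set `closed_end = TRUE` for the final, clipped
#' window so a scan at exactly `roi_end` is included there and only there).
#' Scans are resampled to the uniform m/z `grid` by linear interpolation
#' before averaging.
#'
#' @param run A [fab_run()].
#' @param rt_start,rt_end Window bounds, minutes.
#' @param grid Uniform m/z grid, Th.
#' @param closed_end Include scans at exactly `rt_end`?
#' @return A tibble with columns `mz`, `intensity`; the number of averaged
#'   scans is recorded in attribute `n_scans` (0 flags an empty window whose
#'   spectrum is all zero).
#' @export
average_slice <- function(run, rt_start, rt_end, grid, closed_end = FALSE) {
  stopifnot(inherits(run, "fab_run"))
  rt <- run$scans$rt_min
  sel <- if (closed_end) rt >= rt_start & rt <= rt_end else rt >= rt_start & rt < rt_end
  idx <- which(sel)
  out <- if (length(idx) == 0L) {
    numeric(length(grid))
  } else {
    acc <- numeric(length(grid))
    for (i in idx) acc <- acc + resample_spectrum(run$scans$spectrum[[i]], grid)
    acc / length(idx)
  }
  res <- tibble::tibble(mz = grid, intensity = out)
  attr(res, "n_scans") <- length(idx)
  res
}

# Asymmetric least squares baseline (Eilers): minimise
# sum_i w_i (y_i - b_i)^2 + lambda * sum (d2 b)^2 with w small above the
# baseline, re-estimating w a few times. lambda is set from the flatness
# length scale; solves are banded sparse Cholesky.
als_baseline <- function(y, lambda, p = 0.05, iterations = 10) {
  n <- length(y)
  if (n < 5L) return(rep(min(y), n))
  D2 <- Matrix::bandSparse(n - 2L, n,
                           k = 0:2,
                           diagonals = list(rep(1, n - 2L), rep(-2, n - 2L),
                                            rep(1, n - 2L)))
  P <- lambda * Matrix::crossprod(D2)
  w <- rep(1, n)
  b <- y
  for (it in seq_len(iterations)) {
    C <- Matrix::Diagonal(n, x = w) + P
    b_new <- as.numeric(Matrix::solve(C, w * y))
    w_new <- ifelse(y > b_new, p, 1)
    if (isTRUE(all.equal(w_new, w))) {
      b <- b_new
      break
    }
    w <- w_new
    b <- b_new
  }
  b
}

#' Subtract a slowly varying baseline from a spectrum
#'
#' Estimates the unresolved background (e.g. the elevated hump in the
#' 1000--2000 Th range) by iterative asymmetric least squares smoothing and
#' subtracts it, clipping the result at zero. `flatness` in (0, 1] controls
#' the stiffness of the estimate: it is mapped log-linearly to the baseline
#' length scale over 10--1000 Th (`L = 10^(1 + 2 * flatness)` Th), taken as
#' the cutoff wavelength of the penalised smoother (`lambda = (L / (4 pi
#' d))^4` for grid spacing `d`), so higher flatness gives a stiffer, flatter
#' baseline. Narrow peaks (width far below the length scale) are preserved
#' to within a few percent of their height.
#'
#' @param spectrum A tibble with columns `mz` (uniformly spaced) and
#'   `intensity`.
#' @param flatness Baseline stiffness in (0, 1].
#' @return A tibble with columns `mz`, `intensity`.
#' @export
subtract_baseline <- function(spectrum, flatness = 0.8) {
  if (!(is.numeric(flatness) && length(flatness) == 1L &&
        flatness > 0 && flatness <= 1)) {
    stop("`flatness` must be a single number in (0, 1]", call. = FALSE)
  }
  y <- spectrum$intensity
  if (length(y) == 0L || all(y == 0)) {
    return(tibble::tibble(mz = spectrum$mz, intensity = y))
  }
  d <- if (length(spectrum$mz) > 1L) spectrum$mz[2] - spectrum$mz[1] else 1
  scale_th <- 10^(1 + 2 * flatness)
  lambda <- (scale_th / (4 * pi * d))^4
  b <- als_baseline(y, lambda)
  tibble::tibble(mz = spectrum$mz, intensity = pmax(y - b, 0))
}

#' Gaussian smoothing of a profile spectrum
#'
#' Convolves the intensity trace with a discrete Gaussian kernel of FWHM
#' `width` (sigma = width / 2.3548), applied `iterations` times. The kernel
#' is normalised to unit sum, so total intensity is conserved away from the
#' grid edges.
#'
#' @param spectrum A tibble with columns `mz` (uniformly spaced) and
#'   `intensity`.
#' @param width Kernel FWHM, Th.
#' @param iterations Number of passes; 0 returns the input unchanged.
#' @return A tibble with columns `mz`, `intensity`.
#' @export
smooth_spectrum <- function(spectrum, width = 0.2, iterations = 1) {
  stopifnot(width > 0, iterations >= 0)
  y <- spectrum$intensity
  if (iterations == 0L || length(y) < 2L) {
    return(tibble::tibble(mz = spectrum$mz, intensity = y))
  }
  d <- spectrum$mz[2] - spectrum$mz[1]
  sigma <- width / 2.3548200450309493
  half <- max(1L, ceiling(4 * sigma / d))
  kern <- dnorm((-half:half) * d, 0, sigma)
  kern <- kern / sum(kern)
  for (i in seq_len(iterations)) {
    padded <- c(numeric(half), y, numeric(half))
    y <- as.numeric(stats::filter(padded, kern, sides = 2))[(half + 1L):(half + length(spectrum$mz))]
  }
  tibble::tibble(mz = spectrum$mz, intensity = y)
}

#' Preprocess a run into averaged slice spectra
#'
#' Cuts the region of interest into sliding windows ([make_slices()]) and,
#' for each window, averages its scans, subtracts the baseline and smooths,
#' in that fixed order. Windows are half-open `[rt_start, rt_end)` except the
#' final one, which is closed so a scan at exactly `roi_end` belongs to it
#' alone. Windows containing no scans are flagged empty (all-zero spectrum)
#' and skipped downstream.
#'
#' @param run A [fab_run()].
#' @param config A [fab_config()].
#' @param grid_spacing Spacing of the common m/z grid the scans are resampled
#'   to, Th.
#' @return A tibble with one row per slice: `slice`, `rt_start`, `rt_end`,
#'   `rt_mid`, `n_scans`, `empty`, and a `spectrum` list-column of processed
#'   `mz`/`intensity` tibbles.
#' @export
preprocess_run <- function(run, config = fab_config(), grid_spacing = 0.1) {
  stopifnot(inherits(run, "fab_run"))
  grid <- seq(config$mz_low, config$mz_high, by = grid_spacing)
  windows <- make_slices(config$roi_start, config$roi_end,
                         config$slice_width, config$slice_overlap)
  n <- nrow(windows)
  spectra <- vector("list", n)
  n_scans <- integer(n)
  for (i in seq_len(n)) {
    avg <- average_slice(run, windows$rt_start[i], windows$rt_end[i], grid,
                         closed_end = (i == n))
    n_scans[i] <- attr(avg, "n_scans")
    if (n_scans[i] == 0L || all(avg$intensity == 0)) {
      spectra[[i]] <- tibble::tibble(mz = grid,
                                     intensity = numeric(length(grid)))
      next
    }
    sp <- subtract_baseline(avg, config$baseline_flatness)
    sp <- smooth_spectrum(sp, config$smooth_width, config$smooth_iterations)
    spectra[[i]] <- sp
  }
  dplyr::mutate(windows,
                rt_mid = (.data$rt_start + .data$rt_end) / 2,
                n_scans = n_scans,
                empty = n_scans == 0L,
                spectrum = spectra)
}
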