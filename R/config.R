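#' Pipeline configuration
#'
#' Builds the full set of processing parameters for the Fab-profiling
#' pipeline. Defaults reproduce the published timsTOF workflow settings:
#' a 10--50 min region of interest cut into 0.3 min sliding windows with
#' 0.05 min overlap, baseline flatness 0.8, one pass of Gaussian smoothing
#' with 0.2 Th width, deconvolution onto a 45--52 kDa mass grid at 0.1 Da
#' spacing with instrument resolving power 10000, Sum-Peak-style picking at
#' resolving power 6500 with an absolute intensity threshold of 500, and
#' slice merging at 50 ppm with no retention-time gap limit. Setting
#' `merge_ppm = 30` and `merge_max_rt_gap = 2` reproduces the Orbitrap-style
#' merge instead.
#'
#' @param roi_start,roi_end Region of interest in retention time, minutes.
#' @param slice_width Sliding-window width, minutes.
#' @param slice_overlap Overlap between consecutive windows, minutes; must be
#'   positive and smaller than `slice_width`.
#' @param baseline_flatness Baseline stiffness knob in (0, 1]; larger values
#'   give a flatter (stiffer) baseline estimate. See [subtract_baseline()].
#' @param smooth_width Gaussian smoothing width (FWHM), Th.
#' @param smooth_iterations Number of smoothing passes.
#' @param mz_low,mz_high Acquisition m/z range, Th.
#' @param mass_low,mass_high Deconvolution mass window, Da.
#' @param mass_spacing Mass grid spacing, Da.
#' @param instrument_resolving_power m/dm of the raw peaks; sets the forward
#'   model peak width FWHM = (m/z) / resolving power.
#' @param charge_min,charge_max Charge-state range considered by the
#'   deconvolution.
#' @param peak_resolving_power m/dm used by the peak picker to set the
#'   centroiding/merging window width = mass / `peak_resolving_power`.
#' @param peak_intensity_threshold Absolute apex-intensity threshold for mass
#'   peaks, deconvoluted counts.
#' @param merge_ppm Mass tolerance for merging per-slice peaks into clones,
#'   ppm.
#' @param merge_max_rt_gap Maximum retention-time gap (minutes) between a
#'   peak and the nearest member of the clone it joins; `Inf` disables the
#'   constraint (timsTOF-style merge).
#' @param similarity_top_n Number of most intense clones retained before
#'   cosine scoring.
#' @param similarity_tolerance Mass tolerance for clone matching in the
#'   cosine score, Da.
#' @param proton_mass Proton mass, Da.
#' @param deconv_tol Relative-change convergence tolerance of the
#'   multiplicative deconvolution updates.
#' @param deconv_max_iter Iteration cap for the deconvolution.
#'
#' @return A validated list of class `fab_config`.
#' @seealso [load_config()] to read a configuration file.
#' @export
#' @examples
#' cfg <- fab_config()
#' cfg$merge_ppm
#' orbi <- fab_config(merge_ppm = 30, merge_max_rt_gap = 2)
fab_config <- function(roi_start = 10,
                       roi_end = 50,
                       slice_width = 0.3,
                       slice_overlap = 0.05,
                       baseline_flatness = 0.8,
                       smooth_width = 0.2,
                       smooth_iterations = 1,
                       mz_low = 500,
                       mz_high = 3000,
                       mass_low = 45000,
                       mass_high = 52000,
                       mass_spacing = 0.1,
                       instrument_resolving_power = 10000,
                       charge_min = 12,
                       charge_max = 60,
                       peak_resolving_power = 6500,
                       peak_intensity_threshold = 500,
                       merge_ppm = 50,
                       merge_max_rt_gap = Inf,
                       similarity_top_n = 100,
                       similarity_tolerance = 1.5,
                       proton_mass = 1.007276,
                       deconv_tol = 1e-4,
                       deconv_max_iter = 100) {
  cfg <- list(
    roi_start = as.numeric(roi_start),
    roi_end = as.numeric(roi_end),
    slice_width = as.numeric(slice_width),
    slice_overlap = as.numeric(slice_overlap),
    baseline_flatness = as.numeric(baseline_flatness),
    smooth_width = as.numeric(smooth_width),
    smooth_iterations = as.integer(smooth_iterations),
    mz_low = as.numeric(mz_low),
    mz_high = as.numeric(mz_high),
    mass_low = as.numeric(mass_low),
    mass_high = as.numeric(mass_high),
    mass_spacing = as.numeric(mass_spacing),
    instrument_resolving_power = as.numeric(instrument_resolving_power),
    charge_min = as.integer(charge_min),
    charge_max = as.integer(charge_max),
    peak_resolving_power = as.numeric(peak_resolving_power),
    peak_intensity_threshold = as.numeric(peak_intensity_threshold),
    merge_ppm = as.numeric(merge_ppm),
    merge_max_rt_gap = as.numeric(merge_max_rt_gap),
    similarity_top_n = as.integer(similarity_top_n),
    similarity_tolerance = as.numeric(similarity_tolerance),
    proton_mass = as.numeric(proton_mass),
    deconv_tol = as.numeric(deconv_tol),
    deconv_max_iter = as.integer(deconv_max_iter)
  )
  class(cfg) <- "fab_config"
  validate_config(cfg)
}

#' @export
print.fab_config <- function(x, ...) {
  cat("<fab_config>\n")
  for (k in names(x)) cat(sprintf("  %-28s %s\n", k, format(x[[k]])))
  invisible(x)
}

validate_config <- function(cfg) {
  fail <- function(key, why) {
    stop(sprintf("invalid configuration: `%s` %s", key, why), call. = FALSE)
  }
  num1 <- function(key) {
    v <- cfg[[key]]
    if (length(v) != 1L || !is.numeric(v) || is.na(v)) {
      fail(key, "must be a single non-missing number")
    }
    v
  }
  for (k in setdiff(names(cfg), "merge_max_rt_gap")) {
    if (!is.finite(num1(k))) fail(k, "must be finite")
  }
  num1("merge_max_rt_gap")
  if (cfg$roi_start >= cfg$roi_end) fail("roi_start", "must be < roi_end")
  if (cfg$slice_overlap <= 0) fail("slice_overlap", "must be > 0")
  if (cfg$slice_overlap >= cfg$slice_width) {
    fail("slice_overlap", "must be < slice_width")
  }
  if (cfg$baseline_flatness <= 0 || cfg$baseline_flatness > 1) {
    fail("baseline_flatness", "must lie in (0, 1]")
  }
  if (cfg$smooth_width <= 0) fail("smooth_width", "must be > 0")
  if (cfg$smooth_iterations < 0) fail("smooth_iterations", "must be >= 0")
  if (cfg$mz_low >= cfg$mz_high) fail("mz_low", "must be < mz_high")
  if (cfg$mass_low >= cfg$mass_high) fail("mass_low", "must be < mass_high")
  if (cfg$mass_spacing <= 0) fail("mass_spacing", "must be > 0")
  if (cfg$instrument_resolving_power <= 0) {
    fail("instrument_resolving_power", "must be > 0")
  }
  if (cfg$charge_min < 1) fail("charge_min", "must be >= 1")
  if (cfg$charge_min > cfg$charge_max) fail("charge_min", "must be <= charge_max")
  if (cfg$peak_resolving_power <= 0) fail("peak_resolving_power", "must be > 0")
  if (cfg$merge_ppm <= 0) fail("merge_ppm", "must be > 0")
  if (cfg$merge_max_rt_gap <= 0) fail("merge_max_rt_gap", "must be > 0")
  if (cfg$similarity_top_n < 1) fail("similarity_top_n", "must be >= 1")
  if (cfg$similarity_tolerance <= 0) fail("similarity_tolerance", "must be > 0")
  if (cfg$proton_mass <= 0) fail("proton_mass", "must be > 0")
  if (cfg$deconv_tol <= 0) fail("deconv_tol", "must be > 0")
  if (cfg$deconv_max_iter < 1) fail("deconv_max_iter", "must be >= 1")
  cfg
}

fab_config_defaults <- function() {
  unclass(fab_config())
}

#' Load a pipeline configuration file
#'
#' Reads a flat key-value configuration file. The grammar is one `key = value`
#' pair per line; blank lines and lines starting with `#` are ignored. Keys
#' are the argument names of [fab_config()]. Any key not present takes its
#' timsTOF default, so an empty file yields the published default pipeline.
#' The value `Inf` (or `unbounded`) is accepted for `merge_max_rt_gap`.
#'
#' @param path Path to the configuration file.
#' @return A validated `fab_config`.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".cfg")
#' writeLines(c("# Orbitrap-style merge", "merge_ppm = 30", "merge_max_rt_gap = 2"), tf)
#' load_config(tf)$merge_ppm
load_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("configuration file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  known <- fab_config_defaults()
  overrides <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "=", fixed = TRUE)[[1]]
    if (length(parts) != 2L) {
      stop(sprintf("cannot parse configuration line %d: '%s' (expected 'key = value')",
                   i, lines[[i]]), call. = FALSE)
    }
    key <- trimws(parts[[1]])
    val <- trimws(parts[[2]])
    if (!key %in% names(known)) {
      stop(sprintf("unknown configuration key `%s` (line %d)", key, i), call. = FALSE)
    }
    num <- if (tolower(val) %in% c("inf", "unbounded")) Inf else suppressWarnings(as.numeric(val))
    if (is.na(num)) {
      stop(sprintf("non-numeric value for key `%s`: '%s'", key, val), call. = FALSE)
    }
    overrides[[key]] <- num
  }
  do.call(fab_config, overrides)
}

#' Configuration fingerprint
#'
#' Stable hash of a configuration, recorded in profile provenance and run
#' manifests so outputs can be traced to the exact parameter set.
#'
#' @param config A `fab_config`.
#' @return A character scalar.
#' @export
config_hash <- function(config) {
  stopifnot(inherits(config, "fab_config"))
  rlang::hash(unclass(config))
}
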