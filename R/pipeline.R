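#' Deconvolute preprocessed slices and pick mass peaks
#'
#' Runs [deconvolute()] and [pick_peaks()] on every non-empty slice of a
#' [preprocess_run()] result and stacks the picked peaks with their slice
#' provenance.
#'
#' @param slices Tibble from [preprocess_run()].
#' @param config A [fab_config()].
#' @param verbose Report per-slice peak counts?
#' @return A tibble with columns `mass_da`, `intensity`, `slice`, `slice_rt`.
#' @export
deconvolute_slices <- function(slices, config = fab_config(), verbose = FALSE) {
  # smoothing widens the observed peaks beyond the instrument width; the
  # inversion models the spectrum it is actually given
  extra_fwhm <- sqrt(config$smooth_iterations) * config$smooth_width
  out <- vector("list", nrow(slices))
  for (i in seq_len(nrow(slices))) {
    if (slices$empty[i] || all(slices$spectrum[[i]]$intensity == 0)) next
    ms <- deconvolute(slices$spectrum[[i]], config, extra_fwhm = extra_fwhm)
    pk <- pick_peaks(ms, config$peak_resolving_power,
                     config$peak_intensity_threshold)
    if (verbose) {
      message(sprintf("slice %d [%.2f-%.2f min]: %d peak(s)",
                      slices$slice[i], slices$rt_start[i], slices$rt_end[i],
                      nrow(pk)))
    }
    if (nrow(pk)) {
      pk$slice <- slices$slice[i]
      pk$slice_rt <- slices$rt_mid[i]
      out[[i]] <- pk
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    res <- tibble::tibble(mass_da = numeric(), intensity = numeric(),
                          slice = integer(), slice_rt = numeric())
  }
  res
}

#' Profile a run end-to-end
#'
#' The full pipeline: sliding-window slicing, per-slice averaging, baseline
#' subtraction and smoothing, charge-state deconvolution, mass-peak picking,
#' and ppm-tolerance merging into a clonal profile. Accepts either a
#' [fab_run()] or the path of an mzML file.
#'
#' The returned profile carries a `manifest` attribute recording input,
#' configuration hash, package version, per-stage timings, slice count and
#' clone count; see [write_manifest()].
#'
#' @param x A [fab_run()] or an mzML path.
#' @param config A [fab_config()].
#' @param sample_id Sample identifier; defaults to the run id.
#' @param verbose Report per-slice peak counts while deconvoluting?
#' @return A `fab_profile` tibble sorted by descending intensity.
#' @export
profile_run <- function(x, config = fab_config(), sample_id = NULL,
                        verbose = FALSE) {
  t_all <- proc.time()[["elapsed"]]
  if (is.character(x)) {
    src <- x
    x <- read_mzml(x)
  } else {
    stopifnot(inherits(x, "fab_run"))
    src <- x$metadata$source %||% x$run_id
  }
  sample_id <- sample_id %||% x$run_id
  timings <- c()
  t0 <- proc.time()[["elapsed"]]
  slices <- preprocess_run(x, config)
  timings["preprocess_s"] <- proc.time()[["elapsed"]] - t0
  if (all(slices$empty)) {
    warning("no scans fall inside the region of interest; returning an empty profile",
            call. = FALSE)
  }
  t0 <- proc.time()[["elapsed"]]
  peaks <- deconvolute_slices(slices, config, verbose = verbose)
  timings["deconvolve_s"] <- proc.time()[["elapsed"]] - t0
  t0 <- proc.time()[["elapsed"]]
  profile <- merge_slices(peaks, config$merge_ppm, config$merge_max_rt_gap,
                          sample_id = sample_id,
                          config_hash = config_hash(config),
                          source = as.character(src))
  timings["merge_s"] <- proc.time()[["elapsed"]] - t0
  timings["total_s"] <- proc.time()[["elapsed"]] - t_all
  attr(profile, "manifest") <- list(
    input = as.character(src),
    sample_id = sample_id,
    config_hash = config_hash(config),
    package_version = as.character(utils::packageVersion("fabprofiler")),
    timings = as.list(round(timings, 3)),
    n_slices = nrow(slices),
    n_clones = nrow(profile)
  )
  profile
}

#' Write a run manifest
#'
#' Serialises the `manifest` attribute of a profiled run (input path,
#' configuration hash, package version, per-stage timings, slice and clone
#' counts) as JSON alongside the clone table.
#'
#' @param profile A `fab_profile` from [profile_run()], or a manifest list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(profile, path) {
  manifest <- if (is.list(profile) && !is.data.frame(profile)) {
    profile
  } else {
    attr(profile, "manifest")
  }
  if (is.null(manifest)) stop("no manifest attached to this profile", call. = FALSE)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
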