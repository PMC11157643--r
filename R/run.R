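#' Construct an LC-MS run object
#'
#' A `fab_run` is an ordered set of MS1 profile spectra with retention times,
#' the raw input of the profiling pipeline. Scans are stored as a tibble with
#' one row per scan and a list-column of spectra; each spectrum is a tibble
#' with columns `mz` (Th, strictly increasing) and `intensity` (non-negative
#' counts).
#'
#' @param rt_min Numeric vector of retention times, minutes.
#' @param spectra List of spectra (tibbles or data frames with `mz` and
#'   `intensity` columns), one per retention time.
#' @param run_id Identifier for the run.
#' @param metadata Named list of acquisition metadata. Recognised entries:
#'   `mz_low`, `mz_high` (Th), `scan_rate_hz`, `centroided` (logical),
#'   `source` (file of origin).
#' @return A `fab_run` with scans sorted by retention time.
#' @export
fab_run <- function(rt_min, spectra, run_id = "run", metadata = list()) {
  if (length(rt_min) != length(spectra)) {
    stop("`rt_min` and `spectra` must have the same length", call. = FALSE)
  }
  if (length(rt_min) == 0L) {
    stop("a run must contain at least one MS1 scan", call. = FALSE)
  }
  ord <- order(rt_min)
  rt_min <- rt_min[ord]
  spectra <- spectra[ord]
  if (any(diff(rt_min) <= 0)) {
    stop("scan retention times must be strictly increasing", call. = FALSE)
  }
  spectra <- lapply(spectra, function(s) {
    s <- tibble::as_tibble(s[, c("mz", "intensity")])
    if (nrow(s) && any(diff(s$mz) <= 0)) {
      stop("spectrum m/z values must be strictly increasing", call. = FALSE)
    }
    if (nrow(s) && any(s$intensity < 0)) {
      stop("spectrum intensities must be non-negative", call. = FALSE)
    }
    s
  })
  defaults <- list(mz_low = NA_real_, mz_high = NA_real_,
                   scan_rate_hz = NA_real_, centroided = FALSE,
                   source = NA_character_)
  metadata <- utils::modifyList(defaults, metadata)
  structure(
    list(
      run_id = run_id,
      scans = tibble::tibble(scan = seq_along(rt_min), rt_min = rt_min,
                             spectrum = spectra),
      metadata = metadata
    ),
    class = "fab_run"
  )
}

#' @export
print.fab_run <- function(x, ...) {
  rt <- x$scans$rt_min
  cat(sprintf("<fab_run> '%s': %d MS1 scans, RT %.2f-%.2f min", x$run_id,
              nrow(x$scans), min(rt), max(rt)))
  if (isTRUE(x$metadata$centroided)) cat(" [centroided]")
  cat("\n")
  invisible(x)
}

#' @rdname fab_run
#' @param x A `fab_run`.
#' @param ... Unused.
#' @return `tidy.fab_run()`: a long tibble with columns `scan`, `rt_min`,
#'   `mz`, `intensity`.
#' @method tidy fab_run
#' @export
tidy.fab_run <- function(x, ...) {
  tidyr::unnest(x$scans, "spectrum")
}

#' Read an mzML file into a run
#'
#' Parses profile-mode MS1 spectra (with retention times) from an mzML file.
#' MS2 and higher-level spectra are ignored. Scans are returned sorted by
#' retention time regardless of file order. Centroid-mode spectra are
#' accepted but flagged in the run metadata, since the downstream pipeline
#' assumes profile data.
#'
#' @param path Path to an mzML file.
#' @param run_id Identifier; defaults to the file name without extension.
#' @return A [fab_run()].
#' @export
read_mzml <- function(path, run_id = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("mzML file not found: %s", path), call. = FALSE)
  }
  handle <- tryCatch(
    mzR::openMSfile(path),
    error = function(e) {
      stop(sprintf("failed to parse mzML file '%s': %s", path,
                   conditionMessage(e)), call. = FALSE)
    }
  )
  on.exit(mzR::close(handle), add = TRUE)
  hdr <- mzR::header(handle)
  ms1 <- which(hdr$msLevel == 1L)
  if (length(ms1) == 0L) {
    stop(sprintf("no MS1 spectra with retention times in '%s'", path),
         call. = FALSE)
  }
  spectra <- lapply(ms1, function(i) {
    pk <- mzR::peaks(handle, i)
    tibble::tibble(mz = pk[, 1], intensity = pmax(pk[, 2], 0))
  })
  centroided <- isTRUE(any(hdr$centroided[ms1]))
  if (centroided) {
    warning(sprintf("'%s' contains centroided MS1 spectra; the pipeline assumes profile mode",
                    basename(path)), call. = FALSE)
  }
  fab_run(
    rt_min = hdr$retentionTime[ms1] / 60,
    spectra = spectra,
    run_id = run_id %||% sub("\\.[^.]*$", "", basename(path)),
    metadata = list(
      mz_low = suppressWarnings(min(hdr$lowMZ[ms1], na.rm = TRUE)),
      mz_high = suppressWarnings(max(hdr$highMZ[ms1], na.rm = TRUE)),
      centroided = centroided,
      source = path
    )
  )
}

#' Write a run to mzML
#'
#' Serialises a `fab_run` as an mzML file with one MS1 profile spectrum per
#' scan, suitable for re-reading with [read_mzml()] or any mzML-aware tool.
#'
#' @param run A [fab_run()].
#' @param path Output path (`.mzML`).
#' @return `path`, invisibly.
#' @export
write_mzml <- function(run, path) {
  stopifnot(inherits(run, "fab_run"))
  n <- nrow(run$scans)
  pks <- lapply(run$scans$spectrum, function(s) {
    cbind(mz = s$mz, intensity = s$intensity)
  })
  lo <- vapply(pks, function(p) if (nrow(p)) min(p[, 1]) else NA_real_, 0)
  hi <- vapply(pks, function(p) if (nrow(p)) max(p[, 1]) else NA_real_, 0)
  bp <- vapply(pks, function(p) if (nrow(p)) p[which.max(p[, 2]), 1] else NA_real_, 0)
  bpi <- vapply(pks, function(p) if (nrow(p)) max(p[, 2]) else 0, 0)
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 1L,
    polarity = 1L, peaksCount = vapply(pks, nrow, 0L),
    totIonCurrent = vapply(pks, function(p) sum(p[, 2]), 0),
    retentionTime = run$scans$rt_min * 60,
    basePeakMZ = bp, basePeakIntensity = bpi,
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = lo, highMZ = hi,
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)),
    centroided = isTRUE(run$metadata$centroided),
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = lo, scanWindowUpperLimit = hi
  )
  mzR::writeMSData(pks, file = path, header = hdr)
  invisible(path)
}
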