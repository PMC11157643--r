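#' @noRd
new_fab_profile <- function(df, sample_id = "sample", config_hash = NA_character_,
                            source = NA_character_) {
  df <- tibble::as_tibble(df)
  stopifnot(all(c("clone_id", "mass_da", "rt_min", "intensity", "n_slices")
                %in% names(df)))
  structure(df,
            class = c("fab_profile", class(tibble::tibble())),
            sample_id = sample_id,
            config_hash = config_hash,
            source = source)
}

empty_profile <- function(sample_id = "sample", ...) {
  new_fab_profile(
    tibble::tibble(clone_id = integer(), mass_da = numeric(),
                   rt_min = numeric(), intensity = numeric(),
                   n_slices = integer()),
    sample_id = sample_id, ...
  )
}

#' Merge per-slice mass peaks into a clonal profile
#'
#' Collapses the mass peaks picked from every retention-time slice into a
#' deduplicated clone list, the Fab repertoire profile. Clustering is greedy
#' and intensity-ordered: the most intense unassigned peak seeds a clone,
#' which then absorbs every unassigned peak that (a) lies within `merge_ppm`
#' of the running intensity-weighted mean mass -- also after the absorption,
#' for every member, so the ppm consistency of the clone is guaranteed --
#' (b) lies within `merge_max_rt_gap` minutes of the nearest member, and
#' (c) comes from a slice not already represented in the clone (two masses
#' resolved within one deconvoluted slice are distinct species by
#' construction). Ties in intensity are broken by lower mass, then lower
#' slice index, making the result deterministic.
#'
#' Each clone reports the intensity-weighted mean mass of its members, the
#' retention time of its most intense (apex) slice, the apex intensity, and
#' the number of contributing slices. The attribute `members` maps each
#' clone back to the row indices of `peaks` it absorbed.
#'
#' @param peaks A tibble with columns `mass_da`, `intensity`, `slice`,
#'   `slice_rt` (one row per picked peak).
#' @param merge_ppm Mass tolerance, ppm.
#' @param merge_max_rt_gap Maximum retention-time gap to the nearest cluster
#'   member, minutes (`Inf` = unconstrained, the timsTOF-style merge; the
#'   Orbitrap-style merge uses 2 min).
#' @param sample_id Sample identifier recorded on the profile.
#' @param config_hash,source Optional provenance strings.
#' @return A `fab_profile`: a tibble with columns `clone_id`, `mass_da`,
#'   `rt_min`, `intensity`, `n_slices`, sorted by descending intensity.
#' @export
merge_slices <- function(peaks, merge_ppm = 50, merge_max_rt_gap = Inf,
                         sample_id = "sample", config_hash = NA_character_,
                         source = NA_character_) {
  stopifnot(merge_ppm > 0, merge_max_rt_gap > 0)
  if (nrow(peaks) == 0L) {
    return(empty_profile(sample_id, config_hash = config_hash, source = source))
  }
  stopifnot(all(c("mass_da", "intensity", "slice", "slice_rt") %in% names(peaks)))
  ord <- order(-peaks$intensity, peaks$mass_da, peaks$slice)
  mass <- peaks$mass_da[ord]
  inten <- peaks$intensity[ord]
  slice <- peaks$slice[ord]
  srt <- peaks$slice_rt[ord]
  n <- length(mass)
  assigned <- logical(n)
  clones <- list()
  membership <- list()
  for (seed in seq_len(n)) {
    if (assigned[seed]) next
    members <- seed
    assigned[seed] <- TRUE
    wmean <- mass[seed]
    repeat {
      cand <- which(!assigned &
                      abs(mass - wmean) / wmean * 1e6 <= merge_ppm &
                      !(slice %in% slice[members]))
      if (is.finite(merge_max_rt_gap) && length(cand)) {
        gaps <- vapply(cand, function(j) min(abs(srt[j] - srt[members])), 0)
        cand <- cand[gaps <= merge_max_rt_gap]
      }
      if (length(cand) == 0L) break
      took <- FALSE
      for (j in cand) {  # already in desc-intensity order
        new_members <- c(members, j)
        new_mean <- sum(mass[new_members] * inten[new_members]) /
          sum(inten[new_members])
        if (all(abs(mass[new_members] - new_mean) / new_mean * 1e6 <= merge_ppm)) {
          members <- new_members
          assigned[j] <- TRUE
          wmean <- new_mean
          took <- TRUE
          break
        }
      }
      if (!took) break
    }
    clones[[length(clones) + 1L]] <- tibble::tibble(
      mass_da = wmean,
      rt_min = srt[members[1L]],       # apex member: highest intensity
      intensity = inten[members[1L]],
      n_slices = length(members)
    )
    membership[[length(membership) + 1L]] <- ord[members]
  }
  out <- dplyr::bind_rows(clones)
  new_order <- order(-out$intensity, out$mass_da)
  out <- out[new_order, ]
  res <- new_fab_profile(
    tibble::tibble(clone_id = seq_len(nrow(out)), out),
    sample_id = sample_id, config_hash = config_hash, source = source
  )
  # row indices of `peaks` contributing to each clone, in clone order
  attr(res, "members") <- membership[new_order]
  res
}

#' Keep the most intense clones of a profile
#'
#' Retains the `n` most intense clones (all of them if the profile is
#' smaller). Intensity ties are broken by lower mass.
#'
#' @param profile A clonal profile tibble.
#' @param n Number of clones to keep.
#' @return A profile tibble with at most `n` rows.
#' @export
top_n_clones <- function(profile, n = 100) {
  stopifnot(n >= 1)
  ord <- order(-profile$intensity, profile$mass_da)
  out <- profile[ord[seq_len(min(n, nrow(profile)))], , drop = FALSE]
  for (a in c("sample_id", "config_hash", "source")) {
    attr(out, a) <- attr(profile, a)
  }
  out
}
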