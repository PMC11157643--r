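# Independent oracles the implementation is checked against.

# Brute-force charge-summation scorer for deconvolution: for every candidate
# mass on the grid, sum the observed intensity at mz_of(mass, z) over all
# charges. Its argmax locates the dominant species without any iterative
# solver. The score is symmetric about the true mass by construction but its
# top is broad (~mass/R wide), so off-grid reads must not ripple: the trace
# is read through a cubic spline and must sample the peaks finely (see
# render_envelope_fine). Linear reads of an undersampled trace shift each
# charge's vote by the grid phase error amplified z-fold in mass.
oracle_charge_sum <- function(spectrum, config) {
  mass_grid <- seq(config$mass_low, config$mass_high, by = config$mass_spacing)
  f <- stats::splinefun(spectrum$mz, spectrum$intensity, method = "natural")
  rng <- range(spectrum$mz)
  score <- numeric(length(mass_grid))
  for (z in config$charge_min:config$charge_max) {
    mzs <- (mass_grid + z * config$proton_mass) / z
    v <- f(mzs)
    v[mzs < rng[1] | mzs > rng[2]] <- 0
    score <- score + v
  }
  tibble::tibble(mass_da = mass_grid, score = score)
}

# All set partitions of 1..n as restricted-growth strings (Bell(n) of them;
# keep n <= 8).
all_partitions <- function(n) {
  if (n == 1L) return(list(c(1L)))
  out <- list()
  grow <- function(prefix, maxblock) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (b in seq_len(maxblock + 1L)) {
      grow(c(prefix, b), max(maxblock, b))
    }
  }
  grow(c(1L), 1L)
  out
}

# Is an assignment of peaks to clusters consistent with the merge rules?
# Every member must lie within merge_ppm of its cluster's intensity-weighted
# mean mass, clusters may not contain two peaks from one slice, and (when
# bounded) each member must be within merge_max_rt_gap of some other member.
partition_is_valid <- function(peaks, labels, merge_ppm,
                               merge_max_rt_gap = Inf) {
  for (b in unique(labels)) {
    idx <- which(labels == b)
    if (anyDuplicated(peaks$slice[idx])) return(FALSE)
    wm <- sum(peaks$mass_da[idx] * peaks$intensity[idx]) /
      sum(peaks$intensity[idx])
    if (any(abs(peaks$mass_da[idx] - wm) / wm * 1e6 > merge_ppm)) return(FALSE)
    if (is.finite(merge_max_rt_gap) && length(idx) > 1L) {
      for (i in idx) {
        if (min(abs(peaks$slice_rt[i] - peaks$slice_rt[setdiff(idx, i)])) >
            merge_max_rt_gap) {
          return(FALSE)
        }
      }
    }
  }
  TRUE
}

# Cluster labelling of the input peaks from a merge_slices result (uses the
# `members` attribute: row indices of the input peaks per clone).
labels_from_profile <- function(peaks, profile) {
  members <- attr(profile, "members")
  labels <- integer(nrow(peaks))
  for (b in seq_along(members)) labels[members[[b]]] <- b
  labels
}
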