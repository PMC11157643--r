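#' Align two clonal profiles by mass
#'
#' Greedy one-to-one nearest-mass matching: every candidate pair with
#' `|mass_a - mass_b| <= tolerance` is sorted by ascending mass difference
#' (ties broken by lower `mass_a`, then lower `mass_b`) and accepted when
#' both members are still unmatched. Unmatched clones contribute an entry
#' with zero intensity on the other side, so the two returned intensity
#' vectors have equal length and jointly cover every clone of both profiles.
#'
#' @param a,b Clonal profile tibbles (columns `mass_da`, `intensity`).
#' @param tolerance Mass tolerance, Da.
#' @return A tibble with columns `mass_a`, `mass_b` (NA where unmatched) and
#'   the aligned intensity vectors `intensity_a`, `intensity_b`.
#' @export
align_profiles <- function(a, b, tolerance = 1.5) {
  stopifnot(tolerance > 0)
  na <- nrow(a); nb <- nrow(b)
  if (na == 0L && nb == 0L) {
    return(tibble::tibble(mass_a = numeric(), mass_b = numeric(),
                          intensity_a = numeric(), intensity_b = numeric()))
  }
  pairs <- NULL
  if (na > 0L && nb > 0L) {
    cand <- expand.grid(i = seq_len(na), j = seq_len(nb))
    cand$delta <- abs(a$mass_da[cand$i] - b$mass_da[cand$j])
    cand <- cand[cand$delta <= tolerance, , drop = FALSE]
    if (nrow(cand)) {
      cand <- cand[order(cand$delta, a$mass_da[cand$i], b$mass_da[cand$j]), ,
                   drop = FALSE]
      used_a <- logical(na); used_b <- logical(nb)
      keep <- logical(nrow(cand))
      for (k in seq_len(nrow(cand))) {
        i <- cand$i[k]; j <- cand$j[k]
        if (!used_a[i] && !used_b[j]) {
          keep[k] <- TRUE
          used_a[i] <- TRUE
          used_b[j] <- TRUE
        }
      }
      pairs <- cand[keep, , drop = FALSE]
    }
  }
  if (is.null(pairs)) {
    pairs <- data.frame(i = integer(), j = integer())
  }
  un_a <- setdiff(seq_len(na), pairs$i)
  un_b <- setdiff(seq_len(nb), pairs$j)
  tibble::tibble(
    mass_a = c(a$mass_da[pairs$i], a$mass_da[un_a], rep(NA_real_, length(un_b))),
    mass_b = c(b$mass_da[pairs$j], rep(NA_real_, length(un_a)), b$mass_da[un_b]),
    intensity_a = c(a$intensity[pairs$i], a$intensity[un_a],
                    rep(0, length(un_b))),
    intensity_b = c(b$intensity[pairs$j], rep(0, length(un_a)),
                    b$intensity[un_b])
  )
}

#' Tolerance-matched cosine similarity of two profiles
#'
#' Reduces both profiles to their `top_n` most intense clones, aligns them
#' by mass within `tolerance` ([align_profiles()]), and returns the cosine
#' of the aligned intensity vectors, `(u . v) / (|u| |v|)`. Intensities are
#' used as-is, with no transformation or baseline correction. A score of 1
#' indicates perfect similarity, 0 no similarity; if either aligned vector
#' is empty or all-zero the score is 0 by convention.
#'
#' @param a,b Clonal profile tibbles.
#' @param tolerance Mass tolerance, Da.
#' @param top_n Number of most intense clones retained per profile.
#' @return A number in \[0, 1\].
#' @export
#' @examples
#' p <- tibble::tibble(clone_id = 1:3, mass_da = c(46000, 47500, 49000),
#'                     rt_min = c(12, 14, 16), intensity = c(5, 3, 1),
#'                     n_slices = 1L)
#' cosine_score(p, p)
cosine_score <- function(a, b, tolerance = 1.5, top_n = 100) {
  al <- align_profiles(top_n_clones(a, top_n), top_n_clones(b, top_n),
                       tolerance)
  u <- al$intensity_a
  v <- al$intensity_b
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(0)
  min(max(sum(u * v) / (nu * nv), 0), 1)  # guard 1 + epsilon rounding
}

#' Cross-sample similarity matrix
#'
#' All pairwise tolerance-matched cosine scores between clonal profiles, the
#' cross-platform/cross-donor correlation matrix of the workflow.
#'
#' @param profiles A (preferably named) list of clonal profile tibbles;
#'   unnamed entries take their `sample_id` attribute or a positional name.
#' @param tolerance Mass tolerance, Da.
#' @param top_n Clones retained per profile before scoring.
#' @return A `fab_similarity` object: list with `sample_ids` and the
#'   symmetric `scores` matrix (unit diagonal, values in \[0, 1\]).
#' @export
similarity_matrix <- function(profiles, tolerance = 1.5, top_n = 100) {
  stopifnot(is.list(profiles), length(profiles) >= 1L)
  ids <- names(profiles)
  if (is.null(ids)) ids <- rep("", length(profiles))
  for (i in seq_along(profiles)) {
    if (!nzchar(ids[i])) {
      ids[i] <- attr(profiles[[i]], "sample_id") %||% paste0("sample", i)
    }
  }
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  n <- length(profiles)
  tops <- lapply(profiles, top_n_clones, n = top_n)
  S <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in i:n) {
      S[i, j] <- S[j, i] <- cosine_score(tops[[i]], tops[[j]],
                                         tolerance = tolerance,
                                         top_n = top_n)
    }
  }
  structure(list(sample_ids = ids, scores = S), class = "fab_similarity")
}

#' @export
print.fab_similarity <- function(x, ...) {
  cat(sprintf("<fab_similarity> %d samples\n", length(x$sample_ids)))
  print(round(x$scores, 3))
  invisible(x)
}

#' @rdname similarity_matrix
#' @param x A `fab_similarity`.
#' @param ... Unused.
#' @return `tidy.fab_similarity()`: a long tibble with columns `sample_a`,
#'   `sample_b`, `score`.
#' @method tidy fab_similarity
#' @export
tidy.fab_similarity <- function(x, ...) {
  g <- expand.grid(sample_a = x$sample_ids, sample_b = x$sample_ids,
                   stringsAsFactors = FALSE)
  tibble::tibble(sample_a = g$sample_a, sample_b = g$sample_b,
                 score = as.vector(x$scores))
}

#' Heatmap of a similarity matrix
#'
#' @param object A `fab_similarity`.
#' @param ... Unused.
#' @return A ggplot: tile heatmap of pairwise cosine scores, 0 (pale yellow)
#'   to 1 (green).
#' @method autoplot fab_similarity
#' @export
autoplot.fab_similarity <- function(object, ...) {
  df <- tidy(object)
  df$sample_a <- factor(df$sample_a, levels = object$sample_ids)
  df$sample_b <- factor(df$sample_b, levels = rev(object$sample_ids))
  ggplot2::ggplot(df, ggplot2::aes(.data$sample_a, .data$sample_b,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "lightyellow", high = "darkgreen",
                                 limits = c(0, 1), name = "cosine") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
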