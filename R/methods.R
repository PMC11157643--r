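#' @export
print.fab_profile <- function(x, ...) {
  cat(sprintf("<fab_profile> '%s': %d clone(s)\n",
              attr(x, "sample_id") %||% "?", nrow(x)))
  NextMethod()
}

#' Summaries of a clonal profile
#'
#' `tidy()` returns the profile as a plain tibble; `glance()` gives a
#' one-row summary (clone count, mass range, total and apex intensity).
#'
#' @param x A `fab_profile`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy fab_profile
#' @export
tidy.fab_profile <- function(x, ...) {
  tibble::as_tibble(unclass(x)[profile_columns])
}

#' @rdname tidy.fab_profile
#' @method glance fab_profile
#' @export
glance.fab_profile <- function(x, ...) {
  tibble::tibble(
    sample_id = attr(x, "sample_id") %||% NA_character_,
    n_clones = nrow(x),
    mass_min = if (nrow(x)) min(x$mass_da) else NA_real_,
    mass_max = if (nrow(x)) max(x$mass_da) else NA_real_,
    total_intensity = sum(x$intensity),
    apex_intensity = if (nrow(x)) max(x$intensity) else NA_real_
  )
}

#' Mass-domain stem plot of a clonal profile
#'
#' Draws each clone as a vertical line at its mass with height equal to its
#' intensity -- the zero-charge repertoire "spectrum" of a sample.
#'
#' @param object A `fab_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fab_profile
#' @export
autoplot.fab_profile <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mass_da, xend = .data$mass_da,
                                   y = 0, yend = .data$intensity)) +
    ggplot2::geom_segment() +
    ggplot2::labs(x = "mass (Da)", y = "intensity",
                  title = attr(object, "sample_id")) +
    ggplot2::theme_minimal()
}

#' Plot one spectrum
#'
#' Line plot of an m/z-domain spectrum or a deconvoluted zero-charge mass
#' spectrum (any tibble with an intensity column and an `mz` or `mass_da`
#' axis).
#'
#' @param spectrum A tibble with columns `mz` or `mass_da`, and `intensity`.
#' @return A ggplot.
#' @export
plot_spectrum <- function(spectrum) {
  axis <- if ("mz" %in% names(spectrum)) "mz" else "mass_da"
  lab <- if (axis == "mz") "m/z (Th)" else "mass (Da)"
  ggplot2::ggplot(spectrum,
                  ggplot2::aes(x = .data[[axis]], y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = lab, y = "intensity") +
    ggplot2::theme_minimal()
}
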