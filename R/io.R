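profile_columns <- c("clone_id", "mass_da", "rt_min", "intensity", "n_slices")

validate_profile_table <- function(df, where = "clone table") {
  if (!setequal(names(df), profile_columns) ||
      length(names(df)) != length(profile_columns)) {
    stop(sprintf("%s: expected exactly columns %s, found %s", where,
                 paste(profile_columns, collapse = ", "),
                 paste(names(df), collapse = ", ")), call. = FALSE)
  }
  df <- df[, profile_columns]
  for (col in profile_columns) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad)) {
      stop(sprintf("%s: non-numeric or missing value in column `%s`, row %d",
                   where, col, bad[1]), call. = FALSE)
    }
  }
  neg <- which(df$intensity < 0)
  if (length(neg)) {
    stop(sprintf("%s: negative intensity in row %d", where, neg[1]),
         call. = FALSE)
  }
  bad_n <- which(df$n_slices < 1)
  if (length(bad_n)) {
    stop(sprintf("%s: n_slices < 1 in row %d", where, bad_n[1]),
         call. = FALSE)
  }
  df
}

#' Write / read a clone table
#'
#' Clonal profiles are stored as plain TSV with the fixed header
#' `clone_id, mass_da, rt_min, intensity, n_slices` -- one open format in
#' place of vendor-specific exports. The round trip is lossless well beyond
#' 6 significant digits on mass and 3 on retention time and intensity.
#'
#' @param profile A clonal profile tibble.
#' @param path File path.
#' @return `write_clone_table()`: `path`, invisibly. `read_clone_table()`:
#'   a `fab_profile` tibble.
#' @export
write_clone_table <- function(profile, path) {
  df <- validate_profile_table(tibble::as_tibble(profile))
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_clone_table
#' @param sample_id Sample identifier; defaults to the file name without
#'   extension.
#' @export
read_clone_table <- function(path, sample_id = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("clone table not found: %s", path), call. = FALSE)
  }
  df <- suppressWarnings(readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_double()),
    progress = FALSE, show_col_types = FALSE
  ))
  probs <- readr::problems(df)
  if (nrow(probs)) {
    stop(sprintf("clone table '%s': non-numeric cell at row %d", path,
                 max(probs$row[1] - 1L, 1L)), call. = FALSE)  # data row
  }
  df <- validate_profile_table(df, where = sprintf("clone table '%s'", path))
  df$clone_id <- as.integer(df$clone_id)
  df$n_slices <- as.integer(df$n_slices)
  new_fab_profile(df,
                  sample_id = sample_id %||% sub("\\.[^.]*$", "", basename(path)),
                  source = path)
}

#' Write / read a similarity matrix
#'
#' Similarity matrices are stored as CSV with sample identifiers in the
#' first column and as the header of the remaining columns.
#'
#' @param sim A `fab_similarity` (see [similarity_matrix()]).
#' @param path File path.
#' @return `write_similarity()`: `path`, invisibly. `read_similarity()`: a
#'   `fab_similarity`.
#' @export
write_similarity <- function(sim, path) {
  stopifnot(inherits(sim, "fab_similarity"))
  df <- tibble::as_tibble(sim$scores)
  df <- tibble::add_column(df, sample_id = sim$sample_ids, .before = 1)
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_similarity
#' @export
read_similarity <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("similarity matrix not found: %s", path), call. = FALSE)
  }
  df <- readr::read_csv(path, progress = FALSE, show_col_types = FALSE)
  if (names(df)[1] != "sample_id") {
    stop(sprintf("similarity matrix '%s': first column must be `sample_id`",
                 path), call. = FALSE)
  }
  ids <- as.character(df$sample_id)
  S <- as.matrix(df[, -1, drop = FALSE])
  if (!identical(colnames(S), ids) || nrow(S) != length(ids)) {
    stop(sprintf("similarity matrix '%s' is not square with matching ids",
                 path), call. = FALSE)
  }
  dimnames(S) <- list(ids, ids)
  structure(list(sample_ids = ids, scores = S), class = "fab_similarity")
}
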