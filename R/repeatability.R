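#' Landmark placement error between paired markings
#'
#' Quantifies intra- or inter-rater repeatability of manual point placement as
#' the distance, in pixels, between corresponding points of two markings of
#' the same image. Distances are computed on the raw pixel coordinates — no
#' Procrustes alignment — so the numbers are in the units of the source
#' images. The primary statistic is the Euclidean point-to-point distance
#' pooled over all points and subjects; per-point and per-subject means and
#' per-axis absolute differences are also returned.
#'
#' @param pairs A tibble of paired markings with columns `subject_id`,
#'   `comparison` (`"intra"` or `"inter"`), `rater` (`"a"`/`"b"`), `template`,
#'   `point`, `x`, `y` — two markings (raters) per subject, as produced by
#'   [generate_repeatability_pairs()].
#' @return A list of class `point_error` with elements `overall` (one row per
#'   comparison type: `mean_error`, `mean_abs_dx`, `mean_abs_dy`, `n_subjects`,
#'   `n_distances`), `per_point` and `per_subject` mean-error tibbles.
#' @export
point_error <- function(pairs) {
  required <- c("subject_id", "comparison", "rater", "point", "x", "y")
  missing_cols <- setdiff(required, names(pairs))
  if (length(missing_cols) > 0) {
    stop(glue::glue(
      "pairs table is missing column(s): {paste(missing_cols, collapse = ', ')}"
    ), call. = FALSE)
  }
  if (nrow(pairs) == 0L) stop("no repeatability pairs supplied", call. = FALSE)
  if ("template" %in% names(pairs)) {
    tpl_count <- pairs |>
      dplyr::distinct(.data$subject_id, .data$template) |>
      dplyr::count(.data$subject_id)
    if (any(tpl_count$n > 1)) {
      stop("template mismatch within a repeatability pair", call. = FALSE)
    }
  }
  wide <- pairs |>
    dplyr::select(dplyr::all_of(c("subject_id", "comparison", "rater", "point", "x", "y"))) |>
    tidyr::pivot_wider(
      names_from = "rater", values_from = c("x", "y")
    )
  if (!all(c("x_a", "y_a", "x_b", "y_b") %in% names(wide)) ||
    anyNA(wide[, c("x_a", "y_a", "x_b", "y_b")])) {
    stop("each subject/point needs exactly one marking from rater a and one from rater b",
      call. = FALSE
    )
  }
  dist <- wide |>
    dplyr::mutate(
      dx = abs(.data$x_a - .data$x_b),
      dy = abs(.data$y_a - .data$y_b),
      error = sqrt((.data$x_a - .data$x_b)^2 + (.data$y_a - .data$y_b)^2)
    )
  overall <- dist |>
    dplyr::group_by(.data$comparison) |>
    dplyr::summarise(
      mean_error = mean(.data$error),
      mean_abs_dx = mean(.data$dx),
      mean_abs_dy = mean(.data$dy),
      n_subjects = dplyr::n_distinct(.data$subject_id),
      n_distances = dplyr::n(),
      .groups = "drop"
    )
  per_point <- dist |>
    dplyr::group_by(.data$comparison, .data$point) |>
    dplyr::summarise(mean_error = mean(.data$error), .groups = "drop")
  per_subject <- dist |>
    dplyr::group_by(.data$comparison, .data$subject_id) |>
    dplyr::summarise(mean_error = mean(.data$error), .groups = "drop")
  structure(
    list(overall = overall, per_point = per_point, per_subject = per_subject),
    class = "point_error"
  )
}

#' @export
print.point_error <- function(x, ...) {
  cat("<point_error>\n")
  print(x$overall)
  invisible(x)
}

#' @rdname point_error
#' @param x A `point_error` object.
#' @param ... Unused.
#' @export
tidy.point_error <- function(x, ...) {
  x$overall
}
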