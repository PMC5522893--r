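#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Scree plot of a shape model
#'
#' Per-mode and cumulative percentage of shape variance, the plot used to
#' judge how many modes to retain.
#'
#' @param object A `shape_model`.
#' @param n_modes How many leading modes to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.shape_model <- function(object, n_modes = max(20L, object$n_retained), ...) {
  df <- scree_table(object) |>
    dplyr::slice_head(n = n_modes) |>
    tidyr::pivot_longer(c("pct_variance", "cumulative_pct"),
      names_to = "series", values_to = "pct"
    ) |>
    dplyr::mutate(series = dplyr::recode(.data$series,
      pct_variance = "per mode", cumulative_pct = "cumulative"
    ))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mode, y = .data$pct, colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$n_retained + 0.5, linetype = "dashed") +
    ggplot2::labs(
      x = "mode", y = "% of shape variance", colour = NULL,
      title = sprintf("Scree: '%s' model (%d shapes)", object$template, object$n)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a mode of variation as +/- k SD outlines
#'
#' Draws the mean shape and the reconstructions at `-k_sd` and `+k_sd`
#' standard deviations along one mode, connected along the template outline
#' groups. The y axis is reversed to match the image pixel convention (origin
#' top-left).
#'
#' @param model A `shape_model`.
#' @param mode Mode index.
#' @param k_sd SD offset (default 2, i.e. -2/0/+2 SD are drawn).
#' @param template Optional `point_template` providing the outline groups;
#'   defaults to the built-in template named by the model.
#' @return A ggplot.
#' @export
plot_mode_variation <- function(model, mode, k_sd = 2, template = NULL) {
  if (is.null(template)) template <- builtin_template(model$template)
  at <- function(k, label) {
    dplyr::mutate(reconstruct_shape(model, mode, k), shape = label)
  }
  df <- dplyr::bind_rows(
    at(-k_sd, sprintf("-%g SD", k_sd)),
    at(0, "mean"),
    at(k_sd, sprintf("+%g SD", k_sd))
  )
  groups <- purrr::imap_dfr(
    template$outline_groups,
    function(idx, nm) tibble(point = idx, group = nm)
  )
  df <- dplyr::inner_join(df, groups, by = "point") |>
    dplyr::arrange(.data$shape, .data$group, .data$point)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$x, y = .data$y,
    group = interaction(.data$shape, .data$group), colour = .data$shape
  )) +
    ggplot2::geom_path() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = sprintf("'%s' mode %d", model$template, mode),
      x = "x (px units)", y = "y (px units)", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Aligned-shape cloud of a Procrustes alignment
#'
#' Overlays every aligned shape (points, semi-transparent) with the consensus
#' mean shape.
#'
#' @param object A `shape_alignment`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.shape_alignment <- function(object, ...) {
  ggplot2::ggplot(object$shapes, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.05, size = 0.4) +
    ggplot2::geom_point(
      data = object$mean_shape, colour = "red", size = 0.8
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = sprintf(
        "Procrustes alignment: %d shapes ('%s')",
        nrow(object$centroid_sizes), object$template
      ),
      x = "x (preshape units)", y = "y (preshape units)"
    ) +
    ggplot2::theme_minimal()
}
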