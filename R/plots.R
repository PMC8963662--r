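#' Plot a priority map
#'
#' Raster heat map in image orientation (origin top-left).
#'
#' @param object A `priority_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot priority_map
#' @export
autoplot.priority_map <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse(expand = c(0, 0)) +
    ggplot2::scale_x_continuous(expand = c(0, 0)) +
    ggplot2::scale_fill_viridis_c(name = object$variant) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)",
                  title = sprintf("%s priority map", object$variant)) +
    ggplot2::theme_minimal()
}

#' Plot a normalized weight table
#'
#' Tile plot in the layout of the study's weighting figure: rows are
#' fixation ordinals 1..9, columns the features plus the instance
#' proportion, brightness coding a greater contribution.
#'
#' @param object A `weight_table` from [weight_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot weight_table
#' @export
autoplot.weight_table <- function(object, ...) {
  feats <- attr(object, "features")
  df <- object |>
    as_tibble() |>
    tidyr::pivot_longer(dplyr::all_of(c(feats, "instances")),
                        names_to = "feature", values_to = "weight") |>
    dplyr::mutate(feature = factor(.data$feature,
                                   levels = c(feats, "instances")))
  ggplot2::ggplot(df, ggplot2::aes(.data$feature, .data$fix_index,
                                   fill = .data$weight)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$weight)),
                       colour = "white", size = 3) +
    ggplot2::scale_y_reverse(breaks = object$fix_index) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "weight") +
    ggplot2::labs(x = NULL, y = "fixation index") +
    ggplot2::theme_minimal()
}

#' Plot per-fixation z-statistics of competing priority maps
#'
#' @param results List of `glmm_result` objects (one per fixation index),
#'   a `weight_table` (its retained statistics are used), or a
#'   `recovery_experiment`.
#' @return A ggplot object.
#' @export
plot_glmm_z <- function(results) {
  long <- if (inherits(results, "recovery_experiment")) {
    attr(results$weight_table, "statistics")
  } else if (inherits(results, "weight_table")) {
    attr(results, "statistics")
  } else {
    dplyr::bind_rows(purrr::imap(results, function(r, i) {
      dplyr::mutate(tidy(r), fix_index = r$fixation_index %||% i)
    }))
  }
  ggplot2::ggplot(long, ggplot2::aes(.data$fix_index, .data$statistic,
                                     colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::scale_x_continuous(breaks = unique(long$fix_index)) +
    ggplot2::labs(x = "fixation index", y = "z-statistic",
                  colour = "priority map") +
    ggplot2::theme_minimal()
}
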