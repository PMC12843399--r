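#' @importFrom ggplot2 autoplot ggplot aes geom_area geom_col geom_errorbar
#'   geom_tile geom_point geom_segment geom_text geom_histogram labs
#'   scale_fill_brewer scale_fill_gradient2 theme_minimal after_stat arrow unit
NULL

#' Plot a cross-sectional state distribution
#'
#' Stacked-area view of the proportion of students in each macro state at
#' every sequence position (BLANK fills positions beyond a student's
#' sequence end).
#'
#' @param object An `hpp_state_dist` from [state_distribution()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hpp_state_dist <- function(object, ...) {
  ggplot(object, aes(x = .data$position, y = .data$prop, fill = .data$state)) +
    geom_area(position = "stack") +
    scale_fill_brewer(palette = "Set2") +
    labs(x = "Sequence position", y = "Proportion of students", fill = "State") +
    theme_minimal()
}

#' Plot a fitted efficiency-profile mixture
#'
#' Histogram of completion times with the selected mixture's component
#' densities overlaid.
#'
#' @param object An `hpp_gmm` from [fit_efficiency_profiles()].
#' @param bins Histogram bins (default 30).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hpp_gmm <- function(object, bins = 30, ...) {
  x <- object$assignments$completion_time
  m <- object$model
  grid <- seq(min(x), max(x), length.out = 256)
  dens <- purrr::map_dfr(seq_len(object$K), function(k) {
    tibble(component = factor(k), time = grid,
           density = m$w[k] * stats::dnorm(grid, m$mu[k], m$sd[k]))
  })
  ggplot() +
    geom_histogram(
      data = tibble(time = x),
      aes(x = .data$time, y = after_stat(.data$density)),
      bins = bins, fill = "grey85", colour = "grey60"
    ) +
    ggplot2::geom_line(
      data = dens,
      aes(x = .data$time, y = .data$density, colour = .data$component),
      linewidth = 1
    ) +
    labs(x = "Completion time (s)", y = "Density", colour = "Component") +
    theme_minimal()
}

#' Plot subgroup entropy means with bootstrap intervals
#'
#' @param object An `hpp_entropy` from [entropy_group_comparison()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hpp_entropy <- function(object, ...) {
  d <- mutate(object$means,
              subgroup = paste(.data$effectiveness, .data$efficiency, sep = "-"))
  ggplot(d, aes(x = .data$subgroup, y = .data$mean, fill = .data$effectiveness)) +
    geom_col(width = 0.6) +
    geom_errorbar(aes(ymin = .data$conf.low, ymax = .data$conf.high), width = 0.15) +
    geom_text(aes(label = .data$n, y = .data$conf.high), vjust = -0.6) +
    labs(x = NULL, y = "Normalized entropy") +
    ggplot2::ylim(0, 1) +
    theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot a delta probability map
#'
#' Tile heat map of per-cell transition-probability differences (A minus
#' B); significant cells (bootstrap CI excluding zero) are outlined.
#'
#' @param object An `hpp_delta_map` from [bootstrap_deltas()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hpp_delta_map <- function(object, ...) {
  d <- tidy.hpp_delta_map(object) |>
    mutate(from = factor(.data$from, levels = rev(rownames(object$delta))),
           to = factor(.data$to, levels = colnames(object$delta)))
  ggplot(d, aes(x = .data$to, y = .data$from, fill = .data$delta)) +
    geom_tile(colour = "white") +
    geom_tile(data = filter(d, !is.na(.data$significant) & .data$significant),
              fill = NA, colour = "black", linewidth = 0.8) +
    scale_fill_gradient2(low = "firebrick", mid = "white", high = "forestgreen",
                         na.value = "grey92") +
    labs(x = "To", y = "From", fill = "Delta Pr") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a thresholded process graph
#'
#' Circular-layout node-and-arrow rendering of the retained transitions,
#' with edge colour carrying the delta-map comparison when present.
#'
#' @param object An `hpp_process_graph` from [build_process_graph()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hpp_process_graph <- function(object, ...) {
  nodes <- object$nodes |>
    mutate(angle = 2 * pi * (dplyr::row_number() - 1) / dplyr::n(),
           x = cos(.data$angle), y = sin(.data$angle))
  edges <- object$edges |>
    left_join(select(nodes, "name", x0 = "x", y0 = "y"), by = c(from = "name")) |>
    left_join(select(nodes, "name", x1 = "x", y1 = "y"), by = c(to = "name")) |>
    mutate(
      # shorten segments so arrows stop at the node marker
      dx = .data$x1 - .data$x0, dy = .data$y1 - .data$y0,
      len = sqrt(.data$dx^2 + .data$dy^2),
      x0s = .data$x0 + 0.12 * .data$dx / .data$len,
      y0s = .data$y0 + 0.12 * .data$dy / .data$len,
      x1s = .data$x1 - 0.12 * .data$dx / .data$len,
      y1s = .data$y1 - 0.12 * .data$dy / .data$len
    )
  ggplot() +
    geom_segment(
      data = edges,
      aes(x = .data$x0s, y = .data$y0s, xend = .data$x1s, yend = .data$y1s,
          linewidth = .data$prob),
      colour = edges$colour,
      arrow = arrow(length = unit(0.18, "cm"), type = "closed")
    ) +
    ggplot2::scale_linewidth(range = c(0.3, 1.6), guide = "none") +
    geom_point(data = nodes, aes(x = .data$x, y = .data$y), size = 10,
               colour = "grey80") +
    geom_text(data = nodes, aes(x = 1.25 * .data$x, y = 1.18 * .data$y,
                                label = .data$name), size = 3) +
    ggplot2::coord_equal(xlim = c(-1.5, 1.5), ylim = c(-1.4, 1.4)) +
    ggplot2::theme_void()
}
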