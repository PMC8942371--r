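# ggplot2 visualisations for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_line geom_ribbon
#'   geom_hline geom_vline scale_fill_viridis_c labs facet_wrap theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot an event-aligned ensemble as a depth x time activity map
#'
#' @param object An [align_ensembles()] result.
#' @param ... Unused.
#' @return A ggplot: relative time on x, depth (edge at the top) on y,
#'   ensemble mean in pseudo-colour.
#' @export
autoplot.aligned_ensemble <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$rel_time_s, y = .data$depth,
                 fill = .data$mean)) +
    geom_raster() +
    ggplot2::scale_y_reverse(breaks = object$depths) +
    scale_fill_viridis_c(name = object$signal) +
    geom_vline(xintercept = 0, linetype = "dashed", colour = "white") +
    labs(x = "time from anchor (s)", y = "depth window (um from edge)",
         title = sprintf("%s-aligned %s (n = %d events)",
                         gsub("_", " ", object$anchor), object$signal,
                         object$n_events)) +
    theme_minimal()
}

#' Plot the mean curve of an ensemble at one depth, with CI ribbon
#'
#' @param ensemble An [align_ensembles()] result (run [ensemble_mean_ci()]
#'   first for the ribbon).
#' @param depth Depth window to plot (default: first).
#' @return A ggplot.
#' @export
plot_ensemble_depth <- function(ensemble, depth = ensemble$depths[1]) {
  df <- tidy(ensemble) |> filter(.data$depth == !!depth)
  p <- ggplot(df, aes(x = .data$rel_time_s, y = .data$mean))
  if ("lower" %in% names(df)) {
    p <- p + geom_ribbon(aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.25)
  }
  p + geom_line() +
    geom_vline(xintercept = 0, linetype = "dashed") +
    labs(x = "time from anchor (s)",
         y = sprintf("%s (depth %g)", ensemble$signal, depth),
         title = gsub("_", " ", ensemble$anchor)) +
    theme_minimal()
}

#' Plot a lagged cross-correlation curve
#'
#' @param object A [cross_correlate()] result.
#' @param ... Unused.
#' @return A ggplot with the peak lag marked.
#' @export
autoplot.xcorr_result <- function(object, ...) {
  df <- tidy(object)
  pk <- peak_lag(object)
  ggplot(df, aes(x = .data$lag_s, y = .data$corr)) +
    geom_hline(yintercept = 0, colour = "grey70") +
    geom_line() +
    geom_vline(xintercept = pk, linetype = "dashed", colour = "red") +
    labs(x = sprintf("lag of %s after %s (s)", object$y_name, object$x_name),
         y = "mean correlation",
         title = sprintf("peak at %+g s", pk)) +
    theme_minimal()
}

#' Plot difference-in-difference curves by activation-offset group
#'
#' @param object A [did_curves()] result.
#' @param ... Unused.
#' @return A ggplot: control mean (black) and per-offset-group differences.
#' @export
autoplot.did_result <- function(object, ...) {
  df <- tidy(object)
  ctrl <- df |> filter(.data$curve == "control")
  diffs <- df |>
    filter(.data$curve == "difference") |>
    mutate(offset = factor(.data$offset_group))
  ylab <- if (object$quantity == "velocity") "velocity (um/s)" else "distance (um)"
  ggplot() +
    geom_line(data = ctrl, aes(x = .data$rel_time_s, y = .data$value),
              colour = "black") +
    geom_line(data = diffs,
              aes(x = .data$rel_time_s, y = .data$value,
                  colour = .data$offset)) +
    geom_hline(yintercept = 0, linetype = "dotted") +
    labs(x = "time from onset (s)", y = ylab,
         colour = "activation offset (s)",
         title = "control (black) and difference-in-difference curves") +
    theme_minimal()
}

#' Plot a traction map magnitude
#'
#' @param object A [traction_map()].
#' @param ... Unused.
#' @return A ggplot raster of |t| in Pa.
#' @export
autoplot.traction_map <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$x_um, y = .data$y_um,
                           fill = .data$magnitude_pa)) +
    geom_raster() +
    scale_fill_viridis_c(name = "|t| (Pa)") +
    ggplot2::coord_equal() +
    labs(x = "x (um)", y = "y (um)") +
    theme_minimal()
}

#' Plot a displacement field as arrows
#'
#' @param object A [displacement_field()].
#' @param ... Unused.
#' @return A ggplot quiver-style plot.
#' @export
autoplot.displacement_field <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$x_um, y = .data$y_um)) +
    ggplot2::geom_segment(aes(xend = .data$x_um + .data$u_um,
                              yend = .data$y_um + .data$v_um,
                              colour = sqrt(.data$u_um^2 + .data$v_um^2)),
                          arrow = ggplot2::arrow(length = ggplot2::unit(1, "mm"))) +
    scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    labs(x = "x (um)", y = "y (um)", colour = "|u| (um)") +
    theme_minimal()
}
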