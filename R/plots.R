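# ggplot2 figures: trajectories, phase planes, sweeps, contrasts.

.factor_colours <- c(x = "#1f77b4", y = "#d62728", z = "#2ca02c")

#' Plot an oscillation profile
#'
#' Time courses of the fission (blue), intermediary (red) and fusion
#' (green) factors, the conventional colouring for this model family.
#'
#' @param traj A `mito_trajectory`.
#' @param variables Which variables to draw.
#' @param post_transient_only Drop the burn-in window first.
#' @return A ggplot object.
#' @export
plot_trajectory <- function(traj, variables = c("x", "y", "z"),
                            post_transient_only = FALSE) {
  if (post_transient_only) traj <- post_transient(traj)
  labs <- variable_labels()
  long <- tibble::as_tibble(traj) |>
    tidyr::pivot_longer(dplyr::all_of(variables), names_to = "variable",
                        values_to = "level") |>
    dplyr::left_join(labs, by = "variable")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$level,
                                     colour = .data$variable)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::scale_colour_manual(values = .factor_colours,
                                 labels = rlang::set_names(labs$label,
                                                           labs$variable)) +
    ggplot2::labs(x = "time (dimensionless)", y = "concentration",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_trajectory
#' @param object,... Method arguments passed through.
#' @export
autoplot.mito_trajectory <- function(object, ...) plot_trajectory(object, ...)

#' Plot a phase-plane orbit
#'
#' Fission factor on the horizontal axis, the paired factor vertical;
#' optionally overlays nullclines and the interior fixed point.
#'
#' @param orbit A `mito_orbit` from [phase_orbit()].
#' @param nullcline_set Optional [nullclines()] tibble for the same plane.
#' @param fixed_point Optional `mito_fixed_points` tibble; the interior
#'   point is marked.
#' @return A ggplot object.
#' @export
plot_phase_orbit <- function(orbit, nullcline_set = NULL,
                             fixed_point = NULL) {
  pair <- attr(orbit, "pair")
  labs <- variable_labels()
  lab_of <- function(v) labs$label[labs$variable == v]
  g <- ggplot2::ggplot(tibble::as_tibble(orbit),
                       ggplot2::aes(x = .data$u, y = .data$v)) +
    ggplot2::geom_path(colour = "grey25", linewidth = 0.3) +
    ggplot2::labs(x = lab_of(pair[1]), y = lab_of(pair[2])) +
    ggplot2::theme_minimal()
  if (!is.null(nullcline_set)) {
    plane <- paste(pair, collapse = "-")
    nc <- dplyr::filter(nullcline_set, .data$plane == !!plane)
    if (nrow(nc)) {
      g <- g + ggplot2::geom_line(
        data = nc, ggplot2::aes(x = .data$u, y = .data$v,
                                colour = .data$equation),
        linetype = "dashed", linewidth = 0.4)
    }
  }
  if (!is.null(fixed_point)) {
    fpi <- fixed_point[fixed_point$point == "interior", ]
    pt <- tibble::tibble(u = fpi[[pair[1]]], v = fpi[[pair[2]]])
    g <- g + ggplot2::geom_point(data = pt, colour = "black", size = 2,
                                 shape = 4)
  }
  g
}

#' @rdname plot_phase_orbit
#' @param object,... Method arguments passed through.
#' @export
autoplot.mito_orbit <- function(object, ...) plot_phase_orbit(object, ...)

#' Plot a parameter sweep
#'
#' One panel per variable, the chosen metric against the swept parameter
#' on a log axis; non-oscillatory grid points are hollow.
#'
#' @param sweep A `mito_sweep` tibble from [param_sweep()].
#' @param metric One of `"frequency"`, `"period"`, `"amplitude"`,
#'   `"mean_level"`.
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep, metric = "frequency") {
  metric <- match.arg(metric,
                      c("frequency", "period", "amplitude", "mean_level"))
  ggplot2::ggplot(sweep,
                  ggplot2::aes(x = .data$value, y = .data[[metric]],
                               colour = .data$variable)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$oscillatory), size = 1.8) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    ggplot2::scale_colour_manual(values = .factor_colours) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = unique(sweep$parameter), y = metric) +
    ggplot2::theme_minimal()
}

#' @rdname plot_sweep
#' @param object,... Method arguments passed through.
#' @export
autoplot.mito_sweep <- function(object, ...) plot_sweep(object, ...)

#' Plot a condition comparison
#'
#' Bar chart of signed relative changes per variable and metric for each
#' contrast in a condition report.
#'
#' @param report A `mito_condition_report` from [condition_report()].
#' @return A ggplot object.
#' @export
plot_condition_report <- function(report) {
  deltas <- purrr::imap_dfr(report$contrasts, function(ct, nm) {
    dplyr::mutate(ct$deltas, contrast = nm)
  })
  ggplot2::ggplot(deltas,
                  ggplot2::aes(x = .data$metric,
                               y = .data$relative_change,
                               fill = .data$variable)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::facet_wrap(~contrast) +
    ggplot2::scale_fill_manual(values = .factor_colours) +
    ggplot2::labs(x = NULL, y = "relative change (b - a) / a") +
    ggplot2::theme_minimal()
}
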