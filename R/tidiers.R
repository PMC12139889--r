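# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trajectory into long format
#'
#' @param x A `mito_trajectory`.
#' @param ... Unused.
#' @return A tibble `time`, `variable`, `alias`, `level`.
#' @export
tidy.mito_trajectory <- function(x, ...) {
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(c("x", "y", "z"), names_to = "variable",
                        values_to = "level") |>
    dplyr::left_join(variable_labels()[c("variable", "alias")],
                     by = "variable") |>
    dplyr::select("time", "variable", "alias", "level")
}

#' One-row summary of a trajectory
#'
#' @param x A `mito_trajectory`.
#' @param ... Unused.
#' @return A tibble with the parameters, horizon, grid step and per-variable
#'   minima.
#' @export
glance.mito_trajectory <- function(x, ...) {
  p <- traj_params(x)
  st <- traj_settings(x)
  tibble::tibble(
    epsilon = p$epsilon, epsilon_prime = p$epsilon_prime, q = p$q, f = p$f,
    t_end = st$t_end, dt_out = st$dt_out, n = nrow(x),
    min_x = min(x$x), min_y = min(x$y), min_z = min(x$z)
  )
}

#' Tidy a fixed-point set
#'
#' Unnests eigenvalues into one row per fixed point and eigenvalue.
#'
#' @param x A `mito_fixed_points` tibble.
#' @param ... Unused.
#' @return A tibble `point`, `x`, `y`, `z`, `eigenvalue_re`,
#'   `eigenvalue_im`, `stability`.
#' @export
tidy.mito_fixed_points <- function(x, ...) {
  fp <- x
  purrr::map_dfr(seq_len(nrow(fp)), function(i) {
    ev <- fp$eigenvalues[[i]]
    tibble::tibble(point = fp$point[i], x = fp$x[i], y = fp$y[i],
                   z = fp$z[i],
                   eigenvalue_re = Re(ev), eigenvalue_im = Im(ev),
                   stability = fp$stability[i])
  })
}

#' Tidy oscillation metrics (drops list-columns)
#'
#' @param x A `mito_metrics` tibble.
#' @param ... Unused.
#' @return A plain tibble without the `peak_times` list-column.
#' @export
tidy.mito_metrics <- function(x, ...) {
  tibble::as_tibble(x)[, c("variable", "alias", "n_peaks", "oscillatory",
                           "period", "frequency", "amplitude", "mean_level")]
}

#' One-row summary of oscillation metrics
#'
#' @param x A `mito_metrics` tibble.
#' @param ... Unused.
#' @return A tibble with the common period, the x-z phase lag and its
#'   fraction of the x-period.
#' @export
glance.mito_metrics <- function(x, ...) {
  lag <- phase_lag_xz(x)
  tibble::tibble(
    period_x = x$period[x$variable == "x"],
    all_oscillatory = all(x$oscillatory),
    phase_lag_xz = lag$time,
    phase_lag_fraction = lag$fraction
  )
}

#' Tidy a condition report into its verdict table
#'
#' @param x A `mito_condition_report`.
#' @param ... Unused.
#' @return The combined verdict tibble.
#' @export
tidy.mito_condition_report <- function(x, ...) x$verdicts
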