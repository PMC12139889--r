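# Parameter sweeps and location of the oscillatory-regime boundary.

#' Default log-spaced sweep grid around a base value
#'
#' Seven points spanning four-fold below to four-fold above the base value,
#' bracketing the named preset symmetrically on a log scale.
#'
#' @param base_value Centre of the grid.
#' @param n Number of points.
#' @param span Fold-range on each side.
#' @return Increasing numeric vector.
#' @export
sweep_grid <- function(base_value, n = 7, span = 4) {
  exp(seq(log(base_value / span), log(base_value * span), length.out = n))
}

#' Sweep one parameter and collect oscillation metrics
#'
#' For each grid value the base parameter set is cloned, the chosen
#' parameter replaced, the model integrated, and oscillation metrics
#' computed. A solver failure at a grid point is recorded and the sweep
#' continues. Oscillatory classification uses the >= 3 prominent-peaks rule
#' of [oscillation_metrics()], cross-checked against the sign of the
#' leading eigenvalue at the interior fixed point.
#'
#' @param parameter One of `"epsilon"`, `"epsilon_prime"`, `"q"`, `"f"`.
#' @param values Positive sweep grid (sorted internally).
#' @param base A [mito_params()] object or preset name.
#' @param settings A [solver_settings()] object.
#' @param initial Initial state passed to [mito_simulate()].
#' @return A tibble of class `mito_sweep`: one row per value and variable
#'   with columns `parameter`, `value`, `variable`, `period`, `frequency`,
#'   `amplitude`, `mean_level`, `n_peaks`, `oscillatory`, `max_re`,
#'   `failed`.
#' @export
param_sweep <- function(parameter, values, base,
                        settings = solver_settings(),
                        initial = c(0.1, 0.1, 0.1)) {
  parameter <- match.arg(parameter,
                         c("epsilon", "epsilon_prime", "q", "f"))
  if (is.character(base)) base <- preset_params(base)
  if (any(values <= 0)) {
    rlang::abort("sweep values must be positive",
                 class = "mitodyn_error_invalid_input")
  }
  values <- sort(unique(as.numeric(values)))
  purrr::map_dfr(values, function(v) {
    p <- base
    p[[parameter]] <- v
    fp <- fixed_points(p)
    max_re <- fp$max_re[fp$point == "interior"]
    res <- tryCatch({
      traj <- mito_simulate(p, initial = initial, settings = settings)
      m <- oscillation_metrics(traj)
      tibble::as_tibble(m)[, c("variable", "period", "frequency",
                               "amplitude", "mean_level", "n_peaks",
                               "oscillatory")] |>
        dplyr::mutate(failed = FALSE)
    }, mitodyn_error_solver = function(e) {
      tibble::tibble(variable = c("x", "y", "z"), period = NA_real_,
                     frequency = NA_real_, amplitude = NA_real_,
                     mean_level = NA_real_, n_peaks = NA_integer_,
                     oscillatory = NA, failed = TRUE)
    })
    dplyr::mutate(res, parameter = parameter, value = v, max_re = max_re,
                  .before = 1)
  }) |>
    structure(class = c("mito_sweep", class(tibble::tibble())))
}

#' Locate the oscillatory-regime boundary in one parameter
#'
#' Bisects on the maximum real part of the interior fixed point's Jacobian
#' eigenvalues, the linear-stability signature of the oscillation: positive
#' means an unstable focus surrounded by a limit cycle, negative a stable
#' steady state. The interval must bracket a sign change.
#'
#' @inheritParams param_sweep
#' @param lower,upper Interval endpoints (both positive).
#' @param tol Bisection stops when the interval is shorter than `tol`.
#' @return The critical parameter value, with attributes `max_re` (residual
#'   leading real part there) and `interval`.
#' @export
oscillation_boundary <- function(parameter, lower, upper, base,
                                 tol = 1e-4) {
  parameter <- match.arg(parameter,
                         c("epsilon", "epsilon_prime", "q", "f"))
  if (is.character(base)) base <- preset_params(base)
  g <- function(v) {
    p <- base
    p[[parameter]] <- v
    fp <- fixed_points(p)
    fp$max_re[fp$point == "interior"]
  }
  glo <- g(lower); ghi <- g(upper)
  if (sign(glo) == sign(ghi)) {
    rlang::abort(
      sprintf("no stability boundary in [%g, %g]: leading real part has the same sign (%.3g, %.3g) at both endpoints",
              lower, upper, glo, ghi),
      class = "mitodyn_error_no_boundary"
    )
  }
  lo <- lower; hi <- upper
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (sign(g(mid)) == sign(glo)) lo <- mid else hi <- mid
  }
  # polish with a root bracketing step for a tight residual
  crit <- stats::uniroot(g, c(lo, hi), tol = 1e-12)$root
  structure(crit, max_re = g(crit), interval = c(lo, hi))
}

#' Write a sweep result to CSV
#'
#' Columns `parameter,value,variable,period,frequency,amplitude,mean_level,
#' oscillatory`.
#'
#' @param sweep A `mito_sweep` tibble.
#' @param path Output file.
#' @export
write_sweep_csv <- function(sweep, path) {
  readr::write_csv(
    sweep[c("parameter", "value", "variable", "period", "frequency",
            "amplitude", "mean_level", "oscillatory")], path)
  invisible(path)
}
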