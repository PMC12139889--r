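# Oscillation metrics: peaks, period, frequency, amplitude, mean level,
# and the fission-fusion phase lag.

#' Detect peaks and troughs in a uniformly sampled series
#'
#' Local maxima (and minima) are kept only when their topographic prominence
#' exceeds `prominence_fraction` times the global range of the series, which
#' suppresses solver ripple while retaining the sharp peaks of relaxation
#' waveforms. Prominence of a peak is its height above the higher of the two
#' lowest points separating it from higher terrain on either side (series
#' ends count as terrain boundaries).
#'
#' @param series Numeric vector, length >= 10, sampled on a uniform grid.
#' @param prominence_fraction Fraction of the global range, in (0, 1).
#' @return A list with integer index vectors `peaks` and `troughs`, both
#'   strictly increasing. A flat series yields empty vectors.
#' @examples
#' t <- seq(0, 20 * pi, by = 0.01)
#' detect_peaks(sin(t))$peaks
#' @export
detect_peaks <- function(series, prominence_fraction = 0.1) {
  if (!is.numeric(series) || length(series) < 10L || anyNA(series)) {
    rlang::abort("series must be numeric, length >= 10, without NA",
                 class = "mitodyn_error_invalid_input")
  }
  if (prominence_fraction <= 0 || prominence_fraction >= 1) {
    rlang::abort("prominence_fraction must lie in (0, 1)",
                 class = "mitodyn_error_invalid_input")
  }
  rng <- diff(range(series))
  if (rng == 0) return(list(peaks = integer(0), troughs = integer(0)))
  thr <- prominence_fraction * rng
  list(peaks = .prominent_maxima(series, thr),
       troughs = .prominent_maxima(-series, thr))
}

# Local maxima with prominence above `thr`. A strict rise on the left and a
# non-strict fall on the right picks the first sample of any flat top.
.prominent_maxima <- function(v, thr) {
  n <- length(v)
  cand <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
  keep <- vapply(cand, function(i) .prominence(v, i) > thr, logical(1))
  cand[keep]
}

.prominence <- function(v, i) {
  h <- v[i]
  left <- if (i > 1) {
    j <- i - 1L; lo <- v[j]
    while (j > 1 && v[j] <= h) { j <- j - 1L; lo <- min(lo, v[j]) }
    lo
  } else h
  right <- if (i < length(v)) {
    j <- i + 1L; lo <- v[j]
    while (j < length(v) && v[j] <= h) { j <- j + 1L; lo <- min(lo, v[j]) }
    lo
  } else h
  h - max(left, right)
}

# Parabolic refinement of an extremum location/value on a uniform grid:
# fits a quadratic to the three samples around index i. Sub-grid peak times
# keep period estimates stable under changes of the sampling rate.
.refine_extrema <- function(t, v, idx) {
  if (!length(idx)) return(list(times = numeric(0), values = numeric(0)))
  dt <- t[2] - t[1]
  n <- length(v)
  refine <- function(i) {
    if (i <= 1 || i >= n) return(c(t[i], v[i]))
    a <- v[i - 1]; b <- v[i]; cc <- v[i + 1]
    den <- a - 2 * b + cc
    if (den == 0) return(c(t[i], v[i]))
    delta <- 0.5 * (a - cc) / den
    delta <- max(min(delta, 0.5), -0.5)
    c(t[i] + delta * dt, b - 0.25 * (a - cc) * delta)
  }
  m <- vapply(idx, refine, numeric(2))
  list(times = m[1, ], values = m[2, ])
}

.trapz_mean <- function(t, v) {
  n <- length(v)
  sum((v[-1] + v[-n]) * diff(t)) / (2 * (t[n] - t[1]))
}

#' Oscillation metrics of a trajectory
#'
#' For each variable over the post-transient window: period (mean inter-peak
#' interval), frequency (1/period), amplitude (mean peak value minus mean
#' trough value), time-averaged level (trapezoidal), and detected peak
#' times. A variable with fewer than three prominent peaks is flagged
#' non-oscillatory: its period and frequency are `NA`, its amplitude 0.
#' The fission-fusion phase relation is summarised as the mean time from
#' each x-peak to the next z-peak, both in time units and as a fraction of
#' the x-period.
#'
#' @param traj A `mito_trajectory` from [mito_simulate()].
#' @param prominence_fraction Peak prominence threshold as a fraction of
#'   each series' global range; see [detect_peaks()].
#' @return A tibble of class `mito_metrics` with one row per variable:
#'   `variable`, `alias`, `n_peaks`, `oscillatory`, `period`, `frequency`,
#'   `amplitude`, `mean_level`, `peak_times` (list-column). Attributes
#'   `phase_lag_xz` (list: `time`, `fraction`, `per_cycle`) and `params`.
#' @examples
#' traj <- mito_simulate("normal", settings = solver_settings(t_end = 60))
#' oscillation_metrics(traj)
#' @export
oscillation_metrics <- function(traj, prominence_fraction = 0.1) {
  win <- post_transient(traj)
  labs <- variable_labels()
  rows <- purrr::map_dfr(c("x", "y", "z"), function(v) {
    vals <- win[[v]]
    pk <- detect_peaks(vals, prominence_fraction)
    pref <- .refine_extrema(win$time, vals, pk$peaks)
    tref <- .refine_extrema(win$time, vals, pk$troughs)
    osc <- length(pk$peaks) >= 3L
    period <- if (osc) mean(diff(pref$times)) else NA_real_
    tibble::tibble(
      variable = v,
      alias = labs$alias[labs$variable == v],
      n_peaks = length(pk$peaks),
      oscillatory = osc,
      period = period,
      frequency = if (osc) 1 / period else NA_real_,
      amplitude = if (osc && length(pk$troughs))
        mean(pref$values) - mean(tref$values) else 0,
      mean_level = .trapz_mean(win$time, vals),
      peak_times = list(pref$times)
    )
  })
  class(rows) <- c("mito_metrics", class(rows))
  attr(rows, "params") <- traj_params(traj)
  attr(rows, "prominence_fraction") <- prominence_fraction
  attr(rows, "phase_lag_xz") <- .phase_lag_xz(rows)
  rows
}

# Mean time from each x-peak to the next z-peak; fraction of the x-period.
.phase_lag_xz <- function(metrics) {
  tx <- metrics$peak_times[[which(metrics$variable == "x")]]
  tz <- metrics$peak_times[[which(metrics$variable == "z")]]
  px <- metrics$period[metrics$variable == "x"]
  if (length(tx) < 3L || length(tz) < 3L || is.na(px)) {
    return(list(time = NA_real_, fraction = NA_real_, per_cycle = numeric(0)))
  }
  lags <- purrr::map_dbl(tx, function(t0) {
    nxt <- tz[tz > t0]
    if (length(nxt)) nxt[1] - t0 else NA_real_
  })
  lags <- lags[!is.na(lags)]
  list(time = mean(lags), fraction = (mean(lags) / px) %% 1,
       per_cycle = lags)
}

#' Fission-to-fusion phase lag of a metrics object
#'
#' @param metrics A `mito_metrics` tibble.
#' @return List with `time` (mean x-peak to next z-peak delay), `fraction`
#'   (as a fraction of the x-period, in \[0, 1)) and `per_cycle` lags.
#' @export
phase_lag_xz <- function(metrics) attr(metrics, "phase_lag_xz")

#' Compare two sets of oscillation metrics
#'
#' Signed relative change `(b - a) / a` of frequency, amplitude, period and
#' mean level, per variable. Entries involving a non-oscillatory variable
#' are `NA` and flagged.
#'
#' @param a,b `mito_metrics` tibbles (condition a = baseline).
#' @return A tibble with columns `variable`, `metric`, `value_a`, `value_b`,
#'   `relative_change`, `defined`.
#' @export
compare_waveforms <- function(a, b) {
  pick <- function(m) {
    m |>
      tibble::as_tibble() |>
      dplyr::select("variable", "oscillatory", "frequency", "amplitude",
                    "period", "mean_level") |>
      tidyr::pivot_longer(c("frequency", "amplitude", "period", "mean_level"),
                          names_to = "metric", values_to = "value")
  }
  out <- dplyr::inner_join(pick(a), pick(b), by = c("variable", "metric"),
                           suffix = c("_a", "_b"))
  out |>
    dplyr::mutate(
      defined = .data$oscillatory_a & .data$oscillatory_b,
      relative_change = dplyr::if_else(
        .data$defined, (.data$value_b - .data$value_a) / .data$value_a,
        NA_real_)
    ) |>
    dplyr::select("variable", "metric", value_a = "value_a",
                  value_b = "value_b", "relative_change", "defined")
}

#' Write oscillation metrics to JSON / read them back
#'
#' @param metrics A `mito_metrics` tibble.
#' @param path Output file.
#' @export
write_metrics_json <- function(metrics, path) {
  lag <- phase_lag_xz(metrics)
  recs <- purrr::map(seq_len(nrow(metrics)), function(i) {
    r <- as.list(tibble::as_tibble(metrics)[i,
           c("variable", "alias", "n_peaks", "oscillatory", "period",
             "frequency", "amplitude", "mean_level")])
    r$peak_times <- metrics$peak_times[[i]]
    r
  })
  jsonlite::write_json(
    list(variables = recs,
         phase_lag_xz = list(time = lag$time, fraction = lag$fraction)),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Write a waveform comparison table to CSV
#'
#' Columns `variable,metric,value_a,value_b,relative_change`.
#'
#' @param comparison Output of [compare_waveforms()].
#' @param path Output file.
#' @export
write_comparison_csv <- function(comparison, path) {
  readr::write_csv(
    comparison[c("variable", "metric", "value_a", "value_b",
                 "relative_change")], path)
  invisible(path)
}
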