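# Synthetic replicate-level observations emulating a two-condition
# expression comparison, plus the Welch contrast.

#' Time-averaged factor levels of a condition
#'
#' Integrates a preset and returns the time-averaged level of each factor
#' over the post-transient window — the quantity a bulk measurement over
#' unsynchronized oscillators would see. If the regime is non-oscillatory
#' the interior steady-state level is returned instead and flagged.
#'
#' @param params A [mito_params()] object or preset name.
#' @param settings A [solver_settings()] object.
#' @return A tibble `variable`, `level`, `oscillatory`.
#' @export
condition_levels <- function(params, settings = solver_settings()) {
  if (is.character(params)) params <- preset_params(params)
  traj <- mito_simulate(params, settings = settings)
  m <- oscillation_metrics(traj)
  if (all(m$oscillatory)) {
    tibble::tibble(variable = m$variable, level = m$mean_level,
                   oscillatory = TRUE)
  } else {
    fp <- interior_fixed_state(params)
    tibble::tibble(variable = c("x", "y", "z"),
                   level = unname(fp[c("x", "y", "z")]),
                   oscillatory = FALSE)
  }
}

#' Generate noisy replicate-level observations under two conditions
#'
#' Emulates the structure of a two-condition expression comparison: for
#' each condition the model's time-averaged factor levels are the true
#' signal, and replicates are drawn with multiplicative lognormal noise of
#' coefficient of variation `noise_cv` (expression-like data are positive
#' and right-skewed; the CV parameterization keeps the noise scale
#' interpretable). The lognormal is mean-matched: each replicate's expected
#' value equals the true level. Lognormal draws are strictly positive, so
#' the non-negativity truncation is vacuous by construction. Generation is
#' driven by R's Mersenne-Twister generator with inversion sampling, so the
#' same seed reproduces the data bitwise on any platform.
#'
#' @param condition_a,condition_b Preset names or [mito_params()] objects.
#' @param n_replicates Replicates per condition, >= 3.
#' @param noise_cv Coefficient of variation of the multiplicative noise,
#'   in \[0, 1); 0 gives noise-free replicates equal to the true level.
#' @param seed Integer seed.
#' @param labels Length-2 character vector of condition labels; defaults to
#'   preset names when presets are given.
#' @param true_levels Optional precomputed list of two [condition_levels()]
#'   tibbles (named by label), bypassing integration — useful when drawing
#'   many datasets from the same conditions.
#' @param settings A [solver_settings()] object for the integrations.
#' @return A tidy tibble of class `mito_observations` with columns
#'   `condition`, `replicate`, `variable`, `level`, and metadata attributes
#'   (`seed`, `noise_cv`, `n_replicates`, `true_levels`, `noise_model`).
#' @examples
#' \donttest{
#' obs <- generate_observations("normal", "diseased", 6, 0.1, seed = 1)
#' contrast_observations(obs)
#' }
#' @export
generate_observations <- function(condition_a, condition_b,
                                  n_replicates = 6, noise_cv = 0.1,
                                  seed = 1L, labels = NULL,
                                  true_levels = NULL,
                                  settings = solver_settings()) {
  if (n_replicates < 3) {
    rlang::abort("n_replicates must be at least 3",
                 class = "mitodyn_error_invalid_input")
  }
  if (noise_cv < 0 || noise_cv >= 1) {
    rlang::abort("noise_cv must lie in [0, 1)",
                 class = "mitodyn_error_invalid_input")
  }
  if (is.null(labels)) {
    labels <- c(
      if (is.character(condition_a)) condition_a else "condition_a",
      if (is.character(condition_b)) condition_b else "condition_b"
    )
  }
  if (is.null(true_levels)) {
    true_levels <- list(condition_levels(condition_a, settings),
                        condition_levels(condition_b, settings))
    names(true_levels) <- labels
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion")
  sdlog <- sqrt(log1p(noise_cv^2))
  draws <- purrr::map2_dfr(labels, true_levels, function(lab, tl) {
    purrr::map_dfr(seq_len(nrow(tl)), function(i) {
      mu <- tl$level[i]
      lv <- if (noise_cv == 0) rep(mu, n_replicates) else
        stats::rlnorm(n_replicates, meanlog = log(mu) - sdlog^2 / 2,
                      sdlog = sdlog)
      tibble::tibble(condition = lab,
                     replicate = seq_len(n_replicates),
                     variable = tl$variable[i],
                     level = pmax(lv, 0))
    })
  }) |>
    dplyr::arrange(match(.data$condition, labels), .data$replicate,
                   .data$variable)
  class(draws) <- c("mito_observations", class(draws))
  attr(draws, "seed") <- as.integer(seed)
  attr(draws, "noise_cv") <- noise_cv
  attr(draws, "n_replicates") <- n_replicates
  attr(draws, "true_levels") <- true_levels
  attr(draws, "noise_model") <- "multiplicative lognormal (mean-matched), Mersenne-Twister/Inversion"
  draws
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Welch contrast of a two-condition observation set
#'
#' Per-variable difference of means with a two-sample unequal-variance
#' (Welch) t statistic and two-sided p-value, degrees of freedom by
#' Welch-Satterthwaite — the comparison style standard for small-replicate
#' expression contrasts. The statistic is signed as
#' `(mean_a - mean_b) / se`.
#'
#' @param obs A `mito_observations` tibble (exactly two conditions, >= 3
#'   replicates each).
#' @return A tibble `variable`, `condition_a`, `condition_b`, `mean_a`,
#'   `mean_b`, `difference` (`mean_b - mean_a`), `t`, `df`, `p_value`,
#'   `defined`.
#' @export
contrast_observations <- function(obs) {
  conds <- unique(obs$condition)
  if (length(conds) != 2L) {
    rlang::abort("observations must carry exactly two conditions",
                 class = "mitodyn_error_invalid_input")
  }
  purrr::map_dfr(unique(obs$variable), function(v) {
    a <- obs$level[obs$variable == v & obs$condition == conds[1]]
    b <- obs$level[obs$variable == v & obs$condition == conds[2]]
    if (length(a) < 3L || length(b) < 3L) {
      rlang::abort("need at least 3 replicates per condition",
                   class = "mitodyn_error_invalid_input")
    }
    tt <- tryCatch(stats::t.test(a, b, var.equal = FALSE), error = function(e) NULL)
    tibble::tibble(
      variable = v, condition_a = conds[1], condition_b = conds[2],
      mean_a = mean(a), mean_b = mean(b), difference = mean(b) - mean(a),
      t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
      df = if (is.null(tt)) NA_real_ else unname(tt$parameter),
      p_value = if (is.null(tt)) NA_real_ else tt$p.value,
      defined = !is.null(tt)
    )
  })
}

#' Write observations as tidy CSV with a sidecar metadata JSON
#'
#' @param obs A `mito_observations` tibble.
#' @param path CSV path; metadata goes to `<path>.json`.
#' @export
write_observations <- function(obs, path) {
  readr::write_csv(
    tibble::as_tibble(obs[c("condition", "replicate", "variable", "level")]),
    path)
  tl <- attr(obs, "true_levels")
  meta <- list(
    seed = attr(obs, "seed"), noise_cv = attr(obs, "noise_cv"),
    n_replicates = attr(obs, "n_replicates"),
    noise_model = attr(obs, "noise_model"),
    true_levels = purrr::map(tl, ~ purrr::transpose(as.list(.x)))
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
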