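# Model equations, Jacobian, fixed points, linear stability.

as_state <- function(state) {
  s <- as.numeric(state)
  if (length(s) != 3L || anyNA(s) || any(!is.finite(s))) {
    rlang::abort("state must be three finite numbers (x, y, z)",
                 class = "mitodyn_error_invalid_input")
  }
  names(s) <- c("x", "y", "z")
  s
}

#' Time derivatives of the fission-fusion oscillator
#'
#' The model is the Oregonator reduction of the Belousov-Zhabotinsky
#' mechanism mapped onto mitochondrial dynamics:
#' \deqn{\dot x = (q y - x y + x(1 - x)) / \epsilon}
#' \deqn{\dot y = (-q y - x y + f z) / \epsilon'}
#' \deqn{\dot z = x - z}
#' with `x` the fission factor (DRP1, autocatalytic activator), `y` the
#' intermediary factor (MiD49/51) and `z` the fusion factor (MFN1/2, OPA1)
#' closing the delayed negative feedback loop.
#'
#' @param state Numeric vector `(x, y, z)`, all finite.
#' @param params A [mito_params()] object (or coercible named list).
#' @return Named numeric vector `(x, y, z)` of time derivatives.
#' @examples
#' mito_rhs(c(0.1, 0.1, 0.1), preset_params("normal"))
#' @export
mito_rhs <- function(state, params) {
  validate_params(params)
  s <- as_state(state)
  x <- s[[1]]; y <- s[[2]]; z <- s[[3]]
  c(
    x = (params$q * y - x * y + x * (1 - x)) / params$epsilon,
    y = (-params$q * y - x * y + params$f * z) / params$epsilon_prime,
    z = x - z
  )
}

#' Analytic Jacobian of the model
#'
#' Entry (i, j) is the partial derivative of the i-th component of
#' [mito_rhs()] with respect to the j-th state variable.
#'
#' @inheritParams mito_rhs
#' @return A 3x3 numeric matrix with dimnames `x`, `y`, `z`.
#' @export
mito_jacobian <- function(state, params) {
  validate_params(params)
  s <- as_state(state)
  x <- s[[1]]; y <- s[[2]]
  e <- params$epsilon; ep <- params$epsilon_prime
  J <- matrix(c(
    (1 - 2 * x - y) / e, (params$q - x) / e, 0,
    -y / ep,             -(params$q + x) / ep, params$f / ep,
    1,                   0,                   -1
  ), nrow = 3, byrow = TRUE)
  dimnames(J) <- list(c("x", "y", "z"), c("x", "y", "z"))
  J
}

# Interior steady state in closed form. Setting the derivatives to zero and
# substituting z* = x*, y* = f x* / (q + x*) reduces the system to the
# quadratic x^2 - (1 - q - f) x - q (1 + f) = 0, whose positive root always
# exists for positive parameters.
interior_fixed_state <- function(params) {
  b <- 1 - params$q - params$f
  disc <- b^2 + 4 * params$q * (1 + params$f)
  xs <- (b + sqrt(disc)) / 2
  c(x = xs, y = params$f * xs / (params$q + xs), z = xs)
}

classify_stability <- function(eigenvalues, tol = 1e-9) {
  re <- Re(eigenvalues)
  if (any(re > tol)) "unstable" else if (all(re < -tol)) "stable" else "marginal"
}

#' Fixed points and linear stability
#'
#' Returns the origin and the positive interior steady state of the model,
#' each with the eigenvalues of the analytic Jacobian and a stability label
#' (`unstable` if any eigenvalue real part exceeds `tol`, `stable` if all
#' are below `-tol`, else `marginal`). Sustained oscillations of the model
#' correspond to an unstable interior fixed point surrounded by a limit
#' cycle; the origin is reported for completeness but carries no dynamical
#' conclusion at operating concentrations.
#'
#' @inheritParams mito_rhs
#' @param tol Tolerance on eigenvalue real parts separating numerical zero
#'   from genuine instability.
#' @return A tibble of class `mito_fixed_points` with columns `point`
#'   (`"origin"`, `"interior"`), `x`, `y`, `z`, `eigenvalues` (list-column
#'   of complex 3-vectors), `max_re` and `stability`.
#' @examples
#' fixed_points(preset_params("normal"))
#' @export
fixed_points <- function(params, tol = 1e-9) {
  validate_params(params)
  states <- list(origin = c(x = 0, y = 0, z = 0),
                 interior = interior_fixed_state(params))
  rows <- purrr::imap(states, function(s, nm) {
    ev <- eigen(mito_jacobian(s, params), only.values = TRUE)$values
    tibble::tibble(
      point = nm, x = s[["x"]], y = s[["y"]], z = s[["z"]],
      eigenvalues = list(as.complex(ev)),
      max_re = max(Re(ev)),
      stability = classify_stability(ev, tol)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("mito_fixed_points", class(out))
  attr(out, "params") <- params
  out
}

#' Serialize a fixed-point report to JSON
#'
#' Writes state, eigenvalues (as real/imaginary pairs) and stability label
#' for every fixed point; [read_fixed_points_json()] restores the tibble.
#'
#' @param fp A `mito_fixed_points` tibble from [fixed_points()].
#' @param path Output file.
#' @export
write_fixed_points_json <- function(fp, path) {
  recs <- purrr::map(seq_len(nrow(fp)), function(i) {
    ev <- fp$eigenvalues[[i]]
    list(
      point = fp$point[i],
      state = list(x = fp$x[i], y = fp$y[i], z = fp$z[i]),
      eigenvalues = purrr::map(ev, ~ list(re = Re(.x), im = Im(.x))),
      stability = fp$stability[i]
    )
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fixed_points_json
#' @export
read_fixed_points_json <- function(path) {
  recs <- jsonlite::read_json(path)
  dplyr::bind_rows(purrr::map(recs, function(r) {
    ev <- vapply(r$eigenvalues,
                 function(e) complex(real = e$re, imaginary = e$im),
                 complex(1))
    tibble::tibble(
      point = r$point, x = r$state$x, y = r$state$y, z = r$state$z,
      eigenvalues = list(ev), max_re = max(Re(ev)), stability = r$stability
    )
  }))
}
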