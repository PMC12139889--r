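# Phase-plane machinery: orbits, Poincare sections, nullclines.

#' Phase-plane orbit with Poincare return distances
#'
#' Projects the post-transient trajectory onto a variable pair and measures
#' convergence to a closed orbit through a Poincare section anchored at the
#' interior fixed point: the plane `x = x*` crossed in the direction of
#' increasing x, which is transversal to the limit cycle. `cycle_closure`
#' is the sequence of Euclidean distances between consecutive section
#' crossings in the (y, z) plane; for a trajectory settled on a limit cycle
#' these distances are a small fraction of the orbit diameter.
#'
#' @param traj A `mito_trajectory`.
#' @param pair Variable pair to project onto: `c("x", "y")` or `c("x", "z")`
#'   (any two of the three variables are accepted).
#' @param include_transient If `TRUE`, the section crossings (not the
#'   projected points) are computed from the full trajectory, exposing the
#'   contraction of the return map during the approach to the cycle.
#' @return A tibble of class `mito_orbit` with columns `u`, `v` (the
#'   projected post-transient points). Attributes: `pair`, `oscillatory`,
#'   `cycle_closure` (numeric vector, length 0 when fewer than two
#'   crossings), `diameter`, `section_x`.
#' @export
phase_orbit <- function(traj, pair = c("x", "y"), include_transient = FALSE) {
  stopifnot(length(pair) == 2L, all(pair %in% c("x", "y", "z")),
            pair[1] != pair[2])
  win <- post_transient(traj)
  fp <- fixed_points(traj_params(traj))
  xs <- fp$x[fp$point == "interior"]
  src <- if (include_transient) traj else win
  cross <- .section_crossings(src$time, src$x, src$y, src$z, xs)
  closure <- if (nrow(cross) >= 2L) {
    sqrt(diff(cross$y)^2 + diff(cross$z)^2)
  } else numeric(0)
  out <- tibble::tibble(time = win$time, u = win[[pair[1]]],
                        v = win[[pair[2]]])
  class(out) <- c("mito_orbit", class(out))
  attr(out, "pair") <- pair
  attr(out, "oscillatory") <- nrow(cross) >= 2L
  attr(out, "cycle_closure") <- closure
  attr(out, "diameter") <- sqrt(diff(range(out$u))^2 + diff(range(out$v))^2)
  attr(out, "section_x") <- xs
  attr(out, "section_points") <- cross
  out
}

# Upward crossings of x = xs, linearly interpolated in time.
.section_crossings <- function(time, x, y, z, xs) {
  n <- length(x)
  i <- which(x[-n] < xs & x[-1] >= xs)
  if (!length(i)) {
    return(tibble::tibble(time = numeric(0), y = numeric(0), z = numeric(0)))
  }
  th <- (xs - x[i]) / (x[i + 1] - x[i])
  tibble::tibble(
    time = time[i] + th * (time[i + 1] - time[i]),
    y = y[i] + th * (y[i + 1] - y[i]),
    z = z[i] + th * (z[i + 1] - z[i])
  )
}

#' @rdname phase_orbit
#' @param orbit A `mito_orbit`.
#' @export
cycle_closure <- function(orbit) attr(orbit, "cycle_closure")

#' @rdname phase_orbit
#' @export
orbit_diameter <- function(orbit) attr(orbit, "diameter")

#' Winding number of one cycle of an orbit around a point
#'
#' Sums signed angle increments along one full cycle of the projected
#' orbit (the stretch between the last two Poincare section crossings,
#' falling back to the whole window divided by the number of crossings);
#' a value of +-1 means the point lies inside the cycle. Used to check
#' that the interior fixed point sits inside the x-y limit cycle.
#'
#' @param orbit A `mito_orbit`.
#' @param point Numeric `(u, v)` coordinates in the orbit's plane.
#' @return The (rounded) winding number.
#' @export
orbit_winding <- function(orbit, point) {
  sec <- attr(orbit, "section_points")
  pts <- orbit
  if (!is.null(sec) && nrow(sec) >= 2L) {
    tlast <- utils::tail(sec$time, 2)
    sel <- orbit$time >= tlast[1] & orbit$time <= tlast[2]
    if (sum(sel) > 10L) pts <- orbit[sel, ]
  }
  du <- pts$u - point[1]
  dv <- pts$v - point[2]
  ang <- atan2(dv, du)
  inc <- diff(ang)
  inc <- ifelse(inc > pi, inc - 2 * pi, ifelse(inc < -pi, inc + 2 * pi, inc))
  round(sum(inc) / (2 * pi))
}

#' Nullclines of the model on a 2-D slice
#'
#' Solves each `derivative = 0` condition on a rectangular domain holding
#' the third variable at a fixed slice value (default: its interior
#' fixed-point value, so all three nullclines meet at the fixed point).
#' Closed forms are used — the x-nullcline in the (x, y) plane is
#' `y = x (1 - x) / (x - q)`, the y-nullcline is `y = f z / (q + x)`, the
#' z-nullcline in the (x, z) plane is the diagonal `z = x` — and each point
#' is polished by bisection until the zeroed derivative is below `1e-8` in
#' absolute value.
#'
#' @param params A [mito_params()] object or preset name.
#' @param slice_value Value at which the third variable is held; `NULL`
#'   means its interior fixed-point value.
#' @param domain Rectangle `c(u_min, u_max, v_min, v_max)` in the
#'   non-negative quadrant of each nullcline's plane.
#' @param grid_n Number of grid points along the abscissa, >= 50.
#' @return A tibble with columns `equation` (`"dx"`, `"dy"`, `"dz"`),
#'   `plane` (e.g. `"x-y"`), `u`, `v`, `residual`.
#' @export
nullclines <- function(params, slice_value = NULL,
                       domain = c(0, 1, 0, 10), grid_n = 201) {
  if (is.character(params)) params <- preset_params(params)
  validate_params(params)
  stopifnot(grid_n >= 50, length(domain) == 4, domain[1] >= 0, domain[3] >= 0)
  fpi <- interior_fixed_state(params)
  ug <- seq(domain[1], domain[2], length.out = grid_n)

  polish <- function(g, u, v0) {
    # g is monotone/affine in v near the closed form; bracket then bisect
    if (!is.finite(v0)) return(NA_real_)
    if (abs(g(u, v0)) < 1e-8) return(v0)
    h <- max(abs(v0), 1) * 1e-6
    lo <- v0 - h; hi <- v0 + h
    while (sign(g(u, lo)) == sign(g(u, hi)) && h < 1e3) {
      h <- h * 10; lo <- v0 - h; hi <- v0 + h
    }
    if (sign(g(u, lo)) == sign(g(u, hi))) return(NA_real_)
    stats::uniroot(function(v) g(u, v), c(lo, hi), tol = 1e-14)$root
  }

  # dx/dt = 0 in (x, y), z free (does not enter dx/dt)
  gx <- function(x, y) (params$q * y - x * y + x * (1 - x)) / params$epsilon
  yx <- vapply(ug, function(x) {
    v0 <- x * (1 - x) / (x - params$q)
    polish(gx, x, v0)
  }, numeric(1))
  dx_tab <- tibble::tibble(equation = "dx", plane = "x-y", u = ug, v = yx)

  # dy/dt = 0 in (x, y) at z = slice
  zs <- if (is.null(slice_value)) fpi[["z"]] else slice_value
  gy <- function(x, y) (-params$q * y - x * y + params$f * zs) / params$epsilon_prime
  yy <- vapply(ug, function(x) polish(gy, x, params$f * zs / (params$q + x)),
               numeric(1))
  dy_tab <- tibble::tibble(equation = "dy", plane = "x-y", u = ug, v = yy)

  # dz/dt = 0 in (x, z): z = x, exact
  dz_tab <- tibble::tibble(equation = "dz", plane = "x-z", u = ug, v = ug)

  out <- dplyr::bind_rows(dx_tab, dy_tab, dz_tab) |>
    dplyr::filter(is.finite(.data$v), .data$v >= domain[3],
                  .data$v <= domain[4])
  res <- function(eq, u, v) {
    switch(eq, dx = gx(u, v), dy = gy(u, v), dz = u - v)
  }
  out$residual <- purrr::pmap_dbl(out[c("equation", "u", "v")],
                                  function(equation, u, v) res(equation, u, v))
  attr(out, "slice_value") <- zs
  attr(out, "params") <- params
  out
}
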