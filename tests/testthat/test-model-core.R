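test_that("presets carry the printed parameter regimes", {
  pr <- mito_presets()
  expect_setequal(pr$preset, all_presets)
  expect_equal(
    pr[pr$preset == "oregonator", c("epsilon", "epsilon_prime", "q", "f")],
    tibble::tibble(epsilon = 3.6e-2, epsilon_prime = 1.2e-4, q = 2.4e-4,
                   f = 1))
  expect_equal(
    pr[pr$preset == "normal", c("epsilon", "epsilon_prime", "q", "f")],
    tibble::tibble(epsilon = 0.01, epsilon_prime = 0.001, q = 0.01, f = 1))
  expect_equal(
    pr[pr$preset == "diseased", c("epsilon", "epsilon_prime", "q", "f")],
    tibble::tibble(epsilon = 0.005, epsilon_prime = 0.0005, q = 0.02,
                   f = 0.6))
  expect_equal(
    pr[pr$preset == "therapy", c("epsilon", "epsilon_prime", "q", "f")],
    tibble::tibble(epsilon = 0.005, epsilon_prime = 0.0005, q = 0.02,
                   f = 1.2))
  # the fast intermediary layer: epsilon_prime << epsilon in every regime
  expect_true(all(pr$epsilon_prime < pr$epsilon))
})

test_that("preset lookup is case-insensitive and rejects unknown names", {
  expect_equal(preset_params("Normal"), preset_params("normal"))
  expect_equal(preset_params("  THERAPY "), preset_params("therapy"))
  expect_error(preset_params("bogus"), class = "mitodyn_error_invalid_input")
  expect_error(preset_params(c("normal", "therapy")),
               class = "mitodyn_error_invalid_input")
})

test_that("parameter validation rejects non-positive and non-finite values", {
  expect_error(mito_params(0, 1e-3, 0.01, 1),
               class = "mitodyn_error_invalid_input")
  expect_error(mito_params(0.01, -1e-3, 0.01, 1),
               class = "mitodyn_error_invalid_input")
  expect_error(mito_params(0.01, 1e-3, NA, 1),
               class = "mitodyn_error_invalid_input")
  expect_error(mito_params(0.01, 1e-3, 0.01, Inf),
               class = "mitodyn_error_invalid_input")
})

test_that("rhs reproduces the model equations at hand-checked states", {
  p <- preset_params("normal")
  # origin is an equilibrium
  expect_equal(unname(mito_rhs(c(0, 0, 0), p)), c(0, 0, 0))
  # at (1,0,0) only the fusion equation is active: dz = x - z = 1
  expect_equal(unname(mito_rhs(c(1, 0, 0), p)), c(0, 0, 1))
  # hand arithmetic: dx = (0.005 - 0.25 + 0.25)/0.01, dy = (-0.005 - 0.25
  # + 0.5)/0.001, dz = 0.5 - 0.5
  expect_equal(unname(mito_rhs(c(0.5, 0.5, 0.5), p)), c(0.5, 245, 0))
  expect_error(mito_rhs(c(Inf, 0, 0), p),
               class = "mitodyn_error_invalid_input")
  expect_error(mito_rhs(c(0, 0), p), class = "mitodyn_error_invalid_input")
})

test_that("analytic Jacobian matches hand evaluation and the fusion row is exact", {
  p1 <- mito_params(1, 1, 1, 1)
  expect_equal(unname(mito_jacobian(c(1, 1, 1), p1)),
               matrix(c(-2, 0, 0, -1, -2, 1, 1, 0, -1), 3, byrow = TRUE))
  # the fusion equation is linear: its Jacobian row never depends on state
  J <- mito_jacobian(c(0, 0, 0), preset_params("normal"))
  expect_equal(unname(J[3, ]), c(1, 0, -1))
})

test_that("analytic Jacobian agrees with a finite-difference oracle at random states", {
  set.seed(42)
  p <- preset_params("normal")
  for (i in 1:20) {
    s <- stats::runif(3, 0.01, 2)
    J <- mito_jacobian(s, p)
    Jfd <- fd_jacobian(s, p)
    rel <- abs(J - Jfd) / pmax(abs(Jfd), 1e-8)
    expect_lt(max(rel), 1e-4)
  }
})

test_that("fixed points satisfy the equations and the quadratic closed form", {
  fp_n <- fixed_points(preset_params("normal"))
  expect_setequal(fp_n$point, c("origin", "interior"))
  # back-substituted quadratic root (frozen from hand/numeric evaluation)
  xi <- fp_n[fp_n$point == "interior", ]
  expect_equal(xi$x, 0.13650972, tolerance = 1e-6)
  expect_equal(xi$y, 0.93174475, tolerance = 1e-6)
  expect_equal(xi$z, xi$x)
  fp_o <- fixed_points(preset_params("oregonator"))
  expect_equal(fp_o$x[fp_o$point == "interior"], 0.02178926,
               tolerance = 1e-5)
  # residual of the vector field at every returned fixed point
  for (nm in all_presets) {
    p <- preset_params(nm)
    fp <- fixed_points(p)
    for (i in seq_len(nrow(fp))) {
      expect_lt(max(abs(mito_rhs(c(fp$x[i], fp$y[i], fp$z[i]), p))), 1e-10)
    }
  }
})

test_that("closed-form fixed point agrees with an independent multivariate root-finder", {
  grid <- random_param_grid(50, seed = 7)
  for (i in seq_len(nrow(grid))) {
    p <- mito_params(grid$epsilon[i], grid$epsilon_prime[i], grid$q[i],
                     grid$f[i])
    fp <- fixed_points(p)
    xi <- unlist(fp[fp$point == "interior", c("x", "y", "z")])
    root <- oracle_interior_root(p)
    expect_lt(max(abs(xi - root)), 1e-8)
  }
})

test_that("all four presets have an unstable interior fixed point", {
  for (nm in all_presets) {
    fp <- fixed_points(preset_params(nm))
    xi <- fp[fp$point == "interior", ]
    expect_identical(xi$stability, "unstable")
    expect_gt(xi$max_re, 1e-9)
  }
})

test_that("stability classification separates stable, unstable and marginal", {
  expect_identical(mitodyn:::classify_stability(c(-1 + 0i, -2, -3)), "stable")
  expect_identical(mitodyn:::classify_stability(c(1e-8, -2, -3)), "unstable")
  expect_identical(mitodyn:::classify_stability(c(1e-12 + 5i, -2, -3)),
                   "marginal")
})

test_that("preset config files round-trip and override the built-ins", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_presets_config(mito_presets(), path)
  back <- read_presets_config(path)
  expect_equal(back, mito_presets())
  # user-supplied regime, case-insensitive lookup
  writeLines(c("MyRegime:", "  epsilon: 0.02", "  epsilon_prime: 0.002",
               "  q: 0.015", "  f: 0.9"), path)
  custom <- read_presets_config(path)
  p <- preset_params("myregime", presets = custom)
  expect_equal(p$f, 0.9)
  expect_error(preset_params("normal", presets = custom),
               class = "mitodyn_error_invalid_input")
})

test_that("fixed-point reports round-trip through JSON", {
  fp <- fixed_points(preset_params("diseased"))
  path <- withr::local_tempfile(fileext = ".json")
  write_fixed_points_json(fp, path)
  back <- read_fixed_points_json(path)
  expect_equal(back$x, fp$x)
  expect_equal(back$eigenvalues, fp$eigenvalues)
  expect_equal(back$stability, fp$stability)
})
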