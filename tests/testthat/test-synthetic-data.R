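# True signal levels for the generator, integrated once and reused across
# the Monte-Carlo assertions below.
true_levels_pair <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      val <<- list(normal = condition_levels("normal"),
                   diseased = condition_levels("diseased"))
    }
    val
  }
})

test_that("condition levels are the time-averaged factor levels", {
  tl <- true_levels_pair()$normal
  m <- cached_metrics("normal")
  expect_equal(tl$level, m$mean_level)
  expect_true(all(tl$oscillatory))
  # the fusion equation dz/dt = x - z forces equal x and z time averages
  # over whole cycles
  expect_equal(tl$level[tl$variable == "z"], tl$level[tl$variable == "x"],
               tolerance = 0.02)
})

test_that("a damped regime falls back to the steady-state level, flagged", {
  p <- mito_params(0.01, 0.001, 0.01, 5)
  tl <- condition_levels(p, solver_settings(t_end = 50, dt_out = 0.01))
  expect_false(any(tl$oscillatory))
  fp <- fixed_points(p)
  expect_equal(tl$level, unname(unlist(fp[fp$point == "interior",
                                          c("x", "y", "z")])))
})

test_that("the zero-noise limit reproduces the true levels exactly", {
  obs <- generate_observations("normal", "diseased", n_replicates = 4,
                               noise_cv = 0, seed = 3,
                               true_levels = true_levels_pair(),
                               labels = c("normal", "diseased"))
  tl <- true_levels_pair()
  for (cond in c("normal", "diseased")) {
    for (v in c("x", "y", "z")) {
      lv <- obs$level[obs$condition == cond & obs$variable == v]
      expect_true(all(abs(lv - tl[[cond]]$level[tl[[cond]]$variable == v])
                      < 1e-9))
    }
  }
})

test_that("generation is seed-deterministic and seed-sensitive", {
  tl <- true_levels_pair()
  a <- generate_observations("normal", "diseased", 6, 0.1, seed = 42,
                             true_levels = tl,
                             labels = c("normal", "diseased"))
  b <- generate_observations("normal", "diseased", 6, 0.1, seed = 42,
                             true_levels = tl,
                             labels = c("normal", "diseased"))
  cc <- generate_observations("normal", "diseased", 6, 0.1, seed = 43,
                              true_levels = tl,
                              labels = c("normal", "diseased"))
  expect_identical(a$level, b$level)
  expect_false(identical(a$level, cc$level))
  expect_true(all(a$level >= 0))
  # generation does not disturb the caller's RNG stream
  set.seed(1); before <- stats::runif(1)
  set.seed(1)
  invisible(generate_observations("normal", "diseased", 6, 0.1, seed = 9,
                                  true_levels = tl,
                                  labels = c("normal", "diseased")))
  expect_identical(stats::runif(1), before)
})

test_that("the lognormal noise is mean-matched at the requested CV", {
  tl <- true_levels_pair()
  obs <- generate_observations("normal", "diseased", 2000, 0.2, seed = 5,
                               true_levels = tl,
                               labels = c("normal", "diseased"))
  x <- obs$level[obs$condition == "normal" & obs$variable == "x"]
  mu <- tl$normal$level[tl$normal$variable == "x"]
  expect_equal(mean(x), mu, tolerance = 0.02)
  expect_equal(stats::sd(x) / mean(x), 0.2, tolerance = 0.05)
})

test_that("generator validates replicate count and noise scale", {
  tl <- true_levels_pair()
  expect_error(generate_observations("normal", "diseased", 2, 0.1, seed = 1,
                                     true_levels = tl),
               class = "mitodyn_error_invalid_input")
  expect_error(generate_observations("normal", "diseased", 6, 1.2, seed = 1,
                                     true_levels = tl),
               class = "mitodyn_error_invalid_input")
})

test_that("the Welch contrast matches a hand computation", {
  obs <- tibble::tibble(
    condition = rep(c("a", "b"), each = 3),
    replicate = rep(1:3, 2),
    variable = "x",
    level = c(1, 2, 3, 4, 5, 6))
  ct <- contrast_observations(obs)
  # pooled se = sqrt(1/3 + 1/3); t = (2 - 5) / se = -3.674; Welch df = 4
  expect_equal(round(ct$t, 3), -3.674)
  expect_equal(ct$df, 4)
  expect_equal(ct$difference, 3)
})

test_that("degenerate contrasts are handled explicitly", {
  ident <- tibble::tibble(
    condition = rep(c("a", "b"), each = 4),
    replicate = rep(1:4, 2), variable = "x",
    level = rep(c(1, 2, 3, 4), 2))
  ct <- contrast_observations(ident)
  expect_equal(ct$t, 0)
  expect_equal(ct$p_value, 1)
  const <- tibble::tibble(
    condition = rep(c("a", "b"), each = 3),
    replicate = rep(1:3, 2), variable = "x", level = rep(2, 6))
  ct2 <- contrast_observations(const)
  expect_false(ct2$defined)
  expect_true(is.na(ct2$t))
})

test_that("the Welch contrast is calibrated under the null", {
  tl <- true_levels_pair()
  null_levels <- list(a = tl$normal, b = tl$normal)
  hits <- purrr::map_lgl(1:1000, function(s) {
    obs <- generate_observations("normal", "normal", 6, 0.1, seed = s,
                                 true_levels = null_levels,
                                 labels = c("a", "b"))
    ct <- contrast_observations(obs)
    ct$p_value[ct$variable == "x"] < 0.05
  })
  expect_gte(mean(hits), 0.03)
  expect_lte(mean(hits), 0.07)
})

test_that("small noise recovers the sign of every true difference", {
  tl <- true_levels_pair()
  truth <- sign(tl$diseased$level - tl$normal$level)
  ok <- purrr::map_lgl(1:200, function(s) {
    obs <- generate_observations("normal", "diseased", 6, 0.05, seed = s,
                                 true_levels = tl,
                                 labels = c("normal", "diseased"))
    ct <- contrast_observations(obs)
    all(sign(ct$difference) == truth[match(ct$variable,
                                           tl$normal$variable)])
  })
  expect_gte(mean(ok), 0.99)
})

test_that("the fusion-level gap dominates 10% noise in nearly every draw", {
  tl <- true_levels_pair()
  higher <- purrr::map_lgl(1:200, function(s) {
    obs <- generate_observations("normal", "diseased", 6, 0.1, seed = s,
                                 true_levels = tl,
                                 labels = c("normal", "diseased"))
    ct <- contrast_observations(obs)
    ct$difference[ct$variable == "z"] > 0
  })
  expect_gte(mean(higher), 0.95)
})

test_that("observations round-trip to tidy CSV with metadata sidecar", {
  obs <- generate_observations("normal", "diseased", 5, 0.1, seed = 8,
                               true_levels = true_levels_pair(),
                               labels = c("normal", "diseased"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_observations(obs, path)
  tab <- readr::read_csv(path, show_col_types = FALSE)
  expect_named(tab, c("condition", "replicate", "variable", "level"))
  expect_equal(tab$level, obs$level)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$seed, 8)
  expect_equal(meta$noise_cv, 0.1)
  expect_named(meta$true_levels, c("normal", "diseased"))
})
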