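test_that("hooke_jeeves solves smooth test problems", {
  r1 <- hooke_jeeves(function(x) (x - 2)^2, 0, tol = 1e-6)
  expect_equal(r1$x_opt, 2, tolerance = 1e-4)
  expect_true(r1$converged)

  r2 <- hooke_jeeves(function(x) (x[1] - 1)^2 + 10 * (x[2] + 3)^2,
                     c(0, 0), tol = 1e-6, max_iter = 5000)
  expect_equal(r2$x_opt, c(1, -3), tolerance = 1e-3)
  expect_lte(r2$f_opt, (0 - 1)^2 + 10 * (0 + 3)^2)
})

test_that("hooke_jeeves beats a dense random search on the Rosenbrock valley", {
  rosen <- function(x) (1 - x[1])^2 + 100 * (x[2] - x[1]^2)^2
  res <- hooke_jeeves(rosen, c(-1.2, 1), step0 = 0.5, tol = 1e-7,
                      max_iter = 20000, lower = c(-2, -2), upper = c(2, 2))
  # independent oracle: 1e6 uniform draws over the same box
  set.seed(11)
  xs <- matrix(runif(2e6, -2, 2), ncol = 2)
  f_rand <- min((1 - xs[, 1])^2 + 100 * (xs[, 2] - xs[, 1]^2)^2)
  expect_lt(res$f_opt, f_rand)
})

test_that("hooke_jeeves respects box bounds and never worsens the start", {
  f <- function(x) sum(x^2)
  res <- hooke_jeeves(f, c(2, 2), lower = c(1, -5), upper = c(5, 5),
                      tol = 1e-6)
  expect_gte(res$x_opt[1], 1)
  expect_equal(res$x_opt, c(1, 0), tolerance = 1e-3)
  expect_lte(res$f_opt, f(c(2, 2)))
})

test_that("sse_objective matches direct arithmetic on a toy problem", {
  # 1-parameter exponential decay model, predictions computed by hand
  toy_params <- suppressWarnings(validate_parameters(tibble::tibble(
    name = "k", value = 0.5, unit = "1/d", source = "fitted",
    ci_lo = NA_real_, ci_hi = NA_real_)))
  times <- c(1, 2, 4, 8, 16)
  toy_predict <- function(params, dataset) {
    k <- params$value[params$name == "k"]
    exp(-k * as.numeric(dataset$condition))
  }
  truth <- exp(-0.3 * times)
  ds <- calibration_dataset(observable = "decay", condition = as.character(times),
                            value = truth, weight = rep(1, 5))
  prob <- suppressWarnings(fit_problem(ds, toy_params, free = "k",
                                       predict = toy_predict))
  sse <- sse_objective(0.5, prob)
  expect_equal(sse, sum((exp(-0.5 * times) - truth)^2), tolerance = 1e-10)
  # self-consistency: truth parameters give zero
  expect_equal(sse_objective(0.3, prob), 0, tolerance = 1e-12)

  ft <- fit_model(prob)
  expect_equal(unname(ft$estimate), 0.3, tolerance = 1e-3)
  expect_lte(ft$sse, ft$sse_initial)
  expect_identical(nrow(tidy(ft)), 1L)
  expect_true(glance(ft)$converged)
})

test_that("one-sided observations only penalize violations", {
  toy_params <- suppressWarnings(validate_parameters(tibble::tibble(
    name = "a", value = 2, unit = "au", source = "fitted",
    ci_lo = NA_real_, ci_hi = NA_real_)))
  toy_predict <- function(params, dataset) {
    rep(params$value[params$name == "a"], nrow(dataset))
  }
  ds <- calibration_dataset("level", "c", value = 5, weight = 1,
                            bound = "le")
  prob <- suppressWarnings(fit_problem(ds, toy_params, free = "a",
                                       predict = toy_predict))
  expect_equal(sse_objective(4, prob), 0)
  expect_equal(sse_objective(7, prob), 4)
})

test_that("synthetic observations are reproducible with calibrated noise", {
  p <- cd_parameters()
  design <- tibble::tibble(
    observable = rep("villous_area_pct", 50),
    condition = rep(c("patient_gluten", "patient_gfd"), 25))
  d1 <- synth_observations(p, design, noise_cv = 0.1, seed = 99)
  d2 <- synth_observations(p, design, noise_cv = 0.1, seed = 99)
  expect_identical(d1$value, d2$value)

  d0 <- synth_observations(p, design[1:2, ], noise_cv = 0, seed = 1)
  truth <- predict_observations(p, d0)
  expect_equal(d0$value, truth, tolerance = 1e-9)

  # empirical CV of the multiplicative noise at n = 50
  ratio <- d1$value / predict_observations(p, d1)
  expect_gt(sd(ratio) / mean(ratio), 0.07)
  expect_lt(sd(ratio) / mean(ratio), 0.13)
})

test_that("profile intervals match the closed-form linear-regression oracle", {
  # y = a x + noise; the SSE-profile CI for a must agree with lm()'s
  set.seed(21)
  x <- seq(1, 10)
  a_true <- 1.7
  y <- a_true * x + rnorm(10, sd = 0.4)
  toy_params <- suppressWarnings(validate_parameters(tibble::tibble(
    name = "a", value = 1, unit = "au", source = "fitted",
    ci_lo = NA_real_, ci_hi = NA_real_)))
  toy_predict <- function(params, dataset) {
    params$value[params$name == "a"] * as.numeric(dataset$condition)
  }
  ds <- calibration_dataset("y", as.character(x), value = y,
                            weight = rep(1, 10))
  prob <- suppressWarnings(fit_problem(ds, toy_params, free = "a",
                                       lower = c(a = 0.1), upper = c(a = 10),
                                       tol = 1e-7, predict = toy_predict))
  ft <- fit_model(prob)
  ci <- confidence_intervals(prob, ft, level = 0.95, n_profile = 20)

  lmfit <- lm(y ~ x - 1)
  lm_ci <- confint(lmfit, level = 0.95)
  expect_equal(unname(coef(lmfit)[1]), unname(ft$estimate), tolerance = 1e-3)
  expect_equal(ci$ci_lo, lm_ci[1], tolerance = 0.05)
  expect_equal(ci$ci_hi, lm_ci[2], tolerance = 0.05)
  expect_false(ci$at_bound)
})

test_that("an uninformative parameter profiles out to its bounds", {
  toy_params <- suppressWarnings(validate_parameters(tibble::tibble(
    name = c("a", "b"), value = c(1, 1), unit = "au",
    source = "fitted", ci_lo = NA_real_, ci_hi = NA_real_)))
  toy_predict <- function(params, dataset) {
    params$value[params$name == "a"] * as.numeric(dataset$condition)
  }
  set.seed(5)
  x <- 1:8
  ds <- calibration_dataset("y", as.character(x), 2 * x + rnorm(8, sd = 0.1),
                            weight = rep(1, 8))
  prob <- suppressWarnings(fit_problem(ds, toy_params, free = c("a", "b"),
                                       tol = 1e-6, predict = toy_predict))
  ft <- fit_model(prob)
  ci <- confidence_intervals(prob, ft, n_profile = 6)
  row_b <- ci[ci$name == "b", ]
  expect_true(row_b$at_bound)
  expect_equal(row_b$ci_lo, prob$lower[["b"]], tolerance = 1e-6)
  expect_equal(row_b$ci_hi, prob$upper[["b"]], tolerance = 1e-6)
})

test_that("zero free parameters returns the initial objective", {
  p <- cd_parameters()
  ds <- calibration_dataset("villous_area_pct", "healthy", 100)
  prob <- fit_problem(ds, p, free = character(0))
  ft <- fit_model(prob)
  expect_identical(ft$n_iter, 0L)
  expect_equal(ft$sse, ft$sse_initial)
})

test_that("profile intervals cover the truth at the nominal rate", {
  # two-parameter toy response with multiplicative lognormal noise (CV 10%);
  # the 95% profile interval should cover the true value in the vast
  # majority of replicates
  a_true <- 2; b_true <- 0.5
  x <- seq(0.5, 4, length.out = 12)
  toy_params <- suppressWarnings(validate_parameters(tibble::tibble(
    name = c("a", "b"), value = c(1, 1), unit = "au", source = "fitted",
    ci_lo = NA_real_, ci_hi = NA_real_)))
  toy_predict <- function(params, dataset) {
    a <- params$value[params$name == "a"]
    b <- params$value[params$name == "b"]
    xx <- as.numeric(dataset$condition)
    a * xx + b * xx^2
  }
  cv <- 0.1
  sdlog <- sqrt(log(1 + cv^2))
  set.seed(1301)
  covered <- matrix(FALSE, nrow = 100, ncol = 2)
  for (r in 1:100) {
    y <- (a_true * x + b_true * x^2) *
      exp(rnorm(length(x), -sdlog^2 / 2, sdlog))
    ds <- calibration_dataset("y", as.character(x), y,
                              weight = rep(1, length(x)))
    prob <- suppressWarnings(fit_problem(
      ds, toy_params, free = c("a", "b"),
      lower = c(a = 0.05, b = 0.05), upper = c(a = 40, b = 40),
      tol = 1e-5, predict = toy_predict))
    ft <- fit_model(prob)
    ci <- confidence_intervals(prob, ft, level = 0.95, n_profile = 8)
    covered[r, 1] <- ci$ci_lo[ci$name == "a"] <= a_true &&
      a_true <= ci$ci_hi[ci$name == "a"]
    covered[r, 2] <- ci$ci_lo[ci$name == "b"] <= b_true &&
      b_true <= ci$ci_hi[ci$name == "b"]
  }
  expect_gte(sum(covered[, 1]), 85)
  expect_gte(sum(covered[, 2]), 85)
})
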