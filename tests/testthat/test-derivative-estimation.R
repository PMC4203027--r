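test_that("equilibria are located by interpolated sign changes", {
  a <- seq(0, 90, by = 5)
  eq <- find_equilibria(a, 0.2 - 0.01 * a)
  expect_identical(nrow(eq), 1L)
  expect_equal(eq$alpha_eq, 20)
  expect_lt(eq$local_slope, 0)

  expect_identical(nrow(find_equilibria(a, rep(1, length(a)) + a)), 0L)

  # humped curve with known crossings at 5 and 60 degrees, read off a 5-deg
  # grid of the analytic curve
  cv <- hermite_curve(c(0, 5, 30, 60, 90), c(-0.05, 0, 0.2, 0, -0.25),
                      c(0.5, 0.5, 0, -0.45, -0.45))
  eqs <- find_equilibria(a, curve_value(cv, a))
  expect_identical(nrow(eqs), 2L)
  expect_lt(abs(eqs$alpha_eq[1] - 5), 0.5)
  expect_lt(abs(eqs$alpha_eq[2] - 60), 0.5)
})

test_that("noise-free linear data give the exact slope with zero-width CI", {
  a <- rep(seq(5, 25, by = 5), each = 3)
  C <- 0.1 - 0.5 * a * pi / 180
  fit <- stability_slope(a, C, a0_deg = 15)
  expect_equal(fit$slope, -0.5, tolerance = 1e-12)
  expect_equal(fit$ci_high - fit$ci_low, 0, tolerance = 1e-12)
  expect_error(stability_slope(c(10, 20), c(1, 2), 15), "fewer than 3")
})

test_that("closed-form OLS slope and SE agree with stats::lm", {
  set.seed(12)
  a <- rep(seq(5, 25, by = 5), each = 5)
  C <- 0.05 - 0.4 * a * pi / 180 + stats::rnorm(length(a), 0, 0.01)
  fit <- stability_slope(a, C, 15, ci_level = 0.75)
  lmfit <- stats::lm(C ~ I(a * pi / 180))
  expect_equal(fit$slope, unname(stats::coef(lmfit)[2]), tolerance = 1e-10)
  ci <- stats::confint(lmfit, level = 0.75)[2, ]
  expect_equal(c(fit$ci_low, fit$ci_high), unname(ci), tolerance = 1e-10)
})

test_that("75% interval coverage is exact for iid Gaussian noise", {
  set.seed(2024)
  hits <- 0
  nsim <- 2000
  a <- rep(seq(5, 25, by = 5), each = 5)
  for (i in seq_len(nsim)) {
    C <- -0.5 * a * pi / 180 + stats::rnorm(length(a), 0, 0.01)
    fit <- stability_slope(a, C, 15, ci_level = 0.75)
    hits <- hits + (fit$ci_low <= -0.5 && -0.5 <= fit$ci_high)
  }
  expect_lt(abs(hits / nsim - 0.75), 0.03)
})

test_that("slope estimator is unbiased on linear truth", {
  set.seed(31)
  a <- rep(seq(5, 25, by = 5), each = 5)
  nsim <- 3000
  est <- numeric(nsim)
  for (i in seq_len(nsim)) {
    C <- -0.5 * a * pi / 180 + stats::rnorm(length(a), 0, 0.02)
    est[i] <- stability_slope(a, C, 15)$slope
  }
  se_mean <- stats::sd(est) / sqrt(nsim)
  expect_lt(abs(mean(est) + 0.5), 3 * se_mean)
})

test_that("control effectiveness reduces paired deflections correctly", {
  grid <- seq(5, 25, by = 5)
  mk <- function(C) expand.grid(angle_deg = grid, replicate = 1:5) |>
    transform(C = C)
  # constant offset 0.06 between +15 and -15 deg deflections
  est <- control_effectiveness(NULL, mk(0.13), mk(0.07), delta_deg = 15,
                               x0_deg = 15)
  expect_equal(est$slope, 0.06 / (2 * 15 * pi / 180), tolerance = 1e-12)
  expect_equal(est$slope, 0.1146, tolerance = 1e-3)

  # identical series: exactly zero
  expect_equal(control_effectiveness(NULL, mk(0.1), mk(0.1), 15, 15)$slope, 0)

  # one-sided against baseline
  one <- control_effectiveness(mk(0.02), mk(0.1), NULL, delta_deg = 30,
                               x0_deg = 15)
  expect_equal(one$slope, 0.08 / (30 * pi / 180), tolerance = 1e-12)
  expect_error(control_effectiveness(NULL, mk(0.1), NULL, 30, 15),
               "baseline")

  # antisymmetry: swapping + and - series negates the estimate exactly
  set.seed(4)
  p <- mk(stats::rnorm(25, 0.1, 0.02))
  m <- mk(stats::rnorm(25, -0.1, 0.02))
  expect_equal(control_effectiveness(NULL, p, m, 15, 15)$slope,
               -control_effectiveness(NULL, m, p, 15, 15)$slope,
               tolerance = 1e-12)
})

test_that("control truth is recovered within +/-0.02 at default noise", {
  d <- quick_design()
  g <- model_geometry("lin")
  tr <- linear_truth("lin", slope = -0.4, eq_deg = 15,
                     noise = noise_model(),
                     control = full_control_table(0.2))
  hits <- 0; nrun <- 60
  for (i in seq_len(nrun)) {
    est <- estimate_derivatives(
      reduce_records(simulate_records(tr, d, g, seed = 1000 + i), g))
    sl <- est$slope[est$kind == "control" &
                      est$movement == "tail_dorsiflexion" &
                      est$evaluation_point == "15"]
    hits <- hits + (abs(sl - 0.2) <= 0.02)
  }
  expect_gte(hits / nrun, 0.95)
})

test_that("a full design yields exactly 8 stability and 12 control rows", {
  d <- quick_design()
  g <- model_geometry("lt")
  suite <- make_fixture_suite()
  est <- estimate_derivatives(
    reduce_records(simulate_records(suite$longtail, d, g, 8), g))
  expect_identical(sum(est$kind == "stability"), 8L)
  expect_identical(sum(est$kind == "control"), 12L)
  stab <- est[est$kind == "stability", ]
  expect_setequal(paste(stab$axis, stab$evaluation_point),
                  c("pitch 0", "pitch 15", "pitch 75", "pitch eq",
                    "roll 15", "roll 75", "yaw 15", "yaw 75"))
})
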