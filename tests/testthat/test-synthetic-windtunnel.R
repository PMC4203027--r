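test_that("Hermite truth curves reproduce knot values and slopes exactly", {
  cv <- hermite_curve(c(0, 15, 40, 90), c(0.1, 0.0, -0.2, -0.1),
                      c(-0.5, -0.3, 0.2, 0.1))
  expect_equal(curve_value(cv, c(0, 15, 40, 90)), c(0.1, 0.0, -0.2, -0.1))
  expect_equal(curve_slope(cv, c(0, 15, 40, 90)), c(-0.5, -0.3, 0.2, 0.1))
  # linear extrapolation beyond the last knot
  expect_equal(curve_value(cv, 100), -0.1 + 0.1 * 10 * pi / 180)
  # collinear knots with matching slopes give an exact line between them
  lin <- hermite_curve(c(0, 90), c(0.2, 0.2 - 0.4 * pi / 2), c(-0.4, -0.4))
  a <- seq(0, 90, by = 1)
  expect_equal(curve_value(lin, a), 0.2 - 0.4 * a * pi / 180,
               tolerance = 1e-12)
  expect_equal(curve_slope(lin, a), rep(-0.4, length(a)), tolerance = 1e-12)
})

test_that("test design enumerates positions deterministically", {
  d <- quick_design()
  pts <- design_points(d)
  pb <- pts[pts$series == "pitch" & pts$movement == "none", ]
  expect_true(all(c(15, 75) %in% pb$theta_deg))

  # independent brute-force enumeration over the same grids
  window_pts <- function(grid, center, w) sum(abs(grid - center) <= w + 1e-9)
  mv <- d$movements
  expected <- length(d$pitch_grid) +                       # pitch baseline
    2 * 2 * length(d$body_grid)                            # roll+yaw baseline
  for (k in seq_len(nrow(mv))) {
    nsign <- if (mv$two_sided[k]) 2 else 1
    for (reg in d$aoa_regimes) {
      npts <- if (mv$axis[k] == "pitch") {
        window_pts(d$pitch_grid, reg, d$window)
      } else {
        window_pts(d$body_grid, 0, d$window)
      }
      expected <- expected + nsign * npts
    }
  }
  expect_identical(nrow(pts), as.integer(expected))

  # minimal design: one angle, no movements, one replicate -> 1 pitch position
  dmin <- build_test_design(pitch_grid = 15, body_grid = 0,
                            movements = default_movements()[0, ],
                            replicates = 1)
  pmin <- design_points(dmin)
  expect_identical(nrow(pmin[pmin$series == "pitch", ]), 1L)

  expect_error(build_test_design(pitch_grid = numeric()), "empty")
  expect_error(build_test_design(pitch_grid = c(-5, 10)), "0, 90")
})

test_that("identical (truth, design, seed) give byte-identical records", {
  tr <- linear_truth(noise = noise_model())
  d <- quick_design()
  g <- model_geometry("lin")
  r1 <- simulate_records(tr, d, g, seed = 42)
  r2 <- simulate_records(tr, d, g, seed = 42)
  expect_identical(r1, r2)
  r3 <- simulate_records(tr, d, g, seed = 43)
  expect_false(identical(r1$tx, r3$tx))
})

test_that("zero-noise simulation round-trips coefficients to 1e-12", {
  tr <- linear_truth(slope = -0.37, eq_deg = 12)
  d <- quick_design(replicates = 1)
  g <- model_geometry("lin", sensor_offset = c(-0.04, 0.01, 0.006))
  co <- reduce_records(simulate_records(tr, d, g, seed = 1), g)
  pb <- co[co$series == "pitch" & co$movement == "none", ]
  truth_C <- curve_value(tr$pitch_curve, pb$series_angle_deg)
  expect_equal(pb$C_m, truth_C, tolerance = 1e-12)
})

test_that("an all-zero-coefficient body yields identically zero records", {
  suite <- make_fixture_suite(noise = zero_noise())
  d <- quick_design(replicates = 1)
  g <- model_geometry("sphere")
  rec <- simulate_records(suite$sphere, d, g, seed = 5)
  expect_true(all(abs(as.matrix(rec[c("fx", "fy", "fz",
                                      "tx", "ty", "tz")])) == 0))
})

test_that("coefficients are invariant to tunnel speed (Re 30k vs 70k)", {
  tr <- linear_truth(slope = -0.45, eq_deg = 18)
  g <- model_geometry("lin")
  U_lo <- 30000 * 1.5e-5 / g$snout_vent
  U_hi <- 70000 * 1.5e-5 / g$snout_vent
  co <- lapply(c(U_lo, U_hi), function(U) {
    d <- quick_design(replicates = 1, U = U)
    co <- reduce_records(simulate_records(tr, d, g, seed = 1), g)
    co[order(co$series, co$movement, co$delta_deg, co$alpha_deg,
             co$series_angle_deg), c("C_m", "C_r", "C_y")]
  })
  expect_equal(co[[1]], co[[2]], tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("noise-free pipeline slopes equal analytic truth derivatives", {
  tr <- linear_truth(slope = -0.5, eq_deg = 20)
  d <- quick_design(replicates = 1)
  g <- model_geometry("lin")
  est <- estimate_derivatives(reduce_records(simulate_records(tr, d, g, 1), g))
  st <- est[est$kind == "stability", ]
  expect_equal(st$slope, rep(-0.5, 8), tolerance = 1e-9)
  expect_equal(st$ci_high - st$ci_low, rep(0, 8), tolerance = 1e-9)
  expect_equal(st$equilibrium_angle[st$evaluation_point == "eq"], 20,
               tolerance = 1e-9)
})

test_that("fixture suite has the designed archetype properties", {
  suite <- make_fixture_suite()
  expect_named(suite, c("sphere", "weathervane", "longtail", "shorttail"))
  # stored slope_at equals the analytic curve derivative at those points
  for (tx in suite) {
    for (p in c("0", "15", "75")) {
      expect_equal(tx$slope_at[[p]],
                   curve_slope(tx$pitch_curve, as.numeric(p)))
    }
  }
  expect_true(suite$longtail$equilibrium_angle > 10 &&
                suite$longtail$equilibrium_angle < 25)
  expect_lt(suite$longtail$slope_at$eq, 0)
  expect_lt(suite$shorttail$equilibrium_angle, 5)
  expect_gt(suite$shorttail$slope_at$eq, 0)
  # C_m at the stored equilibrium is zero
  for (tx in suite[c("weathervane", "longtail", "shorttail")]) {
    expect_equal(curve_value(tx$pitch_curve, tx$equilibrium_angle), 0,
                 tolerance = 1e-9)
  }
})

test_that("weathervane with zero noise codes stable in pitch and yaw", {
  suite <- make_fixture_suite(noise = zero_noise())
  d <- quick_design()
  g <- model_geometry("weathervane")
  est <- estimate_derivatives(
    reduce_records(simulate_records(suite$weathervane, d, g, 3), g))
  cm <- build_character_matrix(est)
  st <- cm$states[1, ]
  expect_true(all(st[c("stab_pitch_0", "stab_pitch_15", "stab_pitch_75",
                       "stab_pitch_eq", "stab_yaw_15", "stab_yaw_75")] ==
                    "stable"))
})

test_that("record CSV round-trips through the documented layout", {
  tr <- linear_truth(noise = noise_model())
  d <- quick_design(replicates = 2)
  rec <- simulate_records(tr, d, model_geometry("lin"), seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_records_csv(rec, path)
  back <- read_records_csv(path)
  expect_identical(names(back), names(rec))
  expect_equal(back$tx, rec$tx, tolerance = 1e-12)
})
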