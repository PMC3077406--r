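test_that("relative rotation rate reproduces the regime values and composes", {
  expect_equal(relative_rotation_rate(285.6, 860), 0.332, tolerance = 1e-2)
  expect_equal(relative_rotation_rate(57.7, 860), 0.0671, tolerance = 1e-2)
  # pure object rotation passes through untouched
  expect_identical(relative_rotation_rate(0, 860, 0.1), 0.1)
  expect_error(relative_rotation_rate(100, 0), "positive")
  expect_error(relative_rotation_rate(100, -5), "positive")
})

test_that("def is the product of rotation rate and slant tangent", {
  expect_equal(def_rate(tan(80 * pi / 180), 285.6 / 860), 1.883, tolerance = 1e-3)
  expect_identical(def_rate(0, 0.32), 0)
  expect_identical(def_rate(1, 0.07), 0.07)
  # bilinearity in both arguments
  for (c_ in c(-2, 0.5, 3)) {
    expect_equal(def_rate(c_ * 1.2, 0.3), c_ * def_rate(1.2, 0.3))
    expect_equal(def_rate(1.2, c_ * 0.3), c_ * def_rate(1.2, 0.3))
  }
})

test_that("local velocity is linear in elevation with slope def", {
  expect_identical(local_velocity(0, 5, 0.25), 0.25)
  expect_equal(local_velocity(0.05, tan(80 * pi / 180), 0.332),
    0.332 * (1 + 0.05 * tan(80 * pi / 180)),
    tolerance = 1e-12
  )
  # finite-difference gradient equals def_rate across the valid patch
  h <- 1e-5
  for (beta in seq(-0.06, 0.06, by = 0.02)) {
    for (st in c(0.36, 1.19, 5.67)) {
      for (om in c(0.067, 0.332)) {
        grad <- (local_velocity(beta + h, st, om) -
          local_velocity(beta - h, st, om)) / (2 * h)
        expect_equal(grad, def_rate(st, om), tolerance = 1e-6)
      }
    }
  }
  expect_error(local_velocity(0.1, 1, 0.3), "patch")
})

test_that("swept rotation matches the printed stimulus geometry", {
  expect_equal(sweep_rotation_deg(50, 860), 3.327, tolerance = 1e-3)
  expect_equal(sweep_rotation_deg(50, 760), 3.764, tolerance = 1e-3)
  expect_identical(sweep_rotation_deg(0, 860), 0)
  # monotone in shift, antitone in distance
  shifts <- seq(0, 100, by = 10)
  expect_true(all(diff(sweep_rotation_deg(shifts, 860)) > 0))
  dists <- seq(500, 1500, by = 100)
  expect_true(all(diff(sweep_rotation_deg(50, dists)) < 0))
  expect_error(sweep_rotation_deg(50, 0), "positive")
  expect_error(sweep_rotation_deg(-1, 860), ">= 0")
})

test_that("def profiles follow the trajectory and alternate sign across cycles", {
  surf <- surface_spec(80)
  cond <- viewing_condition("AVV", "normal")

  still <- tibble::tibble(t_s = seq(0, 1, by = 0.01), v_mm_s = 0)
  prof0 <- def_profile(still, surf, cond)
  expect_true(all(prof0$def_rad_s == 0))

  tr <- make_trajectory(285.6, 25, 11, 1000)
  prof <- def_profile(tr, surf, cond)
  expect_equal(nrow(prof), nrow(tr))
  # per-cycle peak equals the closed-form peak def
  expect_equal(max_def(prof), 1.883, tolerance = 1e-3)
  # consecutive cycles have opposite def sign
  cyc <- prof[!is.na(prof$cycle_id), ]
  signs <- tapply(sign(cyc$def_rad_s), cyc$cycle_id, function(s) unique(s[s != 0]))
  expect_true(all(lengths(signs) == 1))
  expect_true(all(diff(unlist(signs)) != 0))

  expect_error(def_profile(tibble::tibble(), surf, cond), "non-empty")
})

test_that("max def averages per-cycle peaks and requires a complete cycle", {
  const <- tibble::tibble(def_rad_s = rep(2.5, 10), cycle_id = rep(1L, 10))
  expect_equal(max_def(const), 2.5)
  two <- tibble::tibble(
    def_rad_s = c(0.5, 1.0, 0.5, -1, -3.0, -2),
    cycle_id = c(1L, 1L, 1L, 2L, 2L, 2L)
  )
  expect_equal(max_def(two), 2.0)
  no_cycle <- tibble::tibble(def_rad_s = 1:3, cycle_id = NA_integer_)
  expect_error(max_def(no_cycle), "complete")
})

test_that("sinusoidal max def matches the analytic peak", {
  surf <- surface_spec(80)
  cond <- viewing_condition("AVV", "normal")
  tr <- make_trajectory(285.6, 25, 11, 2000)
  analytic <- def_rate(surf$slant_tan, 285.6 / 860)
  expect_equal(max_def(def_profile(tr, surf, cond)), analytic, tolerance = 1e-5)
  expect_equal(max_def_closed_form(surf, cond), analytic, tolerance = 1e-12)
})
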