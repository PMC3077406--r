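test_that("trial tables follow the block designs", {
  avv <- generate_trials("AVV", n_subjects = 1, seed = 1)
  expect_equal(nrow(avv), 25) # 5 repetitions x 5 slants
  expect_setequal(unique(avv$slant_sim_deg), c(20, 35, 50, 65, 80))

  avp <- generate_trials("AVP", n_subjects = 1, seed = 1)
  expect_equal(nrow(avp), 16) # 4 repetitions x 4 slants
  expect_setequal(unique(avp$slant_sim_deg), c(10, 20, 40, 50))

  two <- generate_trials("AVV", n_subjects = 2, seed = 1)
  expect_setequal(
    unique(two[, c("subject_id", "regime")])$regime, c("normal", "slow")
  )
  expect_error(generate_trials("AVV", n_subjects = 2, regimes = "normal"), "per subject")
})

test_that("trial def values come from the flow pipeline", {
  avv <- generate_trials("AVV", n_subjects = 1, regimes = "normal", seed = 1)
  d80 <- unique(avv$def_max[avv$slant_sim_deg == 80])
  expect_equal(d80, 1.883, tolerance = 1e-3)
  # slow regime scales def by the velocity ratio
  slow <- generate_trials("AVV", n_subjects = 1, regimes = "slow", seed = 1)
  expect_equal(
    unique(slow$def_max[slow$slant_sim_deg == 80]),
    max_def_closed_form(surface_spec(80), viewing_condition("AVV", "slow")),
    tolerance = 1e-3
  )
})

test_that("the passive block replays the active block's def values", {
  avv <- generate_trials("AVV", n_subjects = 3, seed = 1)
  pvv <- generate_trials("PVV", n_subjects = 3, seed = 2, replay_from = avv)
  expect_identical(pvv$def_max, avv$def_max)
  expect_true(all(pvv$condition == "PVV"))
})

test_that("responses follow k * sqrt(def) with a floor at zero", {
  t1 <- simulate_responses(toy_trials(1, "PVV"), noise_sd_tan = 0, seed = 1)
  expect_equal(t1$response_tan, 1.04)
  t2 <- simulate_responses(toy_trials(1, "AVP"), noise_sd_tan = 0, seed = 1)
  expect_equal(t2$response_tan, 2.41)
  t3 <- simulate_responses(toy_trials(0, "AVV"),
    k_by_condition = c(AVV = 1), noise_sd_tan = 0, seed = 1
  )
  expect_equal(t3$response_tan, 0)
  expect_error(
    simulate_responses(toy_trials(1, "XXX"), seed = 1),
    "No k for condition"
  )
  noisy <- simulate_responses(toy_trials(rep(0.01, 200), "PVV"), seed = 1)
  expect_true(all(noisy$response_tan >= 0))
})

test_that("simulated variability matches the behavioral noise scale", {
  trials <- generate_experiment(n_subjects = 34, seed = 42)
  mu <- unname(c(PVV = 1.04, AVV = 1.88, AVP = 2.41)[trials$condition]) *
    sqrt(trials$def_max)
  # residual SD recovers the generating value (floor truncation shrinks it a bit)
  expect_equal(sd(trials$response_tan - mu), 0.218, tolerance = 0.1)
  # coefficient of variation has the observed order of magnitude
  cv <- sd(trials$response_tan - mu) / mean(trials$response_tan)
  expect_gt(cv, 0.2)
  expect_lt(cv, 0.6)
})

test_that("dot displays are deterministic and geometrically consistent", {
  s <- surface_spec(50)
  f1 <- project_dots(s, c(0, 0, 0), n_dots = 50, seed = 9)
  f2 <- project_dots(s, c(0, 0, 0), n_dots = 50, seed = 9)
  expect_identical(as.data.frame(f1), as.data.frame(f2))
  expect_equal(nrow(f1), 50)
  # frontoparallel surface viewed from the reference eye: image = surface plane
  flat <- project_dots(surface_spec(0), c(0, 0, 0), n_dots = 500, seed = 1)
  expect_equal(flat$x_img_mm, flat$x_mm, tolerance = 1e-9)
  expect_lt(abs(mean(flat$y_img_mm)), 5)
  expect_error(project_dots(s, c(0, 0, 900)), "front of the eye")
})

test_that("differencing dot frames recovers def within the linear patch", {
  s <- surface_spec(50)
  d <- 860
  v <- 285.6
  dt <- 0.005
  f1 <- project_dots(s, c(-v * dt / 2, 0, 0), n_dots = 200, distance_mm = d, seed = 3)
  f2 <- project_dots(s, c(v * dt / 2, 0, 0), n_dots = 200, distance_mm = d, seed = 3)
  a1 <- retinal_angles(f1)
  a2 <- retinal_angles(f2)
  rate <- (a2$alpha_rad - a1$alpha_rad) / dt
  beta <- (a1$beta_rad + a2$beta_rad) / 2
  slope <- unname(coef(lm(rate ~ beta))[2])
  expect_equal(slope, def_rate(s$slant_tan, v / d), tolerance = 0.05)
})
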