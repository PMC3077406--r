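fit_data <- function(x, y) {
  tibble::tibble(response_tan = y, def_max = x^2) # sqrt(def_max) == x
}

test_that("no-intercept slope is the least-squares line through the origin", {
  x <- seq(0.2, 2, by = 0.2)
  fit <- no_intercept_slope(fit_data(x, 2 * x))
  expect_equal(tidy(fit)$estimate, 2, tolerance = 1e-12)
  expect_equal(fit$agreement_r2, 1, tolerance = 1e-12)
  # response orthogonal to the predictor
  fit0 <- no_intercept_slope(fit_data(c(1, 1), c(1, -1)))
  expect_equal(tidy(fit0)$estimate, 0, tolerance = 1e-12)
  expect_error(no_intercept_slope(fit_data(c(0, 0), c(1, 2))), "zero")
  expect_error(no_intercept_slope(fit_data(1, 1)), "two rows")
})

test_that("slope recovery at the experiment's design size", {
  trials <- simulate_responses(
    generate_trials("PVV", n_subjects = 17, seed = 3),
    seed = 3
  )
  fit <- no_intercept_slope(trials)
  expect_equal(tidy(fit)$estimate, 1.04, tolerance = 0.05)
  # row permutation leaves the slope unchanged
  shuffled <- trials[sample(nrow(trials)), ]
  expect_equal(
    tidy(no_intercept_slope(shuffled))$estimate,
    tidy(fit)$estimate,
    tolerance = 1e-12
  )
})

test_that("agreement statistic behaves like a concordance measure", {
  y <- c(1, 2, 3, 4, 5)
  expect_equal(agreement_statistic(y, y), 1)
  # predicting the observed mean everywhere scores zero
  expect_equal(agreement_statistic(y, rep(mean(y), 5)), 0)
  # invariant under a common shift of both vectors
  p <- c(1.2, 1.9, 3.3, 3.8, 5.1)
  expect_equal(
    agreement_statistic(y, p),
    agreement_statistic(y + 10, p + 10),
    tolerance = 1e-12
  )
  expect_lt(agreement_statistic(y, rev(y)), 0)
  expect_error(agreement_statistic(rep(1, 3), rep(1, 3)), "identical")
  expect_error(agreement_statistic(1:3, 1:4), "Lengths")
})

test_that("velocity effect test is null on retinal-model data", {
  trials <- generate_experiment(n_subjects = 34, seed = 1)
  fit <- velocity_effect_test(trials, n_permutations = 500, seed = 1)
  b <- tidy(fit)$estimate[tidy(fit)$term == "regime_normal"]
  expect_lt(abs(b), 0.06)
  expect_gt(fit$p_value, 0.05)
})

test_that("velocity effect test recovers a planted regime offset", {
  trials <- generate_experiment(n_subjects = 34, seed = 2)
  trials$response_tan <- trials$response_tan +
    0.3 * (trials$regime == "normal")
  fit <- velocity_effect_test(trials, n_permutations = 500, seed = 1)
  b <- tidy(fit)$estimate[tidy(fit)$term == "regime_normal"]
  # def ranges never overlap across regimes, so the sqrt(def) slopes absorb
  # part of the planted offset; the contrast stays positive and detectable
  expect_gt(b, 0.1)
  expect_lt(b, 0.4)
  expect_lt(fit$p_value, 0.05)
})

test_that("duplicated regimes give a regime coefficient of exactly zero", {
  base <- simulate_responses(
    generate_trials("AVV", n_subjects = 2, regimes = c("normal", "normal"), seed = 1),
    seed = 1
  )
  flipped <- dplyr::mutate(base, regime = "slow", subject_id = subject_id + 10L)
  both <- dplyr::bind_rows(base, flipped)
  fit <- velocity_effect_test(both, n_permutations = 19, seed = 1)
  b <- tidy(fit)$estimate[tidy(fit)$term == "regime_normal"]
  expect_equal(b, 0, tolerance = 1e-10)
})

test_that("velocity effect permutation test holds its size", {
  # null data at reduced size, many replicates
  n_sig <- 0
  n_rep <- 300
  for (i in seq_len(n_rep)) {
    trials <- simulate_responses(
      generate_trials("AVV", n_subjects = 10, seed = i),
      seed = 1000 + i
    )
    fit <- velocity_effect_test(trials, n_permutations = 99, seed = i)
    if (fit$p_value <= 0.05) n_sig <- n_sig + 1
  }
  expect_lte(n_sig / n_rep, 0.08)
})

test_that("observed vs predicted recovers the identity on self-consistent data", {
  trials <- generate_experiment(n_subjects = 34, seed = 5)
  fit <- observed_vs_predicted(trials)
  co <- tidy(fit)
  expect_equal(co$estimate[co$term == "slope"], 1, tolerance = 0.1)
  expect_lt(abs(co$estimate[co$term == "intercept"]), 0.1)
  expect_gt(fit$agreement_r2, 0.5)

  # noiseless data: perfect agreement
  clean <- simulate_responses(
    generate_trials("AVV", n_subjects = 4, seed = 1),
    noise_sd_tan = 0, seed = 1
  )
  expect_equal(observed_vs_predicted(clean)$agreement_r2, 1, tolerance = 1e-12)

  # doubling the prediction map halves the slope exactly
  k2 <- c(PVV = 2 * 1.04, AVV = 2 * 1.88, AVP = 2 * 2.41)
  fit2 <- observed_vs_predicted(trials, k_by_condition = k2)
  expect_equal(
    tidy(fit2)$estimate[2], co$estimate[co$term == "slope"] / 2,
    tolerance = 1e-12
  )
  expect_error(
    observed_vs_predicted(trials, k_by_condition = c(PVV = 1)),
    "No k for condition"
  )
})

test_that("tidy and glance expose the fit components", {
  trials <- simulate_responses(generate_trials("PVV", n_subjects = 2, seed = 1), seed = 1)
  fit <- no_intercept_slope(trials)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_named(glance(fit), c("type", "agreement_r2", "p_value", "n"))
  expect_equal(glance(fit)$n, nrow(trials))
})
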