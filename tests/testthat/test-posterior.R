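grid_mass <- function(post) {
  ws <- slantflow:::trapezoid_weights(post$sigma_axis)
  wo <- slantflow:::trapezoid_weights(post$omega_axis)
  as.numeric(crossprod(ws, post$density %*% wo))
}

test_that("joint and marginal posteriors are normalized", {
  cfg <- estimator_config(
    rotation_prior = rotation_prior("stationarity", omega_e = 0.332, sigma = 0.05)
  )
  post <- joint_posterior(1.88, cfg)
  expect_equal(grid_mass(post), 1, tolerance = 1e-6)
  marg <- marginal_slant_posterior(post)
  w <- slantflow:::trapezoid_weights(marg$sigma_tan)
  expect_equal(sum(w * marg$density), 1, tolerance = 1e-6)
  expect_true(all(post$density >= 0))
})

test_that("zero def concentrates mass near the axes product zero", {
  cfg <- estimator_config(
    rotation_prior = rotation_prior("noninformative", sigma = 0.5),
    likelihood = def_likelihood(sigma = 0.01)
  )
  post <- joint_posterior(0, cfg)
  df <- tibble::as_tibble(post)
  # expected sigma * omega under the posterior is tiny
  ws <- slantflow:::trapezoid_weights(post$sigma_axis)
  wo <- slantflow:::trapezoid_weights(post$omega_axis)
  prod_mean <- as.numeric(
    crossprod(ws * post$sigma_axis, post$density %*% (wo * post$omega_axis))
  )
  expect_lt(prod_mean, 0.05)
})

test_that("the retinal posterior ridge follows the def hyperbola", {
  cfg <- retinal_config_k(1, likelihood = def_likelihood(sigma = 0.01))
  post <- joint_posterior(1, cfg)
  idx <- which(post$density >= 0.5 * max(post$density), arr.ind = TRUE)
  prods <- post$sigma_axis[idx[, 1]] * post$omega_axis[idx[, 2]]
  expect_true(all(abs(prods - 1) < 0.1))
})

test_that("tight rotation prior collapses onto the 1-D slant posterior", {
  om <- 0.332
  def <- 1.2
  cfg <- io_config_tight(om, sigma_omega = 1e-4, sigma_def = 0.05)
  med_grid <- posterior_median(marginal_slant_posterior(joint_posterior(def, cfg)))
  # oracle: 1-D posterior over sigma at omega fixed to omega_e
  sg <- seq(0, 10, length.out = 20001)
  dens <- slant_prior_density(sg, cfg$slant_prior) * dnorm(def, sg * om, 0.05)
  cdf <- cumsum(c(0, diff(sg) * (head(dens, -1) + tail(dens, -1)) / 2))
  cdf <- cdf / cdf[length(cdf)]
  med_oracle <- approx(cdf, sg, 0.5, ties = "ordered")$y
  expect_equal(med_grid, med_oracle, tolerance = 0.01)
})

test_that("posterior median reads the interpolated CDF midpoint", {
  marg <- gaussian_marginal(2, 0.3)
  expect_equal(posterior_median(marg), 2, tolerance = 1e-3)
  degenerate <- tibble::tibble(sigma_tan = 0:10, density = 0)
  expect_error(posterior_median(degenerate), "Degenerate")
  unnorm <- tibble::tibble(sigma_tan = seq(0, 1, 0.01), density = 5)
  expect_error(posterior_median(unnorm), "normalized")
})

test_that("median is stable under grid refinement", {
  for (n in c(256, 512)) {
    cfg <- retinal_config_k(1, n_sigma = n, n_omega = n)
    med <- estimate_slant(0.8, cfg)
    if (n == 256) ref <- med
  }
  expect_equal(med, ref, tolerance = 0.01)
})

test_that("closed-form retinal prediction is k * sqrt(def)", {
  expect_identical(closed_form_retinal_estimate(1, 1), 1)
  expect_equal(closed_form_retinal_estimate(1.883, 1.88), 1.88 * sqrt(1.883))
  expect_identical(closed_form_retinal_estimate(0, 2), 0)
  expect_error(closed_form_retinal_estimate(-0.1, 1), "non-negative")
  expect_error(closed_form_retinal_estimate(1, 0), "positive")
})

test_that("retinal grid median follows the closed form across spreads", {
  for (k in c(0.5, 2)) {
    cfg <- retinal_config_k(k)
    for (d in c(0.1, 1)) {
      expect_equal(estimate_slant(d, cfg), k * sqrt(d), tolerance = 0.03)
    }
  }
})

test_that("a broad rotation prior makes the two models agree", {
  io <- estimator_config(
    rotation_prior = rotation_prior("stationarity", omega_e = 0.332, sigma = 20)
  )
  ret <- estimator_config(
    rotation_prior = rotation_prior("noninformative", sigma = 20)
  )
  for (d in c(0.3, 1, 3)) {
    expect_equal(estimate_slant(d, io), estimate_slant(d, ret), tolerance = 0.01)
  }
})

test_that("slant estimates shrink as head-motion uncertainty grows", {
  def <- 1.883
  meds <- vapply(c(0.001, 0.02, 0.05, 0.1, 0.2), function(s) {
    cfg <- estimator_config(
      rotation_prior = rotation_prior("stationarity", omega_e = 0.332, sigma = s),
      likelihood = def_likelihood(sigma = 0.01)
    )
    estimate_slant(def, cfg)
  }, numeric(1))
  expect_true(all(diff(meds) <= 1e-9))
})

test_that("estimate_slant vectorizes over observations", {
  cfg <- retinal_config_k(1)
  out <- estimate_slant(c(0.25, 1), cfg)
  expect_length(out, 2)
  expect_true(all(diff(out) > 0))
})
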