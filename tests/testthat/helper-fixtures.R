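# Shared fixtures for the slantflow test suite.

# Rotation rates implied by the two head-velocity regimes at 860 mm.
omega_fast <- 285.6 / 860
omega_slow <- 57.7 / 860

# A tight inverse-optics config: near-noiseless measurements of both the
# head motion and def.
io_config_tight <- function(omega_e, sigma_omega = 1e-3, sigma_def = 1e-3) {
  estimator_config(
    rotation_prior = rotation_prior("stationarity",
      omega_e = omega_e, sigma = sigma_omega
    ),
    likelihood = def_likelihood(sigma = sigma_def)
  )
}

# A retinal config with prior spreads chosen to give slope k (sigma_Sigma =
# k * s, sigma_Omega = s / k for unit product scale s).
retinal_config_k <- function(k, scale = 1, ...) {
  estimator_config(
    slant_prior = slant_prior(k * scale),
    rotation_prior = rotation_prior("noninformative", sigma = scale / k),
    ...
  )
}

# A hand-built normalized marginal on a grid (Gaussian truncated to x >= 0).
gaussian_marginal <- function(mean, sd, n = 2001, hi = mean + 8 * sd) {
  x <- seq(max(0, mean - 8 * sd), hi, length.out = n)
  y <- dnorm(x, mean, sd)
  w <- c(diff(x)[1] / 2, (diff(x)[-1] + diff(x)[-(n - 1)]) / 2, diff(x)[n - 1] / 2)
  tibble::tibble(sigma_tan = x, density = y / sum(w * y))
}

# Minimal trial table with known def and condition.
toy_trials <- function(def, condition = "PVV", subject_id = 1L, regime = "normal") {
  tibble::tibble(
    subject_id = subject_id,
    condition = condition,
    regime = regime,
    slant_sim_deg = NA_real_,
    slant_sim_tan = NA_real_,
    def_max = def,
    seed = 0L
  )
}
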