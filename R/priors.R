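#' Half-Gaussian flatness prior on slant tangent
#'
#' The prior belief that surfaces tend to be close to frontoparallel: a
#' half-Gaussian on the slant tangent, centered at zero with spread
#' `sigma`. Density is `2 * dnorm(x, 0, sigma)` for `x >= 0` and 0 otherwise.
#'
#' @param sigma Spread of the half-Gaussian (> 0), on the slant-tangent scale.
#' @return A `slantflow_slant_prior` object.
#' @examples
#' slant_prior(1)
#' @export
slant_prior <- function(sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    abort("`sigma` must be a single positive number.")
  }
  structure(list(sigma = sigma), class = "slantflow_slant_prior")
}

#' Density of the slant prior
#'
#' @param sigma_tan Slant-tangent values (vector ok).
#' @param prior A [slant_prior()].
#' @return Density values; integrates to 1 over `[0, Inf)`.
#' @export
slant_prior_density <- function(sigma_tan, prior) {
  ifelse(sigma_tan < 0, 0, 2 * dnorm(sigma_tan, 0, prior$sigma))
}

#' Prior over the relative rotation rate
#'
#' Three kinds of prior over the (non-negative) relative rotation magnitude:
#'
#' * `"stationarity"`: the inverse-optics observer believes the surface is
#'   stationary, so the relative rotation is centered on the egocentric
#'   rotation implied by the measured head translation, `omega_e`, with spread
#'   `sigma` reflecting the precision of the extra-retinal measurement. The
#'   Gaussian is truncated to `omega >= 0` and renormalized.
#' * `"noninformative"`: the retinal-only observer has no head-motion
#'   information; the prior is a zero-centered half-Gaussian with spread
#'   `sigma`, a generic preference for slow relative rotations. This is the
#'   prior under which the posterior median follows `k * sqrt(def)` with
#'   `k = sqrt(sigma_Sigma / sigma_Omega)`.
#' * `"uniform"`: a bounded flat prior on `bounds` (sensitivity variant).
#'
#' @param kind One of `"stationarity"`, `"noninformative"`, `"uniform"`.
#' @param omega_e Mean egocentric rotation rate in rad/s (stationarity only).
#' @param sigma Spread in rad/s (stationarity and noninformative).
#' @param bounds Length-2 numeric, lower bound >= 0 (uniform only); default
#'   `c(0, 2)`.
#' @return A `slantflow_rotation_prior` object.
#' @examples
#' rotation_prior("stationarity", omega_e = 0.332, sigma = 0.05)
#' rotation_prior("noninformative", sigma = 1)
#' @export
rotation_prior <- function(kind = c("stationarity", "noninformative", "uniform"),
                           omega_e = NULL, sigma = NULL, bounds = c(0, 2)) {
  kind <- match.arg(kind)
  if (kind == "stationarity") {
    if (is.null(omega_e) || is.null(sigma) || sigma <= 0 || omega_e < 0) {
      abort("stationarity prior needs `omega_e` >= 0 and `sigma` > 0.")
    }
  } else if (kind == "noninformative") {
    if (is.null(sigma) || sigma <= 0) {
      abort("noninformative prior needs `sigma` > 0.")
    }
    omega_e <- 0
  } else {
    if (length(bounds) != 2L || bounds[1] < 0 || bounds[2] <= bounds[1]) {
      abort("uniform prior needs `bounds = c(lo, hi)` with 0 <= lo < hi.")
    }
  }
  structure(
    list(kind = kind, omega_e = omega_e, sigma = sigma, bounds = bounds),
    class = "slantflow_rotation_prior"
  )
}

#' Density of the rotation prior
#'
#' @param omega Rotation rates in rad/s (vector ok).
#' @param prior A [rotation_prior()].
#' @return Density values; integrates to 1 on the prior's support.
#' @export
rotation_prior_density <- function(omega, prior) {
  switch(prior$kind,
    stationarity = {
      z <- pnorm(0, prior$omega_e, prior$sigma) # mass truncated below 0
      ifelse(omega < 0, 0, dnorm(omega, prior$omega_e, prior$sigma) / (1 - z))
    },
    noninformative = ifelse(omega < 0, 0, 2 * dnorm(omega, 0, prior$sigma)),
    uniform = ifelse(
      omega >= prior$bounds[1] & omega <= prior$bounds[2],
      1 / diff(prior$bounds), 0
    )
  )
}

#' Gaussian measurement model for def
#'
#' The observed def is the true `slant_tan * omega` corrupted by zero-mean
#' Gaussian noise. The noise spread can be given in absolute terms
#' (`sigma`) or as a coefficient of variation (`cv`), in which case
#' `sigma_def = max(cv * def_obs, sigma_min)` is resolved per observation.
#'
#' @param sigma Absolute noise SD in rad/s (> 0); mutually exclusive with `cv`.
#' @param cv Coefficient of variation (> 0); default 0.05 if `sigma` missing.
#' @param sigma_min Floor on the resolved SD in cv mode (default 1e-4 rad/s),
#'   keeping the likelihood proper at def = 0.
#' @return A `slantflow_def_likelihood` object.
#' @examples
#' def_likelihood(sigma = 0.01)
#' def_likelihood(cv = 0.05)
#' @export
def_likelihood <- function(sigma = NULL, cv = NULL, sigma_min = 1e-4) {
  if (!is.null(sigma) && !is.null(cv)) {
    abort("Give either `sigma` (absolute) or `cv` (relative), not both.")
  }
  if (is.null(sigma) && is.null(cv)) cv <- 0.05
  if (!is.null(sigma) && sigma <= 0) abort("`sigma` must be positive.")
  if (!is.null(cv) && cv <= 0) abort("`cv` must be positive.")
  structure(
    list(
      mode = if (is.null(sigma)) "cv" else "absolute",
      sigma = sigma, cv = cv, sigma_min = sigma_min
    ),
    class = "slantflow_def_likelihood"
  )
}

# Resolve the noise SD for a given observation.
resolve_sigma_def <- function(lik, def_obs) {
  if (lik$mode == "absolute") lik$sigma else max(lik$cv * def_obs, lik$sigma_min)
}

#' Likelihood of an observed def
#'
#' Gaussian density of `def_obs` around the model mean `sigma_tan * omega`.
#'
#' @param def_obs Observed def in rad/s.
#' @param sigma_tan Slant tangent (vector ok).
#' @param omega Rotation rate in rad/s (vector ok, recycled).
#' @param lik A [def_likelihood()].
#' @return Density values.
#' @export
def_likelihood_density <- function(def_obs, sigma_tan, omega, lik) {
  dnorm(def_obs, mean = sigma_tan * omega, sd = resolve_sigma_def(lik, def_obs))
}

#' Estimator configuration
#'
#' Bundles the priors, the measurement model and the numerical grid for one
#' Bayesian slant estimator. The model identity follows from the rotation
#' prior: a `"stationarity"` prior gives the inverse-optics estimator (which
#' conditions on measured head motion); any other kind gives the retinal-only
#' estimator.
#'
#' The default grid covers slant tangent `[0, 10]` (tan 80 deg = 5.67 lies
#' well inside) with 512 nodes, and rotation `[0, omega_max]` with 512 nodes,
#' where `omega_max` defaults to `max(1, omega_e + 5 * sigma)` for the
#' stationarity prior, `max(1, 5 * sigma)` for the noninformative prior and the
#' upper bound for the uniform prior. When the posterior is much narrower than
#' the base grid (tight priors or a tight likelihood), [joint_posterior()]
#' refines the axes adaptively; see `refine`.
#'
#' @param slant_prior A [slant_prior()]; default spread 3, which is weak over
#'   the stimulus range (tan 80 deg is ~1.9 spreads out) while keeping 99% of
#'   the prior mass inside the default slant-tangent grid.
#' @param rotation_prior A [rotation_prior()].
#' @param likelihood A [def_likelihood()]; default cv = 0.05.
#' @param n_sigma,n_omega Base grid sizes (default 512).
#' @param sigma_max Upper edge of the slant-tangent axis (default 10).
#' @param omega_max Upper edge of the rotation axis; `NULL` for the default
#'   above.
#' @param refine Adaptively refine the grid where the posterior mass lies
#'   (default `TRUE`).
#' @return A `slantflow_config` object with a `model` field
#'   (`"inverse_optics"` or `"retinal"`).
#' @examples
#' estimator_config(rotation_prior = rotation_prior("stationarity", 0.332, 0.05))
#' estimator_config(rotation_prior = rotation_prior("noninformative", sigma = 1))
#' @export
estimator_config <- function(slant_prior = slantflow::slant_prior(3),
                             rotation_prior,
                             likelihood = def_likelihood(cv = 0.05),
                             n_sigma = 512, n_omega = 512,
                             sigma_max = 10, omega_max = NULL,
                             refine = TRUE) {
  stopifnot(inherits(slant_prior, "slantflow_slant_prior"))
  stopifnot(inherits(rotation_prior, "slantflow_rotation_prior"))
  stopifnot(inherits(likelihood, "slantflow_def_likelihood"))
  if (n_sigma < 16 || n_omega < 16) abort("grid sizes must be >= 16.")
  omega_max <- omega_max %||% switch(rotation_prior$kind,
    stationarity = max(1, rotation_prior$omega_e + 5 * rotation_prior$sigma),
    noninformative = max(1, 5 * rotation_prior$sigma),
    uniform = rotation_prior$bounds[2]
  )
  if (sigma_max <= 0 || omega_max <= 0) abort("grid bounds must be positive.")
  structure(
    list(
      slant_prior = slant_prior,
      rotation_prior = rotation_prior,
      likelihood = likelihood,
      n_sigma = n_sigma, n_omega = n_omega,
      sigma_max = sigma_max, omega_max = omega_max,
      refine = refine,
      model = if (rotation_prior$kind == "stationarity") "inverse_optics" else "retinal"
    ),
    class = "slantflow_config"
  )
}

#' @export
print.slantflow_config <- function(x, ...) {
  cat(sprintf(
    "<slantflow_config> %s model; slant prior sd %.3g; rotation prior %s; grid %dx%d on [0,%g]x[0,%g]\n",
    x$model, x$slant_prior$sigma, x$rotation_prior$kind,
    x$n_sigma, x$n_omega, x$sigma_max, x$omega_max
  ))
  invisible(x)
}

#' Slope of the retinal model's predicted slant-vs-sqrt(def) line
#'
#' For the retinal-only estimator the posterior median is `k * sqrt(def)` with
#' `k = sqrt(sigma_Sigma / sigma_Omega)`, the square root of the ratio of the
#' two prior spreads.
#'
#' @param config A retinal-model [estimator_config()].
#' @return The slope `k`.
#' @export
retinal_k <- function(config) {
  if (config$model != "retinal" || config$rotation_prior$kind != "noninformative") {
    abort("`retinal_k` is defined for configs with a noninformative rotation prior.")
  }
  sqrt(config$slant_prior$sigma / config$rotation_prior$sigma)
}
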