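# Trapezoidal quadrature weights for a sorted axis.
trapezoid_weights <- function(x) {
  n <- length(x)
  d <- diff(x)
  c(d[1] / 2, (d[-1] + d[-(n - 1)]) / 2, d[n - 1] / 2)
}

trapezoid_integral <- function(x, y) sum(trapezoid_weights(x) * y)

# Locate the index window holding essentially all of a nonnegative mass vector,
# padded by `pad` cells.
mass_window <- function(mass, pad = 3L, tail_frac = 1e-9) {
  total <- sum(mass)
  cdf <- cumsum(mass) / total
  lo <- max(1L, which(cdf > tail_frac)[1] - pad)
  hi <- min(length(mass), which(cdf >= 1 - tail_frac)[1] + pad)
  c(lo, hi)
}

# Refined axis: base nodes plus a dense linspace inside the mass window.
refine_axis <- function(axis, mass, n_extra, pad = 3L) {
  win <- mass_window(mass, pad = pad)
  if (win[2] - win[1] >= length(axis) * 0.5) {
    return(axis) # mass already spans most of the axis; nothing to gain
  }
  sort(unique(c(axis, seq(axis[win[1]], axis[win[2]], length.out = n_extra))))
}

# Unnormalized joint density on the (sigma, omega) grid.
eval_joint <- function(sigma_axis, omega_axis, def_obs, config) {
  ps <- slant_prior_density(sigma_axis, config$slant_prior)
  po <- rotation_prior_density(omega_axis, config$rotation_prior)
  sd_def <- resolve_sigma_def(config$likelihood, def_obs)
  lik <- dnorm(def_obs, mean = outer(sigma_axis, omega_axis), sd = sd_def)
  lik * outer(ps, po)
}

# Extra nodes guaranteeing that a tight stationarity posterior is seen by the
# coarse pass: cluster omega around omega_e and sigma around def/omega_e.
anchor_nodes <- function(def_obs, config) {
  rp <- config$rotation_prior
  if (rp$kind != "stationarity") {
    return(list(sigma = numeric(0), omega = numeric(0)))
  }
  sd_def <- resolve_sigma_def(config$likelihood, def_obs)
  omega_lo <- max(0, rp$omega_e - 6 * rp$sigma)
  omega_hi <- min(config$omega_max, rp$omega_e + 6 * rp$sigma)
  omega_nodes <- seq(omega_lo, omega_hi, length.out = 33)
  omega_ref <- max(rp$omega_e, rp$sigma, 1e-12)
  mu <- def_obs / omega_ref
  half <- 8 * (sd_def / omega_ref + mu * (6 * rp$sigma / omega_ref + 1e-3))
  sigma_nodes <- seq(
    max(0, mu - half), min(config$sigma_max, mu + half),
    length.out = 33
  )
  list(sigma = sigma_nodes, omega = omega_nodes)
}

#' Joint posterior over slant tangent and rotation rate
#'
#' Evaluates, on a numerical grid, the joint posterior density of the slant
#' tangent and the relative rotation rate given one observed def:
#' `p(sigma, omega | def) ∝ p(sigma) p(omega) N(def; sigma * omega, sd)`.
#' Normalization uses trapezoidal quadrature over both axes. When the
#' posterior occupies a small fraction of the base grid (tight priors or a
#' tight likelihood), the axes are refined once with a dense cluster of nodes
#' inside the region that carries the mass, so that median readouts stay
#' accurate without an enormous uniform grid.
#'
#' @param def_obs Observed def in rad/s (>= 0).
#' @param config An [estimator_config()].
#' @return A `slantflow_posterior` object: list with `sigma_axis`,
#'   `omega_axis`, `density` (matrix, rows = sigma), `normalized`, `model`,
#'   `def_obs`, `config`.
#' @examples
#' cfg <- estimator_config(
#'   rotation_prior = rotation_prior("stationarity", omega_e = 0.332, sigma = 0.05)
#' )
#' post <- joint_posterior(1.88, cfg)
#' posterior_median(marginal_slant_posterior(post))
#' @export
joint_posterior <- function(def_obs, config) {
  stopifnot(inherits(config, "slantflow_config"))
  if (!is.numeric(def_obs) || length(def_obs) != 1L || is.na(def_obs) || def_obs < 0) {
    abort("`def_obs` must be a single non-negative number.")
  }
  check_prior_coverage(config)

  anchors <- anchor_nodes(def_obs, config)
  sigma_axis <- sort(unique(c(
    seq(0, config$sigma_max, length.out = config$n_sigma), anchors$sigma
  )))
  omega_axis <- sort(unique(c(
    seq(0, config$omega_max, length.out = config$n_omega), anchors$omega
  )))

  m <- eval_joint(sigma_axis, omega_axis, def_obs, config)
  if (config$refine) {
    ws <- trapezoid_weights(sigma_axis)
    wo <- trapezoid_weights(omega_axis)
    row_mass <- ws * as.vector(m %*% wo)
    col_mass <- wo * as.vector(crossprod(m, ws))
    if (sum(row_mass) > 0) {
      sigma_axis <- refine_axis(sigma_axis, row_mass, config$n_sigma)
      omega_axis <- refine_axis(omega_axis, col_mass, config$n_omega)
      m <- eval_joint(sigma_axis, omega_axis, def_obs, config)
    }
  }

  total <- as.numeric(
    crossprod(trapezoid_weights(sigma_axis), m %*% trapezoid_weights(omega_axis))
  )
  if (!is.finite(total) || total <= 0) {
    abort(paste(
      "Posterior mass is zero on the grid; the likelihood is too tight for the",
      "grid resolution. Increase `n_sigma`/`n_omega` or widen the likelihood."
    ))
  }
  structure(
    list(
      sigma_axis = sigma_axis, omega_axis = omega_axis,
      density = m / total, normalized = TRUE,
      model = config$model, def_obs = def_obs, config = config
    ),
    class = "slantflow_posterior"
  )
}

# Validate that the grid holds at least 99% of each prior's mass.
check_prior_coverage <- function(config) {
  sp <- config$slant_prior
  cover_sigma <- 2 * (pnorm(config$sigma_max, 0, sp$sigma) - 0.5)
  rp <- config$rotation_prior
  cover_omega <- switch(rp$kind,
    stationarity = {
      below <- pnorm(0, rp$omega_e, rp$sigma)
      (pnorm(config$omega_max, rp$omega_e, rp$sigma) - below) / (1 - below)
    },
    noninformative = 2 * (pnorm(config$omega_max, 0, rp$sigma) - 0.5),
    uniform = if (rp$bounds[2] <= config$omega_max + 1e-12) 1 else
      (config$omega_max - rp$bounds[1]) / diff(rp$bounds)
  )
  if (cover_sigma < 0.99 || cover_omega < 0.99) {
    abort(sprintf(
      "Grid holds only %.1f%% of the slant prior and %.1f%% of the rotation prior; need >= 99%%.",
      100 * cover_sigma, 100 * cover_omega
    ))
  }
  invisible(TRUE)
}

#' @export
print.slantflow_posterior <- function(x, ...) {
  cat(sprintf(
    "<slantflow_posterior> %s model, def = %.4g rad/s, grid %d x %d\n",
    x$model, x$def_obs, length(x$sigma_axis), length(x$omega_axis)
  ))
  invisible(x)
}

#' @export
as_tibble.slantflow_posterior <- function(x, ...) {
  tibble::tibble(
    sigma_tan = rep(x$sigma_axis, times = length(x$omega_axis)),
    omega_rad_s = rep(x$omega_axis, each = length(x$sigma_axis)),
    density = as.vector(x$density)
  )
}

#' Marginal posterior over slant tangent
#'
#' Integrates the joint posterior over the rotation axis (trapezoidal rule),
#' giving the 1-D posterior from which the slant estimate is read out.
#'
#' @param grid A `slantflow_posterior` from [joint_posterior()].
#' @return A `slantflow_marginal` tibble with columns `sigma_tan`, `density`;
#'   integrates to 1.
#' @export
marginal_slant_posterior <- function(grid) {
  stopifnot(inherits(grid, "slantflow_posterior"))
  if (!isTRUE(grid$normalized)) abort("`grid` must be normalized.")
  dens <- as.vector(grid$density %*% trapezoid_weights(grid$omega_axis))
  out <- tibble::tibble(sigma_tan = grid$sigma_axis, density = dens)
  structure(out,
    model = grid$model, def_obs = grid$def_obs,
    class = c("slantflow_marginal", class(out))
  )
}

#' Posterior median slant estimate
#'
#' The Bayes estimator under absolute-error loss: the interpolated 50th
#' percentile of the marginal posterior CDF.
#'
#' @param marginal A `slantflow_marginal` (or a `slantflow_posterior`, which is
#'   marginalized first).
#' @return Slant-tangent estimate (scalar).
#' @export
posterior_median <- function(marginal) {
  if (inherits(marginal, "slantflow_posterior")) {
    marginal <- marginal_slant_posterior(marginal)
  }
  x <- marginal$sigma_tan
  y <- marginal$density
  if (all(y == 0)) abort("Degenerate marginal: all densities are zero.")
  w <- trapezoid_weights(x)
  total <- sum(w * y)
  if (abs(total - 1) > 1e-3) {
    abort("Marginal is not normalized (integral differs from 1 by > 1e-3).")
  }
  # cumulative trapezoid
  cdf <- cumsum(c(0, diff(x) * (head(y, -1) + tail(y, -1)) / 2)) / total
  i <- which(cdf >= 0.5)[1]
  if (i == 1L) {
    return(x[1])
  }
  x[i - 1] + (0.5 - cdf[i - 1]) / (cdf[i] - cdf[i - 1]) * (x[i] - x[i - 1])
}

#' Closed-form retinal-model prediction
#'
#' The retinal-only estimator's prediction in closed form: perceived slant
#' tangent equals `k * sqrt(def)`, where `k` is the square root of the ratio
#' of the prior spreads (see [retinal_k()]). This is the algebraic shortcut the
#' grid posterior is checked against, and the predictor used to compare model
#' and behavior.
#'
#' @param def_obs Observed def in rad/s (>= 0, vector ok).
#' @param k Slope parameter (> 0).
#' @return Predicted slant tangent(s).
#' @examples
#' closed_form_retinal_estimate(1.883, 1.88)
#' @export
closed_form_retinal_estimate <- function(def_obs, k) {
  if (any(def_obs < 0)) abort("`def_obs` must be non-negative.")
  if (any(k <= 0)) abort("`k` must be positive.")
  k * sqrt(def_obs)
}

#' One-call slant estimate
#'
#' Convenience wrapper running [joint_posterior()], [marginal_slant_posterior()]
#' and [posterior_median()] for each observed def.
#'
#' @param def_obs Observed def value(s) in rad/s.
#' @param config An [estimator_config()].
#' @return Numeric vector of slant-tangent estimates.
#' @export
estimate_slant <- function(def_obs, config) {
  vapply(
    def_obs,
    function(d) posterior_median(marginal_slant_posterior(joint_posterior(d, config))),
    numeric(1)
  )
}
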