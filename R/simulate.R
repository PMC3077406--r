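#' Design of a Monte Carlo estimator comparison
#'
#' Describes a factorial simulation crossing simulated slants with relative
#' rotation rates (equivalently, head-velocity regimes) for one or both
#' estimators. Defaults mirror the virtual-surface experiment: slants
#' {20, 35, 50, 65, 80} degrees and rotation rates {0.332, 0.067} rad/s (peak
#' head velocity 285.6 or 57.7 mm/s at 860 mm).
#'
#' For the inverse-optics model the rotation prior is centered, cell by cell,
#' on the cell's own rotation rate (the observer measures their head motion);
#' its spread is `io_sigma_omega` if given, otherwise
#' `io_sigma_omega_frac * omega_e`. For the retinal model the prior spreads are
#' fixed across cells (`sigma_sigma`, `retinal_sigma_omega`), so its predicted
#' slant is `sqrt(sigma_sigma / retinal_sigma_omega) * sqrt(def)`.
#'
#' @param slants_deg Simulated slants in degrees, each in (0, 90).
#' @param omegas_rad_s Relative rotation rates in rad/s (> 0).
#' @param models `"inverse_optics"`, `"retinal"`, or both (default).
#' @param sigma_sigma Slant prior spread shared by both models (default 3).
#' @param io_sigma_omega Absolute rotation prior spread for the inverse-optics
#'   model (rad/s); overrides `io_sigma_omega_frac`.
#' @param io_sigma_omega_frac Rotation prior spread as a fraction of the cell's
#'   `omega_e` (default 0.5).
#' @param retinal_sigma_omega Rotation prior spread of the retinal model
#'   (default 1 rad/s).
#' @param likelihood A [def_likelihood()] used by both estimators.
#' @param noise_sd SD of measurement noise added to the simulated def before
#'   estimation (default 0: the deterministic estimator output is recorded).
#' @param replicates Replicates per cell (default 1; > 1 only useful with
#'   noise).
#' @param seed Integer seed driving the def noise.
#' @param grid_n Grid size per axis for the estimators (default 512).
#' @return A `slantflow_design` object.
#' @examples
#' simulation_design(models = "retinal")
#' @export
simulation_design <- function(slants_deg = c(20, 35, 50, 65, 80),
                              omegas_rad_s = c(285.6 / 860, 57.7 / 860),
                              models = c("inverse_optics", "retinal"),
                              sigma_sigma = 3,
                              io_sigma_omega = NULL,
                              io_sigma_omega_frac = 0.5,
                              retinal_sigma_omega = 1,
                              likelihood = def_likelihood(cv = 0.05),
                              noise_sd = 0,
                              replicates = 1,
                              seed = 1,
                              grid_n = 512) {
  models <- match.arg(models, several.ok = TRUE)
  if (any(slants_deg <= 0 | slants_deg >= 90)) abort("`slants_deg` must lie in (0, 90).")
  if (any(omegas_rad_s <= 0)) abort("`omegas_rad_s` must be positive.")
  if (replicates < 1) abort("`replicates` must be >= 1.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  structure(
    list(
      slants_deg = slants_deg, omegas_rad_s = omegas_rad_s, models = models,
      sigma_sigma = sigma_sigma,
      io_sigma_omega = io_sigma_omega,
      io_sigma_omega_frac = io_sigma_omega_frac,
      retinal_sigma_omega = retinal_sigma_omega,
      likelihood = likelihood, noise_sd = noise_sd,
      replicates = replicates, seed = seed, grid_n = grid_n
    ),
    class = "slantflow_design"
  )
}

# Build the estimator config for one design cell.
design_config <- function(design, model, omega_e) {
  if (model == "inverse_optics") {
    s_omega <- design$io_sigma_omega %||% (design$io_sigma_omega_frac * omega_e)
    rp <- rotation_prior("stationarity", omega_e = omega_e, sigma = s_omega)
  } else {
    rp <- rotation_prior("noninformative", sigma = design$retinal_sigma_omega)
  }
  estimator_config(
    slant_prior = slant_prior(design$sigma_sigma),
    rotation_prior = rp,
    likelihood = design$likelihood,
    n_sigma = design$grid_n, n_omega = design$grid_n
  )
}

#' Run a Monte Carlo estimator comparison
#'
#' For every cell (model x slant x rotation rate x replicate) the true def is
#' `tan(slant) * omega`; an observed def is drawn from the measurement model
#' (or taken noise-free when `noise_sd = 0`); the designated estimator is run
#' and its posterior median recorded. Deterministic given the design's seed.
#'
#' @param design A [simulation_design()].
#' @return A tibble with columns `model`, `slant_deg`, `slant_sim_tan`,
#'   `omega_rad_s`, `replicate`, `def_true`, `def_obs`, `estimate_tan`.
#' @examples
#' \donttest{
#' tab <- run_simulation(simulation_design(models = "retinal", slants_deg = c(20, 80)))
#' }
#' @export
run_simulation <- function(design) {
  stopifnot(inherits(design, "slantflow_design"))
  cells <- tidyr::expand_grid(
    model = design$models,
    slant_deg = design$slants_deg,
    omega_rad_s = design$omegas_rad_s,
    replicate = seq_len(design$replicates)
  )
  withr_seed <- design$seed
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(withr_seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  out <- purrr::pmap(cells, function(model, slant_deg, omega_rad_s, replicate) {
    slant_tan <- tan(deg2rad(slant_deg))
    def_true <- def_rate(slant_tan, omega_rad_s)
    def_obs <- if (design$noise_sd > 0) {
      max(0, def_true + rnorm(1, 0, design$noise_sd))
    } else {
      def_true
    }
    cfg <- design_config(design, model, omega_rad_s)
    est <- tryCatch(
      estimate_slant(def_obs, cfg),
      error = function(e) {
        abort(sprintf(
          "Estimator failed in cell (model=%s, slant=%g, omega=%.4g): %s",
          model, slant_deg, omega_rad_s, conditionMessage(e)
        ))
      }
    )
    tibble::tibble(
      model = model, slant_deg = slant_deg, slant_sim_tan = slant_tan,
      omega_rad_s = omega_rad_s, replicate = replicate,
      def_true = def_true, def_obs = def_obs, estimate_tan = est
    )
  })
  res <- dplyr::bind_rows(out)
  structure(res, seed = design$seed, class = c("slantflow_estimates", class(res)))
}

#' Velocity-collapse diagnostic
#'
#' The signature separating the two models: when slant estimates are plotted
#' against `sqrt(def)`, the retinal model's estimates for different head
#' velocities fall on one line, while the inverse-optics model's estimates fall
#' on distinct curves. This diagnostic fits a no-intercept line
#' `estimate = a * sqrt(def)` separately within each rotation-rate group and
#' reports the spread of the fitted slopes (max minus min, and the slow-minus-
#' fast signed difference when there are exactly two groups), plus an optional
#' permutation p-value obtained by shuffling group labels across rows.
#'
#' @param table An estimate table from [run_simulation()] (or any data frame
#'   with columns `omega_rad_s`, `def_obs`, `estimate_tan`).
#' @param n_permutations Number of label permutations for the p-value
#'   (default 0: no test).
#' @param seed Seed for the permutation draw.
#' @return A `slantflow_collapse` list: `slopes` (tibble per group),
#'   `slope_diff` (max - min), `slope_diff_signed` (slow minus fast, two
#'   groups), `relative_diff` (`slope_diff` / mean slope), `p_value` (or NA).
#' @export
collapse_diagnostic <- function(table, n_permutations = 0, seed = 1) {
  need <- c("omega_rad_s", "def_obs", "estimate_tan")
  if (!all(need %in% names(table))) {
    abort("`table` must have columns omega_rad_s, def_obs, estimate_tan.")
  }
  groups <- sort(unique(table$omega_rad_s))
  if (length(groups) < 2) abort("`table` must contain at least two omega groups.")

  slope_of <- function(x, y) sum(x * y) / sum(x * x)
  fit_slopes <- function(g) {
    vapply(groups, function(om) {
      rows <- g == om
      slope_of(sqrt(table$def_obs[rows]), table$estimate_tan[rows])
    }, numeric(1))
  }
  slopes <- fit_slopes(table$omega_rad_s)
  slope_diff <- max(slopes) - min(slopes)
  slope_diff_signed <- if (length(groups) == 2) {
    # groups sorted ascending: slow (small omega) minus fast
    slopes[1] - slopes[2]
  } else {
    NA_real_
  }

  p_value <- NA_real_
  if (n_permutations > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    perm_stats <- vapply(seq_len(n_permutations), function(i) {
      g <- sample(table$omega_rad_s)
      s <- fit_slopes(g)
      max(s) - min(s)
    }, numeric(1))
    p_value <- (1 + sum(perm_stats >= slope_diff)) / (n_permutations + 1)
  }

  structure(
    list(
      slopes = tibble::tibble(omega_rad_s = groups, slope = slopes),
      slope_diff = slope_diff,
      slope_diff_signed = slope_diff_signed,
      relative_diff = slope_diff / mean(slopes),
      p_value = p_value,
      n = nrow(table)
    ),
    class = "slantflow_collapse"
  )
}

#' @export
print.slantflow_collapse <- function(x, ...) {
  cat(sprintf(
    "<slantflow_collapse> slope spread %.4g (relative %.3g%%), p = %s\n",
    x$slope_diff, 100 * x$relative_diff,
    if (is.na(x$p_value)) "NA" else format.pval(x$p_value)
  ))
  print(x$slopes)
  invisible(x)
}
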