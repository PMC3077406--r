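# Construct the common fit-result container.
new_fit <- function(type, coefficients, agreement_r2, n, p_value = NA_real_,
                    extra = list()) {
  structure(
    c(
      list(
        type = type, coefficients = coefficients,
        agreement_r2 = agreement_r2, n = n, p_value = p_value
      ),
      extra
    ),
    class = "slantflow_fit"
  )
}

#' @export
print.slantflow_fit <- function(x, ...) {
  cat(sprintf(
    "<slantflow_fit: %s> n = %d, agreement R2 = %.3f%s\n",
    x$type, x$n, x$agreement_r2,
    if (!is.na(x$p_value)) sprintf(", permutation p = %s", format.pval(x$p_value)) else ""
  ))
  print(x$coefficients)
  invisible(x)
}

#' No-intercept regression of responses on sqrt(def)
#'
#' The behavioral summary regression: perceived slant tangent regressed on
#' `sqrt(def)` through the origin. The least-squares slope is
#' `sum(x * y) / sum(x^2)`; a Vonesh-style agreement statistic between
#' observed and fitted values is attached.
#'
#' @param data A trial table with a response column and a def column.
#' @param response Name of the response column (default `"response_tan"`).
#' @param def Name of the def column (default `"def_max"`); the predictor is
#'   its square root.
#' @return A `slantflow_fit` with one coefficient (`sqrt_def` slope); see
#'   [tidy()] and [glance()].
#' @examples
#' trials <- simulate_responses(generate_trials("PVV", n_subjects = 4), seed = 1)
#' no_intercept_slope(trials)
#' @export
no_intercept_slope <- function(data, response = "response_tan", def = "def_max") {
  y <- data[[response]]
  x <- sqrt(data[[def]])
  if (is.null(y) || is.null(x)) abort("`data` must contain the response and def columns.")
  if (length(y) < 2) abort("Need at least two rows.")
  if (all(x == 0)) abort("The sqrt(def) predictor is identically zero.")
  fit <- lm(y ~ 0 + x)
  slope <- unname(coef(fit))
  # a perfect fit triggers a benign precision warning in summary.lm
  se <- suppressWarnings(summary(fit)$coefficients[1, 2])
  new_fit(
    "no_intercept_slope",
    tibble::tibble(
      term = "sqrt_def", estimate = slope, std_error = se
    ),
    agreement_r2 = agreement_statistic(y, slope * x),
    n = length(y)
  )
}

#' Vonesh-style agreement between observed and predicted values
#'
#' A model-concordance coefficient measuring agreement rather than mere
#' correlation:
#' `1 - sum((y - yhat)^2) / (sum((y - ybar)^2) + sum((yhat - yhatbar)^2) +
#' n * (ybar - yhatbar)^2)`.
#' It equals 1 only when observed and predicted agree exactly, 0 when the
#' model does no better than the observed mean, and can be negative for
#' models in systematic disagreement. It is invariant to a common shift of
#' both vectors.
#'
#' @param observed,predicted Numeric vectors of equal length >= 2.
#' @return Scalar in `(-Inf, 1]`.
#' @examples
#' agreement_statistic(1:5, 1:5) # 1
#' @export
agreement_statistic <- function(observed, predicted) {
  if (length(observed) != length(predicted)) abort("Lengths must match.")
  n <- length(observed)
  if (n < 2) abort("Need at least two observations.")
  ybar <- mean(observed)
  phat <- mean(predicted)
  denom <- sum((observed - ybar)^2) + sum((predicted - phat)^2) +
    n * (ybar - phat)^2
  if (denom == 0) abort("Agreement undefined: observed and predicted are all identical constants.")
  1 - sum((observed - predicted)^2) / denom
}

#' Permutation test for a head-velocity effect
#'
#' Tests whether the velocity regime influences responses beyond its effect on
#' def. The model is `response = a_c * sqrt(def) + b * regime`, with a
#' separate no-intercept `sqrt(def)` slope `a_c` per condition (conditions
#' have different behavioral slopes) and the regime contrast-coded +1/2
#' (normal) / -1/2 (slow), so `b` is the normal-minus-slow offset at matched
#' def. Under the retinal account the regime term is null — velocity
#' influences responses only through def.
#'
#' Significance comes from a Freedman-Lane permutation: the reduced model
#' (without the regime term) is fitted, its residuals are permuted in
#' subject-sized blocks (regime is assigned between subjects), pseudo-data are
#' rebuilt from the reduced fit plus permuted residuals, and the regime
#' coefficient is re-estimated. This keeps the permutation distribution's
#' variance faithful to the design even though regime and def range are
#' confounded by construction.
#'
#' @param data Trial table with columns `subject_id`, `condition`, `regime`, a
#'   response and a def column.
#' @param n_permutations Number of permutations (default 1000).
#' @param seed Integer seed for the permutations.
#' @param response,def Column names as in [no_intercept_slope()].
#' @return A `slantflow_fit` with the per-condition `sqrt_def` slopes and the
#'   `regime_normal` contrast, and a permutation `p_value` for the latter.
#' @export
velocity_effect_test <- function(data, n_permutations = 1000, seed = 1,
                                 response = "response_tan", def = "def_max") {
  need <- c("subject_id", "condition", "regime", response, def)
  if (!all(need %in% names(data))) {
    abort(sprintf("`data` must have columns: %s.", paste(need, collapse = ", ")))
  }
  if (length(unique(data$regime)) < 2) {
    abort("Both velocity regimes must be present.")
  }
  y <- data[[response]]
  x <- sqrt(data[[def]])
  conds <- sort(unique(data$condition))
  slope_cols <- vapply(conds, function(cc) x * (data$condition == cc),
    numeric(length(x))
  )
  g <- (data$regime == "normal") - 0.5

  X_full <- cbind(slope_cols, g)
  X_red <- slope_cols
  solve_ls <- function(X, yy) solve(crossprod(X), crossprod(X, yy))[, 1]
  coefs <- solve_ls(X_full, y)
  obs_b <- coefs[length(coefs)]

  # Freedman-Lane: permute reduced-model residuals in subject blocks
  red_coef <- solve_ls(X_red, y)
  fitted_red <- as.vector(X_red %*% red_coef)
  resid_red <- y - fitted_red
  blocks <- split(seq_along(y), data$subject_id)
  equal_blocks <- length(unique(lengths(blocks))) == 1L

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  perm_b <- vapply(seq_len(n_permutations), function(i) {
    idx <- if (equal_blocks) {
      unlist(blocks[sample(length(blocks))], use.names = FALSE)
    } else {
      sample(length(y))
    }
    y_star <- fitted_red + resid_red[idx]
    b <- solve_ls(X_full, y_star)
    b[length(b)]
  }, numeric(1))
  p <- (1 + sum(abs(perm_b) >= abs(obs_b))) / (n_permutations + 1)

  fitted <- as.vector(X_full %*% coefs)
  new_fit(
    "velocity_effect_test",
    tibble::tibble(
      term = c(paste0("sqrt_def_", conds), "regime_normal"),
      estimate = unname(coefs)
    ),
    agreement_r2 = agreement_statistic(y, fitted),
    n = length(y),
    p_value = p,
    extra = list(n_permutations = n_permutations)
  )
}

#' Observed versus model-predicted slant
#'
#' Regresses observed responses on the retinal model's closed-form predictions
#' `k_condition * sqrt(def)`. Perfect correspondence gives slope 1 and
#' intercept 0; the agreement statistic summarizes concordance.
#'
#' @param data Trial table with columns `condition`, a response and a def
#'   column.
#' @param k_by_condition Named vector of condition slopes used for the
#'   predictions.
#' @param response,def Column names as in [no_intercept_slope()].
#' @return A `slantflow_fit` with `intercept` and `slope` coefficients
#'   (including 95% confidence bounds) and the agreement statistic.
#' @export
observed_vs_predicted <- function(data,
                                  k_by_condition = c(PVV = 1.04, AVV = 1.88, AVP = 2.41),
                                  response = "response_tan", def = "def_max") {
  if (!all(c("condition", response, def) %in% names(data))) {
    abort("`data` must have columns `condition`, response and def.")
  }
  missing_k <- setdiff(unique(data$condition), names(k_by_condition))
  if (length(missing_k)) {
    abort(sprintf("No k for condition(s): %s.", paste(missing_k, collapse = ", ")))
  }
  y <- data[[response]]
  pred <- closed_form_retinal_estimate(
    data[[def]], unname(k_by_condition[data$condition])
  )
  fit <- lm(y ~ pred)
  ci <- suppressWarnings(confint(fit))
  new_fit(
    "observed_vs_predicted",
    tibble::tibble(
      term = c("intercept", "slope"),
      estimate = unname(coef(fit)),
      conf_low = ci[, 1],
      conf_high = ci[, 2]
    ),
    agreement_r2 = agreement_statistic(y, pred),
    n = length(y)
  )
}

#' Tidy a slantflow fit
#'
#' Returns the coefficient table of a [no_intercept_slope()],
#' [velocity_effect_test()] or [observed_vs_predicted()] result as a tibble.
#'
#' @param x A `slantflow_fit`.
#' @param ... Unused.
#' @return A tibble with one row per term.
#' @export
tidy.slantflow_fit <- function(x, ...) x$coefficients

#' One-row summary of a slantflow fit
#'
#' @param x A `slantflow_fit`.
#' @param ... Unused.
#' @return A one-row tibble with `type`, `agreement_r2`, `p_value`, `n`.
#' @export
glance.slantflow_fit <- function(x, ...) {
  tibble::tibble(
    type = x$type,
    agreement_r2 = x$agreement_r2,
    p_value = x$p_value,
    n = x$n
  )
}
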