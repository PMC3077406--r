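#' Plot a joint posterior grid
#'
#' Raster of the joint density over (slant tangent, rotation rate), with the
#' constraint hyperbola `sigma * omega = def` overlaid.
#'
#' @param object A `slantflow_posterior`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.slantflow_posterior <- function(object, ...) {
  df <- as_tibble(object)
  hyper <- tibble::tibble(
    sigma_tan = object$sigma_axis[object$sigma_axis > 0]
  )
  hyper$omega_rad_s <- object$def_obs / hyper$sigma_tan
  hyper <- hyper[hyper$omega_rad_s <= max(object$omega_axis), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(.data$omega_rad_s, .data$sigma_tan)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$density)) +
    ggplot2::geom_line(
      data = hyper, linetype = "dashed", colour = "white", na.rm = TRUE
    ) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(
      x = expression(omega ~ "(rad/s)"), y = expression(tan ~ sigma),
      title = sprintf("%s posterior, def = %.3g rad/s", object$model, object$def_obs)
    )
}

#' Plot a marginal slant posterior
#'
#' @param object A `slantflow_marginal`.
#' @param ... Unused.
#' @return A ggplot with the posterior median marked.
#' @export
autoplot.slantflow_marginal <- function(object, ...) {
  med <- posterior_median(object)
  ggplot2::ggplot(object, ggplot2::aes(.data$sigma_tan, .data$density)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = med, linetype = "dotted") +
    ggplot2::labs(
      x = expression(tan ~ sigma), y = "posterior density",
      title = sprintf("median = %.3g", med)
    )
}

#' Plot a Monte Carlo estimate table
#'
#' Shows estimated slant tangent against simulated slant tangent and against
#' `sqrt(def)`, by rotation-rate group — the layout in which the retinal
#' model's estimates collapse onto one line while the inverse-optics model's
#' estimates separate.
#'
#' @param object An estimate table from [run_simulation()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.slantflow_estimates <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::mutate(object, sqrt_def = sqrt(.data$def_obs)),
    cols = c("slant_sim_tan", "sqrt_def"),
    names_to = "x_var", values_to = "x"
  )
  ggplot2::ggplot(df, ggplot2::aes(
    .data$x, .data$estimate_tan,
    colour = factor(round(.data$omega_rad_s, 3))
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::facet_grid(model ~ x_var, scales = "free_x") +
    ggplot2::labs(
      x = NULL, y = "estimated tan(slant)", colour = expression(omega ~ "(rad/s)")
    )
}

#' Plot simulated (or observed) responses against sqrt(def)
#'
#' The behavioral summary view: responses on the tangent scale against
#' `sqrt(def)`, colored by velocity regime and faceted by condition, with the
#' per-condition no-intercept regression line.
#'
#' @param trials A trial table with a `response_tan` column.
#' @return A ggplot.
#' @export
plot_responses <- function(trials) {
  if (!"response_tan" %in% names(trials)) {
    abort("`trials` must contain responses; see simulate_responses().")
  }
  df <- dplyr::mutate(trials, sqrt_def = sqrt(.data$def_max))
  slopes <- df |>
    dplyr::group_by(.data$condition) |>
    dplyr::group_modify(function(d, key) {
      tidy(no_intercept_slope(d))
    }) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(.data$sqrt_def, .data$response_tan)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$regime), alpha = 0.4) +
    ggplot2::geom_abline(
      data = slopes,
      ggplot2::aes(intercept = 0, slope = .data$estimate)
    ) +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = expression(sqrt(def)), y = "response tan(slant)")
}
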