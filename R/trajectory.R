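#' Sinusoidal lateral head trajectory
#'
#' Generates the idealized back-and-forth lateral head translation used to
#' drive the flow model: `x(t) = A * sin(2 * pi * t / T)` with the period set
#' by the required peak velocity, `T = 2 * pi * A / v_peak`, truncated after
#' `n_half_cycles` half-periods. With the default amplitude of 25 mm the
#' peak-to-peak excursion is the experiment's 50 mm maximum lateral head shift,
#' and 11 half-cycles at 285.6 mm/s last about 3.0 s.
#'
#' @param peak_velocity_mm_s Peak lateral velocity in mm/s (> 0).
#' @param amplitude_mm Amplitude `A` in mm (> 0); peak-to-peak shift is `2 * A`.
#' @param n_half_cycles Number of half-periods (>= 2).
#' @param sample_rate_hz Sampling rate in Hz; must give at least 20 samples per
#'   half-cycle.
#'
#' @return A `slantflow_trajectory` tibble with columns `t_s`, `x_mm`,
#'   `v_mm_s` and attributes `peak_velocity_mm_s`, `amplitude_mm`,
#'   `n_half_cycles`, `sample_rate_hz`.
#' @examples
#' tr <- make_trajectory(285.6, 25, 11, 1000)
#' range(tr$x_mm)
#' max(abs(tr$v_mm_s))
#' @export
make_trajectory <- function(peak_velocity_mm_s, amplitude_mm = 25,
                            n_half_cycles = 11, sample_rate_hz = 250) {
  if (peak_velocity_mm_s <= 0 || amplitude_mm <= 0 || sample_rate_hz <= 0) {
    abort("`peak_velocity_mm_s`, `amplitude_mm` and `sample_rate_hz` must be positive.")
  }
  if (n_half_cycles < 2) abort("`n_half_cycles` must be >= 2.")
  period_s <- 2 * pi * amplitude_mm / peak_velocity_mm_s
  if (sample_rate_hz * period_s / 2 < 20) {
    abort("`sample_rate_hz` too low: need at least 20 samples per half-cycle.")
  }
  duration_s <- n_half_cycles * period_s / 2
  t_s <- seq(0, duration_s, by = 1 / sample_rate_hz)
  out <- tibble::tibble(
    t_s = t_s,
    x_mm = amplitude_mm * sin(2 * pi * t_s / period_s),
    v_mm_s = peak_velocity_mm_s * cos(2 * pi * t_s / period_s)
  )
  structure(
    out,
    peak_velocity_mm_s = peak_velocity_mm_s,
    amplitude_mm = amplitude_mm,
    n_half_cycles = n_half_cycles,
    sample_rate_hz = sample_rate_hz,
    period_s = period_s,
    class = c("slantflow_trajectory", class(out))
  )
}

#' Check a trajectory against the experiment's velocity feedback bands
#'
#' The experiment signaled, via acoustic feedback, whether the average lateral
#' head speed stayed inside a target band: 83 +/- 40 mm/s in the normal regime,
#' 20 +/- 10 mm/s in the slow regime. This check mirrors that criterion on a
#' simulated trajectory. Note that the printed bands refer to measured human
#' kinematics and are not consistent with the printed peak velocities under any
#' simple periodic trajectory, so for the idealized sinusoid the check is
#' advisory: it reports the band and the trajectory's mean speed rather than
#' gating any computation.
#'
#' @param trajectory A data frame with column `v_mm_s`.
#' @param regime `"normal"` or `"slow"`.
#'
#' @return Logical scalar (`TRUE` if mean |v| is inside the band), with
#'   attributes `mean_speed_mm_s` and `band_mm_s`.
#' @export
velocity_band_check <- function(trajectory, regime = c("normal", "slow")) {
  regime <- match.arg(regime)
  band <- if (regime == "normal") c(83 - 40, 83 + 40) else c(20 - 10, 20 + 10)
  mean_speed <- mean(abs(trajectory$v_mm_s))
  ok <- mean_speed >= band[1] && mean_speed <= band[2]
  structure(ok, mean_speed_mm_s = mean_speed, band_mm_s = band)
}
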