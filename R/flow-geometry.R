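#' Relative rotation rate between observer and surface
#'
#' A laterally translating observer who keeps fixating a point on a surface at
#' distance `d` experiences the surface rotating, in egocentric coordinates, at
#' `v / d` radians per second. Any independent rotation of the object adds to
#' this egocentric component; for the stationary surfaces modeled here the
#' object term is zero and the relative rotation is produced entirely by the
#' observer's own movement.
#'
#' @param head_velocity_mm_s Lateral head velocity in mm/s (may be signed).
#' @param distance_mm Viewing distance in mm (> 0).
#' @param object_rotation_rad_s Independent rotation of the surface in rad/s
#'   (default 0: stationary surface).
#'
#' @return Relative rotation rate in rad/s.
#' @examples
#' relative_rotation_rate(285.6, 860) # normal regime, ~0.33 rad/s
#' relative_rotation_rate(57.7, 860)  # slow regime, ~0.07 rad/s
#' @export
relative_rotation_rate <- function(head_velocity_mm_s, distance_mm,
                                   object_rotation_rad_s = 0) {
  if (any(distance_mm <= 0)) abort("`distance_mm` must be positive.")
  object_rotation_rad_s + head_velocity_mm_s / distance_mm
}

#' Deformation gradient of the first-order flow field
#'
#' The def component of the velocity field generated by a slanted plane
#' rotating at `omega` relative to the observer equals the rotation rate times
#' the slant tangent: `def = omega * tan(slant)`. It is the spatial gradient of
#' the local image velocity with respect to angular elevation, and the single
#' flow quantity both estimators consume.
#'
#' @param slant_tan Slant tangent (dimensionless, signed allowed).
#' @param omega_rad_s Relative rotation rate in rad/s (signed allowed).
#'
#' @return def in rad/s; bilinear in both arguments.
#' @examples
#' def_rate(tan(80 * pi / 180), 285.6 / 860)
#' @export
def_rate <- function(slant_tan, omega_rad_s) {
  omega_rad_s * slant_tan
}

# Half-width (rad) of the image patch over which the first-order linearization
# of the flow holds (~8 deg full width).
patch_half_width_rad <- 0.07

#' Local image velocity of the linearized flow field
#'
#' First-order approximation of the image angular velocity at elevation `beta`
#' for a plane slanted about the horizontal axis (tilt 90 deg):
#' `v(beta) = omega * (1 + beta * tan(slant))`. The approximation is valid over
#' a patch of about 8 degrees around the fixation point; `beta` outside
#' that patch is rejected.
#'
#' @param beta_rad Angular elevation of the feature in radians
#'   (|beta| <= 0.07).
#' @param slant_tan Slant tangent.
#' @param omega_rad_s Relative rotation rate in rad/s.
#'
#' @return Image angular velocity in rad/s. The derivative of this function
#'   with respect to `beta_rad` is [def_rate()].
#' @examples
#' local_velocity(0.05, tan(80 * pi / 180), 0.332)
#' @export
local_velocity <- function(beta_rad, slant_tan, omega_rad_s) {
  if (any(abs(beta_rad) > patch_half_width_rad)) {
    abort(sprintf(
      "`beta_rad` must satisfy |beta| <= %.2f rad (the ~8 deg linearization patch).",
      patch_half_width_rad
    ))
  }
  omega_rad_s * (1 + beta_rad * slant_tan)
}

#' Surface rotation swept by the full head excursion
#'
#' The total lateral head shift subtends, at the viewing distance, a relative
#' surface rotation of `atan(shift / d)`, independent of surface slant.
#'
#' @param total_lateral_shift_mm Total lateral head shift in mm (>= 0).
#' @param distance_mm Viewing distance in mm (> 0).
#'
#' @return Swept rotation in degrees.
#' @examples
#' sweep_rotation_deg(50, 860) # virtual surface, ~3.33 deg
#' sweep_rotation_deg(50, 760) # physical surface, ~3.76 deg
#' @export
sweep_rotation_deg <- function(total_lateral_shift_mm, distance_mm) {
  if (any(distance_mm <= 0)) abort("`distance_mm` must be positive.")
  if (any(total_lateral_shift_mm < 0)) abort("`total_lateral_shift_mm` must be >= 0.")
  rad2deg(atan(total_lateral_shift_mm / distance_mm))
}

#' Instantaneous def profile of a trial
#'
#' Converts a head trajectory into the time course of the deformation gradient:
#' `def(t) = (v(t) / d) * tan(slant)`, signed (back-and-forth motion alternates
#' the sign of def). Samples are assigned to def cycles delimited by the
#' velocity zero-crossings; the leading and trailing partial cycles get
#' `cycle_id = NA` and are excluded from per-trial summaries.
#'
#' @param trajectory A head trajectory from [make_trajectory()] (or any data
#'   frame with columns `t_s`, `v_mm_s`).
#' @param surface A [surface_spec()].
#' @param condition A [viewing_condition()]; supplies the viewing distance.
#'
#' @return A tibble with columns `t_s`, `def_rad_s`, `cycle_id`.
#' @seealso [max_def()]
#' @export
def_profile <- function(trajectory, surface, condition) {
  if (!is.data.frame(trajectory) || nrow(trajectory) == 0) {
    abort("`trajectory` must be a non-empty data frame with columns t_s, v_mm_s.")
  }
  if (!all(c("t_s", "v_mm_s") %in% names(trajectory))) {
    abort("`trajectory` must have columns `t_s` and `v_mm_s`.")
  }
  t_s <- trajectory$t_s
  if (is.unsorted(t_s, strictly = TRUE)) abort("`t_s` must be strictly increasing.")
  omega <- relative_rotation_rate(trajectory$v_mm_s, condition$distance_mm)
  def <- def_rate(surface$slant_tan, omega)
  tibble::tibble(
    t_s = t_s,
    def_rad_s = def,
    cycle_id = assign_cycles(trajectory$v_mm_s)
  )
}

# Cycle bookkeeping: a def cycle is the interval between consecutive velocity
# zero-crossings (one sign-constant lobe of def). Partial lobes at either end
# are NA.
assign_cycles <- function(v) {
  n <- length(v)
  s <- sign(v)
  # treat exact zeros as boundaries belonging to the following lobe
  crossing_after <- which(s[-n] * s[-1] < 0 | (s[-n] != 0 & s[-1] == 0))
  cycle <- rep(NA_integer_, n)
  if (length(crossing_after) >= 2) {
    for (k in seq_len(length(crossing_after) - 1L)) {
      idx <- (crossing_after[k] + 1L):crossing_after[k + 1L]
      cycle[idx] <- k
    }
  }
  cycle
}

#' Per-trial maximum def
#'
#' Summarizes a def profile as the mean over complete cycles of the per-cycle
#' maximum of |def(t)| — the per-trial quantity the retinal model's
#' `k * sqrt(def)` prediction is evaluated on.
#'
#' @param profile A def profile from [def_profile()] (columns `def_rad_s`,
#'   `cycle_id`), or any data frame with those columns.
#'
#' @return Non-negative scalar, rad/s.
#' @export
max_def <- function(profile) {
  if (!is.data.frame(profile) || !all(c("def_rad_s", "cycle_id") %in% names(profile))) {
    abort("`profile` must be a data frame with columns `def_rad_s` and `cycle_id`.")
  }
  complete <- profile[!is.na(profile$cycle_id), , drop = FALSE]
  if (nrow(complete) == 0) {
    abort("`profile` contains no complete def cycle.")
  }
  peaks <- tapply(abs(complete$def_rad_s), complete$cycle_id, max)
  mean(peaks)
}

#' Closed-form max def for a sinusoidal trial
#'
#' Convenience wrapper: for the sinusoidal head trajectory the per-cycle peak of
#' |def| is attained at peak velocity, so the per-trial max def is
#' `(v_peak / d) * tan(slant)` exactly.
#'
#' @inheritParams def_profile
#' @return Non-negative scalar, rad/s.
#' @export
max_def_closed_form <- function(surface, condition) {
  abs(def_rate(
    surface$slant_tan,
    relative_rotation_rate(condition$peak_velocity_mm_s, condition$distance_mm)
  ))
}
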