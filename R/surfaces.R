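#' Specify a planar stimulus surface
#'
#' A planar surface is described by its slant (the angle between the surface
#' normal and the line of sight) and its tilt (the image-plane orientation of
#' the projected normal). All stimuli modeled here have tilt fixed at 90
#' degrees, i.e. the surface is slanted about the horizontal axis so that depth
#' varies with vertical position in the image. Slant is carried as its tangent,
#' which is the scale on which responses and model predictions are expressed.
#'
#' @param slant_deg Slant in degrees, in `[0, 90)`.
#' @param kind `"virtual"` (rendered dot display) or `"physical"` (real
#'   surface); affects only bookkeeping such as the default viewing distance.
#'
#' @return A `slantflow_surface` object: a list with fields `slant_deg`,
#'   `slant_tan`, `tilt_deg` (always 90) and `kind`.
#' @examples
#' surface_spec(80)
#' surface_spec(50, kind = "physical")
#' @export
surface_spec <- function(slant_deg, kind = c("virtual", "physical")) {
  kind <- match.arg(kind)
  if (!is.numeric(slant_deg) || length(slant_deg) != 1L || is.na(slant_deg)) {
    abort("`slant_deg` must be a single number.")
  }
  if (slant_deg < 0 || slant_deg >= 90) {
    abort("`slant_deg` must lie in [0, 90).")
  }
  structure(
    list(
      slant_deg = slant_deg,
      slant_tan = tan(deg2rad(slant_deg)),
      tilt_deg = 90,
      kind = kind
    ),
    class = "slantflow_surface"
  )
}

#' @export
print.slantflow_surface <- function(x, ...) {
  cat(sprintf(
    "<slantflow_surface> %s, slant %.4g deg (tan = %.4g), tilt 90 deg\n",
    x$kind, x$slant_deg, x$slant_tan
  ))
  invisible(x)
}

#' Specify a viewing condition
#'
#' Viewing distance, head-translation velocity regime and viewing mode for one
#' experimental condition. The three condition labels are AVV (active viewing,
#' virtual surface), PVV (passive viewing, virtual surface) and AVP (active
#' viewing, physical surface). Virtual surfaces sit at 860 mm, the physical
#' surface at 760 mm; peak head velocity is 285.6 mm/s in the normal regime and
#' 57.7 mm/s in the slow regime.
#'
#' @param label Condition label: `"AVV"`, `"PVV"` or `"AVP"`.
#' @param regime Velocity regime, `"normal"` or `"slow"`.
#' @param distance_mm Viewing distance in mm; defaults to 860 (virtual) or 760
#'   (physical) according to `label`.
#' @param peak_velocity_mm_s Peak lateral head velocity in mm/s; defaults to
#'   285.6 (`"normal"`) or 57.7 (`"slow"`).
#'
#' @return A `slantflow_condition` object.
#' @examples
#' viewing_condition("AVV", "normal")
#' viewing_condition("AVP", "slow")
#' @export
viewing_condition <- function(label = c("AVV", "PVV", "AVP"),
                              regime = c("normal", "slow"),
                              distance_mm = NULL,
                              peak_velocity_mm_s = NULL) {
  label <- match.arg(label)
  regime <- match.arg(regime)
  distance_mm <- distance_mm %||% if (label == "AVP") 760 else 860
  peak_velocity_mm_s <- peak_velocity_mm_s %||%
    if (regime == "normal") 285.6 else 57.7
  if (distance_mm <= 0) abort("`distance_mm` must be positive.")
  if (peak_velocity_mm_s <= 0) abort("`peak_velocity_mm_s` must be positive.")
  structure(
    list(
      label = label,
      mode = if (label == "PVV") "passive" else "active",
      kind = if (label == "AVP") "physical" else "virtual",
      regime = regime,
      distance_mm = distance_mm,
      peak_velocity_mm_s = peak_velocity_mm_s
    ),
    class = "slantflow_condition"
  )
}

#' @export
print.slantflow_condition <- function(x, ...) {
  cat(sprintf(
    "<slantflow_condition> %s (%s, %s surface), d = %g mm, v_peak = %g mm/s (%s)\n",
    x$label, x$mode, x$kind, x$distance_mm, x$peak_velocity_mm_s, x$regime
  ))
  invisible(x)
}

# Experimental design constants: slant sets, repetitions, per-condition defaults.
condition_design <- function(label) {
  switch(label,
    AVV = ,
    PVV = list(slants_deg = c(20, 35, 50, 65, 80), repetitions = 5, distance_mm = 860),
    AVP = list(slants_deg = c(10, 20, 40, 50), repetitions = 4, distance_mm = 760),
    abort(sprintf("Unknown condition label '%s'.", label))
  )
}
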