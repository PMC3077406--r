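#' Project surface dots through a pinhole eye
#'
#' Perspective projection of random dots lying on a slanted plane, with the
#' (right) eye position as the center of projection and the screen as image
#' plane — the exact generative model behind the linearized flow equations.
#'
#' Geometry: the eye's reference position is the origin, the screen is the
#' plane `z = distance_mm`, and the surface is the plane through the screen
#' center satisfying `z = d + y * tan(slant)` (slant about the horizontal
#' axis; tilt 90 deg). As in the experiment, dots are uniform in the *image*
#' from the reference viewpoint (removing texture cues): image positions are
#' drawn uniformly in a disk of angular radius `aperture_deg`, back-projected
#' onto the surface plane, and those fixed 3-D points are then projected
#' through the given eye position. Calling the function twice with the same
#' seed but different eye positions therefore yields two frames of the same
#' rigid dot field.
#'
#' @param surface A [surface_spec()].
#' @param eye_position_mm Numeric length-3 eye position (mm); the reference
#'   viewpoint is `c(0, 0, 0)`.
#' @param n_dots Number of dots (default 100, the virtual display; the
#'   physical surface carried about 13).
#' @param distance_mm Viewing distance to the screen/surface center (mm).
#' @param aperture_deg Angular radius of the visible patch (default 4, the 8
#'   degree patch over which the first-order flow model is valid).
#' @param seed Integer seed for the dot field.
#' @return A `slantflow_dots` tibble with the surface points (`x_mm`, `y_mm`,
#'   `z_mm`) and their image projections (`x_img_mm`, `y_img_mm`); the eye
#'   position is stored as an attribute.
#' @examples
#' s <- surface_spec(50)
#' f1 <- project_dots(s, c(-10, 0, 0), seed = 1)
#' f2 <- project_dots(s, c(10, 0, 0), seed = 1)
#' @export
project_dots <- function(surface, eye_position_mm = c(0, 0, 0), n_dots = 100,
                         distance_mm = 860, aperture_deg = 4, seed = 1) {
  stopifnot(inherits(surface, "slantflow_surface"))
  if (length(eye_position_mm) != 3L) abort("`eye_position_mm` must have length 3.")
  if (n_dots < 1) abort("`n_dots` must be >= 1.")
  if (eye_position_mm[3] >= distance_mm) abort("Surface must be in front of the eye.")

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))

  # uniform dots in an image disk seen from the reference eye at the origin
  r_max <- distance_mm * tan(deg2rad(aperture_deg))
  r <- r_max * sqrt(stats::runif(n_dots))
  th <- stats::runif(n_dots, 0, 2 * pi)
  xi <- r * cos(th)
  yi <- r * sin(th)

  # back-project: ray t * (xi, yi, d) meets z = d + y * tan(slant)
  g <- surface$slant_tan
  t_scale <- distance_mm / (distance_mm - yi * g)
  x3 <- xi * t_scale
  y3 <- yi * t_scale
  z3 <- distance_mm * t_scale

  # project the fixed 3-D points through the actual eye onto the screen plane
  e <- as.numeric(eye_position_mm)
  lambda <- (distance_mm - e[3]) / (z3 - e[3])
  if (any(lambda <= 0)) abort("Surface must be in front of the eye.")
  out <- tibble::tibble(
    dot = seq_len(n_dots),
    x_mm = x3, y_mm = y3, z_mm = z3,
    x_img_mm = e[1] + lambda * (x3 - e[1]),
    y_img_mm = e[2] + lambda * (y3 - e[2])
  )
  structure(out,
    eye_position_mm = e, distance_mm = distance_mm, seed = seed,
    class = c("slantflow_dots", class(out))
  )
}

#' Eye-centered angular dot positions under fixation
#'
#' Converts the 3-D dots of a frame into horizontal and vertical angular
#' coordinates relative to the gaze direction of an eye fixating
#' `fixation_mm`. Differencing these angles across two frames with displaced
#' eye positions gives the retinal flow that the linearized model describes.
#'
#' @param dots A `slantflow_dots` frame from [project_dots()].
#' @param eye_position_mm Eye position of this frame (defaults to the frame's
#'   own attribute).
#' @param fixation_mm Fixated 3-D point (default: screen center at the frame's
#'   viewing distance).
#' @return A tibble with columns `dot`, `alpha_rad` (horizontal angle),
#'   `beta_rad` (vertical elevation).
#' @export
retinal_angles <- function(dots, eye_position_mm = NULL, fixation_mm = NULL) {
  stopifnot(inherits(dots, "slantflow_dots"))
  e <- eye_position_mm %||% attr(dots, "eye_position_mm")
  f <- fixation_mm %||% c(0, 0, attr(dots, "distance_mm"))
  # gaze frame: z' toward fixation, x' horizontal, y' up
  gz <- (f - e) / sqrt(sum((f - e)^2))
  gx <- c(gz[3], 0, -gz[1])
  gx <- gx / sqrt(sum(gx^2))
  gy <- c(
    gz[2] * gx[3] - gz[3] * gx[2],
    gz[3] * gx[1] - gz[1] * gx[3],
    gz[1] * gx[2] - gz[2] * gx[1]
  )
  p <- cbind(dots$x_mm - e[1], dots$y_mm - e[2], dots$z_mm - e[3])
  tibble::tibble(
    dot = dots$dot,
    alpha_rad = atan2(p %*% gx, p %*% gz)[, 1],
    beta_rad = atan2(p %*% gy, p %*% gz)[, 1]
  )
}

#' Generate the trial table of one condition (without responses)
#'
#' Builds the full crossing of simulated slants and repetitions for each
#' subject of one experimental block: AVV and PVV blocks have 25 trials (5
#' repetitions of slants 20, 35, 50, 65, 80 deg at 860 mm), AVP blocks 16
#' trials (4 repetitions of slants 10, 20, 40, 50 deg at 760 mm). Subjects are
#' assigned between-subjects to the normal or slow velocity regime
#' (alternating, so `n_subjects` splits as evenly as possible), and each
#' trial's `def_max` is computed through the flow-geometry pipeline from the
#' regime's head trajectory.
#'
#' In the passive block the experiment replayed the optic flow recorded in the
#' active block; pass the AVV table as `replay_from` to copy its per-trial def
#' values (and regime assignment) into the PVV table.
#'
#' @param condition `"AVV"`, `"PVV"` or `"AVP"`.
#' @param n_subjects Number of subjects (default 34, split across regimes).
#' @param regimes Optional character vector of per-subject regimes
#'   (`"normal"`/`"slow"`); default alternates.
#' @param seed Integer seed recorded in the table (trial structure itself is
#'   deterministic).
#' @param replay_from Optional AVV trial table whose def values are replayed
#'   (PVV only).
#' @param sample_rate_hz Trajectory sampling rate (default 250).
#' @return A tibble with columns `subject_id`, `condition`, `regime`,
#'   `slant_sim_deg`, `slant_sim_tan`, `def_max`, `seed`.
#' @examples
#' trials <- generate_trials("AVV", n_subjects = 2, seed = 7)
#' nrow(trials) # 50
#' @export
generate_trials <- function(condition = c("AVV", "PVV", "AVP"),
                            n_subjects = 34, regimes = NULL, seed = 1,
                            replay_from = NULL, sample_rate_hz = 250) {
  condition <- match.arg(condition)
  design <- condition_design(condition)
  if (is.null(regimes)) {
    regimes <- rep(c("normal", "slow"), length.out = n_subjects)
  }
  if (length(regimes) != n_subjects) {
    abort("`regimes` must have one entry per subject.")
  }
  if (!all(regimes %in% c("normal", "slow"))) {
    abort("`regimes` entries must be 'normal' or 'slow'.")
  }

  if (condition == "PVV" && !is.null(replay_from)) {
    out <- replay_from
    out$condition <- "PVV"
    out$seed <- seed
    return(out)
  }

  # def_max is shared within (regime, slant), so compute once per combination
  key <- tidyr::expand_grid(
    regime = unique(regimes), slant_sim_deg = design$slants_deg
  )
  key$def_max <- purrr::pmap_dbl(key, function(regime, slant_sim_deg) {
    cond <- viewing_condition(condition, regime, distance_mm = design$distance_mm)
    tr <- make_trajectory(cond$peak_velocity_mm_s, sample_rate_hz = sample_rate_hz)
    surf <- surface_spec(slant_sim_deg, kind = cond$kind)
    max_def(def_profile(tr, surf, cond))
  })

  out <- tidyr::expand_grid(
    subject_id = seq_len(n_subjects),
    slant_sim_deg = design$slants_deg,
    repetition = seq_len(design$repetitions)
  )
  out$regime <- regimes[out$subject_id]
  out <- dplyr::left_join(out, key, by = c("regime", "slant_sim_deg"))
  tibble::tibble(
    subject_id = out$subject_id,
    condition = condition,
    regime = out$regime,
    slant_sim_deg = out$slant_sim_deg,
    slant_sim_tan = tan(deg2rad(out$slant_sim_deg)),
    def_max = out$def_max,
    seed = seed
  )
}

#' Simulate slant judgments
#'
#' Adds responses to a trial table under the behavioral model the experiment
#' supports: perceived slant tangent is `k * sqrt(def)` plus Gaussian noise,
#' floored at zero (judgments are magnitudes in 0-90 deg). The default
#' condition slopes are the fitted behavioral values (PVV 1.04, AVV 1.88, AVP
#' 2.41) and the default noise SD is 0.218 on the tangent scale.
#'
#' @param trials A trial table from [generate_trials()].
#' @param k_by_condition Named vector mapping condition labels to slopes.
#' @param noise_sd_tan Gaussian noise SD on the tangent scale (>= 0).
#' @param seed Integer seed for the noise.
#' @return The trial table with a `response_tan` column appended.
#' @examples
#' trials <- generate_trials("PVV", n_subjects = 2, seed = 7)
#' simulate_responses(trials, seed = 7)
#' @export
simulate_responses <- function(trials,
                               k_by_condition = c(PVV = 1.04, AVV = 1.88, AVP = 2.41),
                               noise_sd_tan = 0.218, seed = 1) {
  if (!all(c("condition", "def_max") %in% names(trials))) {
    abort("`trials` must have columns `condition` and `def_max`.")
  }
  if (noise_sd_tan < 0) abort("`noise_sd_tan` must be >= 0.")
  missing_k <- setdiff(unique(trials$condition), names(k_by_condition))
  if (length(missing_k)) {
    abort(sprintf("No k for condition(s): %s.", paste(missing_k, collapse = ", ")))
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  k <- unname(k_by_condition[trials$condition])
  mu <- closed_form_retinal_estimate(trials$def_max, k)
  eps <- rnorm(nrow(trials), 0, noise_sd_tan)
  dplyr::mutate(trials, response_tan = pmax(0, mu + eps))
}

#' Generate a full synthetic experiment
#'
#' Runs the three blocks in the experiment's order — AVV, then PVV replaying
#' the AVV def values, then AVP — for `n_subjects` subjects split between the
#' normal and slow velocity regimes, and simulates responses for each block.
#'
#' @inheritParams generate_trials
#' @inheritParams simulate_responses
#' @return A single tibble of all trials with responses.
#' @examples
#' \donttest{
#' experiment <- generate_experiment(n_subjects = 4, seed = 7)
#' dplyr::count(experiment, condition)
#' }
#' @export
generate_experiment <- function(n_subjects = 34, seed = 1,
                                k_by_condition = c(PVV = 1.04, AVV = 1.88, AVP = 2.41),
                                noise_sd_tan = 0.218) {
  avv <- generate_trials("AVV", n_subjects = n_subjects, seed = seed)
  pvv <- generate_trials("PVV",
    n_subjects = n_subjects, seed = seed + 1L,
    replay_from = avv
  )
  avp <- generate_trials("AVP", n_subjects = n_subjects, seed = seed + 2L)
  trials <- dplyr::bind_rows(avv, pvv, avp)
  simulate_responses(trials,
    k_by_condition = k_by_condition,
    noise_sd_tan = noise_sd_tan, seed = seed + 3L
  )
}
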