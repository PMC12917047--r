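#' Simulation presets
#'
#' A `simulation_preset` bundles every generative parameter of the synthetic
#' scenes: fibre drift, the two-population (mobile persistent-random-walk /
#' static jitter) speed mixture, post-mitotic sister dispersal, activation and
#' cell-cycle timing, division-mode and orientation probabilities, MYOG-onset
#' kinetics and the terminal differentiation-index calibration. The `wt` and
#' `mdx` presets encode the published calibration values for wild-type and
#' dystrophic muscle stem cells; parameters the literature does not quantify
#' (persistence, jitter, fibre-drift magnitudes) are generator conventions
#' documented in the methods vignette.
#'
#' @param name preset name.
#' @param dt_min frame interval, minutes.
#' @param duration_h movie duration for lineage scenes, hours.
#' @param track_duration_h movie duration for division-free motility scenes,
#'   hours.
#' @param fibre_rot_sd_deg per-frame SD of the fibre rotation random walk,
#'   degrees.
#' @param fibre_trans_sd_um per-frame SD of the fibre translation random
#'   walk, um (each axis).
#' @param f_mobile mixture weight of the mobile population.
#' @param mobile_speed_mean_um_h mean step speed of mobile cells, um/h
#'   (lognormal mean).
#' @param mobile_speed_sigma_log lognormal sigma of mobile step speeds.
#' @param static_speed_median_um_min median instantaneous speed of static
#'   cells, um/min (sets the positional jitter SD).
#' @param heading_sd_deg per-step SD of the mobile heading random walk,
#'   degrees (directional persistence).
#' @param p_comigrate probability that a sister pair disperses in the same
#'   rather than opposite direction after mitosis.
#' @param dispersal_min duration of the ballistic post-mitotic dispersal
#'   phase, minutes.
#' @param activation_mean_h,activation_sd_h mean/SD of the time to first
#'   division (from observation start), hours.
#' @param cycle_mean_h,cycle_sd_h mean/SD of inter-division intervals
#'   (generations >= 2), hours.
#' @param cycle_slowdown multiplier on the cycle mean for generations >= 2
#'   (dystrophic cells cycle more slowly after the first division).
#' @param p_modes division-mode probabilities, named c(ACD, SCDd, SCDp),
#'   summing to 1.
#' @param p_orientation orientation probabilities, named
#'   c(planar, perpendicular, undetermined), summing to 1.
#' @param myog_onset_mean_h,myog_onset_sd_h delay between mitosis and live
#'   reporter onset, hours.
#' @param p_redivide_positive probability that a MYOG-positive cell performs
#'   one more division.
#' @param diff_index_target calibrated terminal differentiation index
#'   (fraction of surviving cells MYOG-positive at the endpoint); reached by
#'   fusion of excess positive cells into myotubes.
#' @param max_generation cells beyond this generation do not divide again
#'   (lineages are followed for up to five consecutive divisions).
#' @param fibre_length_um,fibre_width_um fibre ellipse axes for landmark and
#'   mask geometry.
#' @param n_landmarks number of fixed landmarks tracked for registration.
#' @param landmark_noise_sd_um isotropic measurement noise on landmark
#'   positions, um.
#' @return object of class `simulation_preset` (a validated named list).
#' @export
simulation_preset <- function(name = "custom",
                              dt_min = 10,
                              duration_h = 72,
                              track_duration_h = 24,
                              fibre_rot_sd_deg = 0.3,
                              fibre_trans_sd_um = 0.5,
                              f_mobile = 0.52,
                              mobile_speed_mean_um_h = 46.4,
                              mobile_speed_sigma_log = 0.35,
                              static_speed_median_um_min = 0.1,
                              heading_sd_deg = 25,
                              p_comigrate = 0.03,
                              dispersal_min = 90,
                              activation_mean_h = 47.3,
                              activation_sd_h = 8,
                              cycle_mean_h = 8.5,
                              cycle_sd_h = 2,
                              cycle_slowdown = 1,
                              p_modes = c(ACD = 0.129, SCDd = 0.325,
                                          SCDp = 0.545),
                              p_orientation = c(planar = 0.68,
                                                perpendicular = 0.189,
                                                undetermined = 0.131),
                              myog_onset_mean_h = 9,
                              myog_onset_sd_h = 1.5,
                              p_redivide_positive = 0.091,
                              diff_index_target = 0.38,
                              max_generation = 6,
                              fibre_length_um = 400,
                              fibre_width_um = 40,
                              n_landmarks = 50,
                              landmark_noise_sd_um = 0.3) {
  preset <- list(
    name = name, dt_min = dt_min, duration_h = duration_h,
    track_duration_h = track_duration_h,
    fibre_rot_sd_deg = fibre_rot_sd_deg,
    fibre_trans_sd_um = fibre_trans_sd_um,
    f_mobile = f_mobile,
    mobile_speed_mean_um_h = mobile_speed_mean_um_h,
    mobile_speed_sigma_log = mobile_speed_sigma_log,
    static_speed_median_um_min = static_speed_median_um_min,
    heading_sd_deg = heading_sd_deg,
    p_comigrate = p_comigrate, dispersal_min = dispersal_min,
    activation_mean_h = activation_mean_h, activation_sd_h = activation_sd_h,
    cycle_mean_h = cycle_mean_h, cycle_sd_h = cycle_sd_h,
    cycle_slowdown = cycle_slowdown,
    p_modes = p_modes, p_orientation = p_orientation,
    myog_onset_mean_h = myog_onset_mean_h, myog_onset_sd_h = myog_onset_sd_h,
    p_redivide_positive = p_redivide_positive,
    diff_index_target = diff_index_target,
    max_generation = max_generation,
    fibre_length_um = fibre_length_um, fibre_width_um = fibre_width_um,
    n_landmarks = n_landmarks,
    landmark_noise_sd_um = landmark_noise_sd_um)
  validate_preset(preset)
  preset$p_modes <- preset$p_modes / sum(preset$p_modes)
  preset$p_orientation <- preset$p_orientation / sum(preset$p_orientation)
  structure(preset, class = "simulation_preset")
}

validate_preset <- function(p) {
  probs <- c(p$f_mobile, p$p_comigrate, p$p_redivide_positive,
             p$diff_index_target, p$p_modes, p$p_orientation)
  if (any(probs < 0 | probs > 1))
    stop("preset probabilities must lie in [0, 1]")
  # published fractions are rounded to 0.1%; accept that rounding slack,
  # then renormalise exactly
  if (abs(sum(p$p_modes) - 1) > 2e-3)
    stop("division-mode probabilities must sum to 1")
  if (!identical(sort(names(p$p_modes)), c("ACD", "SCDd", "SCDp")))
    stop("p_modes must be named ACD, SCDd, SCDp")
  if (abs(sum(p$p_orientation) - 1) > 1e-9)
    stop("orientation probabilities must sum to 1 (within 1e-9)")
  sds <- c(p$fibre_rot_sd_deg, p$fibre_trans_sd_um, p$mobile_speed_sigma_log,
           p$heading_sd_deg, p$activation_sd_h, p$cycle_sd_h,
           p$myog_onset_sd_h, p$landmark_noise_sd_um)
  if (any(sds < 0)) stop("preset SDs must be >= 0")
  if (any(c(p$dt_min, p$duration_h, p$track_duration_h,
            p$mobile_speed_mean_um_h, p$static_speed_median_um_min,
            p$activation_mean_h, p$cycle_mean_h, p$cycle_slowdown) <= 0))
    stop("preset durations, means and slowdown must be > 0")
  invisible(TRUE)
}

#' @rdname simulation_preset
#' @param genotype "wt" or "mdx".
#' @param ... overrides forwarded to [simulation_preset()].
#' @export
muscle_preset <- function(genotype = c("wt", "mdx"), ...) {
  genotype <- match.arg(genotype)
  base <- if (genotype == "wt") list(
    name = "wt",
    f_mobile = 0.52,
    mobile_speed_mean_um_h = 46.4,
    p_comigrate = 0.03,
    cycle_slowdown = 1,
    p_modes = c(ACD = 0.129, SCDd = 0.325, SCDp = 0.545),
    diff_index_target = 0.38
  ) else list(
    name = "mdx",
    f_mobile = 0.19,
    mobile_speed_mean_um_h = 36.4,
    p_comigrate = 0.20,
    cycle_slowdown = 1.3,
    p_modes = c(ACD = 0.144, SCDd = 0.577, SCDp = 0.279),
    diff_index_target = 0.76
  )
  args <- utils::modifyList(base, list(...))
  do.call(simulation_preset, args)
}

#' @export
print.simulation_preset <- function(x, ...) {
  cat("<simulation_preset '", x$name, "'>\n", sep = "")
  cat("  mobile fraction ", x$f_mobile, ", mobile mean speed ",
      x$mobile_speed_mean_um_h, " um/h\n", sep = "")
  cat("  activation ", x$activation_mean_h, " h, cycle ",
      x$cycle_mean_h * x$cycle_slowdown, " h (gen >= 2)\n", sep = "")
  cat("  modes ACD/SCDd/SCDp = ",
      paste(x$p_modes[c("ACD", "SCDd", "SCDp")], collapse = "/"),
      ", terminal differentiation index ", x$diff_index_target, "\n", sep = "")
  invisible(x)
}

# positional jitter SD (um) of static cells: consecutive independent
# Gaussian positions give Rayleigh step lengths with median
# 2 * s * sqrt(ln 2); solve for s from the target median speed
static_jitter_sd_um <- function(preset) {
  preset$static_speed_median_um_min * preset$dt_min / (2 * sqrt(log(2)))
}
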