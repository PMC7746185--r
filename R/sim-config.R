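#' Configuration for the synthetic lateral-balance walker
#'
#' Builds and validates the full parameter set of the synthetic treadmill
#' walker. The walker is a mediolateral inverted pendulum whose stance leg
#' pivots about the stance-foot center of pressure (CoP); at every heel
#' strike the next foot position is chosen by a linear step-to-step
#' controller driven by the CoM state, which is exactly the data-generating
#' process assumed by the foot placement regression model.
#'
#' Belt speed follows the leg-length normalization `1.25 * sqrt(leg_length)`
#' m/s in `"normal"` mode and `0.63 * sqrt(leg_length)` m/s in `"slow"` mode.
#'
#' The `nominal_step_width` is the *target mean* step width: the constant
#' offset fed to the controller is derived internally from the gains and the
#' stance duration so that the deterministic periodic orbit realizes this
#' width (see the methods vignette for the closed-form orbit).
#'
#' @param leg_length leg length (m); sets the pendulum frequency
#'   `omega = sqrt(g / leg_length)` and the belt speed.
#' @param speed_mode `"normal"` or `"slow"`.
#' @param stride_frequency imposed stride frequency (Hz), as set by the
#'   metronome in the emulated protocol.
#' @param n_strides number of analyzable strides to generate (default 200,
#'   the number of consecutive strides entering the analysis). A few extra
#'   warm-up and tail strides are simulated and flagged so that exactly
#'   `n_strides` complete strides survive step extraction.
#' @param k_pos,k_vel controller gains: next foot placement (leg frame,
#'   lateral positive) = offset + `k_pos` * CoM position + `k_vel` * CoM
#'   velocity at the end of swing. `k_pos` is dimensionless, `k_vel` in s.
#' @param nominal_step_width target mean step width (m).
#' @param fp_noise_sd sd of Gaussian motor noise added to each placement (m).
#' @param process_noise_sd sd of white lateral acceleration noise (m/s^2)
#'   perturbing the CoM within stance; this is what makes the CoM state vary
#'   from step to step even when `fp_noise_sd = 0`.
#' @param cop_half_width maximum within-stance mediolateral CoP excursion
#'   about the stance-foot position (m). `0.005` emulates walking on the
#'   1 cm ridge of the ankle-moment-constraining shoe.
#' @param cop_shift_amp amplitude (m) of the open-loop within-stance CoP
#'   profile before clipping to `cop_half_width`.
#' @param condition `"steady"`, `"ankle_constrained"` or `"fp_constrained"`.
#'   The condition label does not silently change other parameters; use
#'   [condition_preset()] to obtain the conventional parameter bundle for a
#'   constraint condition.
#' @param fp_constraint_weight in `fp_constrained` mode, weight `w` in
#'   `[0, 1]` with which the placement tracks the projected target line
#'   instead of the controller output (`w = 0` reduces to steady walking).
#' @param fp_target_noise_sd execution noise (m) on stepping onto the
#'   projected line, active only in `fp_constrained` mode.
#' @param nonstep_damping lateral damping coefficient (1/s) of a
#'   non-stepping control force `-nonstep_damping * v` acting on the CoM,
#'   emulating the hip/ankle/push-off strategies that keep a walker stable
#'   when stepping is constrained. Default 0; the `fp_constrained` preset
#'   enables it, since stepping onto target lines removes most of the
#'   stabilizing placement feedback.
#' @param nonstep_stiffness stiffness (1/s^2) of the same non-stepping
#'   control force, restoring the CoM toward the treadmill midline. Must
#'   exceed `g / leg_length` to be stabilizing on its own; 0 disables it.
#' @param stride_time_jitter_sd sd of Gaussian jitter on individual step
#'   durations (s).
#' @param double_support_fraction fraction of the stride spent in double
#'   support (split equally over the two transfers; default 0.2).
#' @param emg_gain overall synthetic EMG amplitude (a.u.).
#' @param emg_coupling coupling (1/m) between a step's lateral placement
#'   deviation and the preceding swing-phase EMG burst amplitude
#'   (positive for gluteus medius, negative for adductor longus).
#' @param emg_noise_sd additive wide-band EMG noise sd (a.u.).
#' @param body_mass body mass (kg), used for the vertical force channels.
#' @param force_rate,kin_rate,emg_rate sampling rates (Hz) of the force,
#'   kinematic and EMG channels (defaults 200, 50, 2000).
#' @param seed integer seed; identical configurations with identical seeds
#'   reproduce trials bit for bit.
#' @return an object of class `sim_config` (a validated list).
#' @seealso [simulate_trial()], [condition_preset()]
#' @examples
#' cfg <- sim_config(seed = 1, n_strides = 20)
#' cfg$belt_speed
#' @export
sim_config <- function(leg_length = 0.9,
                       speed_mode = c("normal", "slow"),
                       stride_frequency = NULL,
                       n_strides = 200,
                       k_pos = 1.0,
                       k_vel = 0.30,
                       nominal_step_width = 0.12,
                       fp_noise_sd = 0.002,
                       process_noise_sd = 0.08,
                       cop_half_width = 0.03,
                       cop_shift_amp = 0.015,
                       condition = c("steady", "ankle_constrained", "fp_constrained"),
                       fp_constraint_weight = 0.5,
                       fp_target_noise_sd = 0.004,
                       nonstep_damping = 0,
                       nonstep_stiffness = 0,
                       stride_time_jitter_sd = 0.01,
                       double_support_fraction = 0.2,
                       emg_gain = 1.0,
                       emg_coupling = 4,
                       emg_noise_sd = 0.02,
                       body_mass = 70,
                       force_rate = 200,
                       kin_rate = 50,
                       emg_rate = 2000,
                       seed = 1L) {
  speed_mode <- match.arg(speed_mode)
  condition <- match.arg(condition)
  if (is.null(stride_frequency))
    stride_frequency <- if (speed_mode == "normal") 0.90 else 0.72
  for (nm in c("leg_length", "stride_frequency", "n_strides", "k_pos", "k_vel",
               "nominal_step_width", "fp_noise_sd", "process_noise_sd",
               "cop_half_width", "cop_shift_amp", "fp_constraint_weight",
               "fp_target_noise_sd", "nonstep_damping", "nonstep_stiffness",
               "stride_time_jitter_sd",
               "double_support_fraction", "emg_gain", "emg_coupling",
               "emg_noise_sd", "body_mass", "force_rate", "kin_rate",
               "emg_rate")) {
    v <- get(nm)
    if (!is_number(v)) stopf("sim_config: '%s' must be a single finite number", nm)
  }
  if (n_strides < 1) stopf("sim_config: n_strides must be >= 1")
  if (cop_half_width < 0) stopf("sim_config: cop_half_width must be >= 0")
  if (fp_noise_sd < 0 || process_noise_sd < 0 || emg_noise_sd < 0 ||
      fp_target_noise_sd < 0 || stride_time_jitter_sd < 0)
    stopf("sim_config: noise sds must be >= 0")
  if (leg_length <= 0 || stride_frequency <= 0 || body_mass <= 0)
    stopf("sim_config: leg_length, stride_frequency and body_mass must be > 0")
  if (force_rate <= 0 || kin_rate <= 0 || emg_rate <= 0)
    stopf("sim_config: sampling rates must be > 0")
  if (double_support_fraction <= 0 || double_support_fraction >= 0.5)
    stopf("sim_config: double_support_fraction must be in (0, 0.5)")
  if (fp_constraint_weight < 0 || fp_constraint_weight > 1)
    stopf("sim_config: fp_constraint_weight must be in [0, 1]")
  if (nonstep_damping < 0 || nonstep_stiffness < 0)
    stopf("sim_config: nonstep_damping and nonstep_stiffness must be >= 0")

  speed_coef <- if (speed_mode == "normal") 1.25 else 0.63
  cfg <- list(
    leg_length = leg_length, speed_mode = speed_mode,
    belt_speed = speed_coef * sqrt(leg_length),
    stride_frequency = stride_frequency, n_strides = as.integer(n_strides),
    k_pos = k_pos, k_vel = k_vel,
    nominal_step_width = nominal_step_width,
    fp_noise_sd = fp_noise_sd, process_noise_sd = process_noise_sd,
    cop_half_width = cop_half_width, cop_shift_amp = cop_shift_amp,
    condition = condition,
    fp_constraint_weight = fp_constraint_weight,
    fp_target_noise_sd = fp_target_noise_sd,
    nonstep_damping = nonstep_damping,
    nonstep_stiffness = nonstep_stiffness,
    stride_time_jitter_sd = stride_time_jitter_sd,
    double_support_fraction = double_support_fraction,
    emg_gain = emg_gain, emg_coupling = emg_coupling,
    emg_noise_sd = emg_noise_sd,
    body_mass = body_mass,
    force_rate = force_rate, kin_rate = kin_rate, emg_rate = emg_rate,
    seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$condition, "/", x$speed_mode,
      sprintf("(belt %.2f m/s, f %.2f Hz, %d strides, seed %d)\n",
              x$belt_speed, x$stride_frequency, x$n_strides, x$seed))
  cat(sprintf("  controller: k_pos %.3f, k_vel %.3f s, width %.3f m, fp noise %.4f m\n",
              x$k_pos, x$k_vel, x$nominal_step_width, x$fp_noise_sd))
  cat(sprintf("  CoP half-width %.3f m; process noise %.2f m/s^2\n",
              x$cop_half_width, x$process_noise_sd))
  invisible(x)
}

#' Conventional parameter bundles for the experimental conditions
#'
#' Returns a `sim_config` emulating one cell of the 2 (condition) x 2 (speed)
#' design relative to a baseline steady-state configuration:
#'
#' * `ankle_constrained`: CoP half-width shrunk to 0.005 m (the 1 cm ridge)
#'   together with the behavioral compensations observed under this
#'   constraint — a wider target step width (x 1.25) and a higher stride
#'   frequency (x 1.08). The stepping controller itself is unchanged, so the
#'   degree of foot placement control is unchanged by construction.
#' * `fp_constrained`: placement tracks the projected target line; the
#'   tracking weight is higher at slow speed (0.8) than at normal speed
#'   (0.5), reflecting that the projections constrain stepping more
#'   effectively in slow walking.
#' * `steady`: the baseline itself.
#'
#' @param base a `sim_config` for steady walking (condition `"steady"`).
#' @param condition one of `"steady"`, `"ankle_constrained"`,
#'   `"fp_constrained"`.
#' @return a `sim_config`.
#' @export
condition_preset <- function(base, condition = c("steady", "ankle_constrained",
                                                 "fp_constrained")) {
  condition <- match.arg(condition)
  stopifnot(inherits(base, "sim_config"))
  cfg <- unclass(base)
  cfg$condition <- condition
  if (condition == "ankle_constrained") {
    cfg$cop_half_width <- 0.005
    cfg$nominal_step_width <- base$nominal_step_width * 1.25
    cfg$stride_frequency <- base$stride_frequency * 1.08
  } else if (condition == "fp_constrained") {
    cfg$fp_constraint_weight <- if (base$speed_mode == "slow") 0.8 else 0.5
    cfg$nonstep_damping <- 7
    cfg$nonstep_stiffness <- 14
  }
  do.call(sim_config, cfg[setdiff(names(cfg), c("belt_speed"))])
}
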