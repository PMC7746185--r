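#' Analyze one trial end to end
#'
#' Runs the full single-trial pipeline: gait-event detection, step-record
#' extraction, optional EMG features, the foot placement model, the muscle
#' model (when EMG is present) and the condition metrics.
#'
#' @param trial a `trial_timeseries`.
#' @param n_strides number of strides to analyze (default: trial metadata,
#'   else all).
#' @param event_method "force" or "butterfly".
#' @param min_steps minimum steps for the model fits.
#' @param with_emg process EMG if channels are present.
#' @return list with `events`, `records`, `fp_fit`, `muscle_fit` (or
#'   NULL), `metrics`.
#' @export
analyze_trial <- function(trial, n_strides = NULL,
                          event_method = c("force", "butterfly"),
                          min_steps = 50, with_emg = TRUE) {
  event_method <- match.arg(event_method)
  if (is.null(n_strides)) n_strides <- trial$meta$n_strides
  ev <- if (event_method == "force") {
    detect_events_force(trial$forces)
  } else {
    detect_events_butterfly(trial$forces[, c("time", "cop_ml", "cop_ap")])
  }
  rec <- extract_step_records(trial, ev, n_strides = n_strides)
  muscle <- NULL
  if (with_emg && !is.null(trial$emg)) {
    rec <- add_emg_features(rec, extract_emg_features(trial, ev))
    muscle <- fit_muscle_model(rec, min_steps = min_steps)
  }
  list(events = ev, records = rec,
       fp_fit = fit_fp_model(rec, min_steps = min_steps),
       muscle_fit = muscle,
       metrics = condition_metrics(rec))
}

#' Draw a synthetic cohort of participants
#'
#' Samples participant-level parameters (leg length, preferred stride
#' frequencies, controller gains, step width, noise levels) around the
#' package defaults, emulating between-participant variability of a
#' healthy adult cohort.
#'
#' @param n_participants number of participants.
#' @param seed RNG seed for the draws.
#' @return data.frame, one row per participant.
#' @export
draw_participants <- function(n_participants, seed = 1) {
  with_local_seed(seed, {
    data.frame(
      participant = sprintf("P%02d", seq_len(n_participants)),
      leg_length = clip(stats::rnorm(n_participants, 0.90, 0.05), 0.75, 1.05),
      k_pos = clip(stats::rnorm(n_participants, 1.00, 0.05), 0.88, 1.12),
      k_vel = clip(stats::rnorm(n_participants, 0.30, 0.012), 0.27, 0.33),
      nominal_step_width = clip(stats::rnorm(n_participants, 0.12, 0.015),
                                0.08, 0.17),
      f_normal = clip(stats::rnorm(n_participants, 0.90, 0.04), 0.78, 1.02),
      f_slow = clip(stats::rnorm(n_participants, 0.72, 0.03), 0.62, 0.82),
      fp_noise_sd = clip(stats::rnorm(n_participants, 0.002, 0.0004),
                         0.001, 0.004),
      body_mass = clip(stats::rnorm(n_participants, 70, 13), 45, 110))
  })
}

#' Build the sim_config for one participant x condition x speed cell
#'
#' Applies the speed mode (preferred frequency, process noise scaled down
#' at slow speed where accelerations are smaller) and the condition preset
#' of [condition_preset()].
#'
#' @param p one row of [draw_participants()].
#' @param condition condition label.
#' @param speed_mode "normal" or "slow".
#' @param n_strides strides per trial.
#' @param seed trial seed.
#' @return a [sim_config()].
#' @export
participant_config <- function(p, condition, speed_mode, n_strides = 200,
                               seed = 1) {
  base <- sim_config(
    leg_length = p$leg_length, speed_mode = speed_mode,
    stride_frequency = if (speed_mode == "normal") p$f_normal else p$f_slow,
    n_strides = n_strides, k_pos = p$k_pos, k_vel = p$k_vel,
    nominal_step_width = p$nominal_step_width,
    fp_noise_sd = p$fp_noise_sd,
    process_noise_sd = if (speed_mode == "normal") 0.08 else 0.05,
    body_mass = p$body_mass, seed = seed)
  condition_preset(base, condition)
}

#' Simulate and analyze a synthetic cohort
#'
#' One trial per participant x condition x speed cell; trials are
#' simulated with [simulate_trial()] and analyzed with [analyze_trial()].
#' Returns a tidy group table with one row per cell, carrying the Fisher-z
#' degree of control at mid and terminal swing, the muscle-model results
#' (if EMG was generated) and the condition metrics — the input expected
#' by [rm_2x2()].
#'
#' @param participants data.frame from [draw_participants()].
#' @param conditions character vector of condition labels.
#' @param speeds character vector of speed modes.
#' @param n_strides strides per trial.
#' @param seed base seed; each trial's seed is derived deterministically.
#' @param with_emg simulate and analyze EMG channels (slower).
#' @param keep_fits return the per-trial analyses too.
#' @return data.frame (the group table); per-trial analyses in attribute
#'   `"fits"` when `keep_fits = TRUE`.
#' @export
simulate_cohort <- function(participants, conditions = "steady",
                            speeds = "normal", n_strides = 200, seed = 1,
                            with_emg = FALSE, keep_fits = FALSE) {
  rows <- NULL; fits <- list()
  trial_id <- 0L
  for (i in seq_len(nrow(participants))) {
    p <- participants[i, ]
    for (cond in conditions) for (spd in speeds) {
      trial_id <- trial_id + 1L
      cfg <- participant_config(p, cond, spd, n_strides,
                                seed = (seed * 10007L + trial_id * 131L) %% 2000000011L)
      st <- simulate_trial(cfg, with_emg = with_emg)
      an <- analyze_trial(st$trial, n_strides = n_strides,
                          with_emg = with_emg,
                          min_steps = min(50, 2 * n_strides))
      row <- data.frame(
        participant = p$participant, condition = cond, speed = spd,
        r2_mid = an$fp_fit$mid$r2, r2_ts = an$fp_fit$ts$r2,
        z_mid = fisher_transform(an$fp_fit$mid$r2),
        z_ts = fisher_transform(an$fp_fit$ts$r2),
        beta_pos_mid = an$fp_fit$mid$beta_pos,
        beta_vel_mid = an$fp_fit$mid$beta_vel,
        beta_pos_ts = an$fp_fit$ts$beta_pos,
        beta_vel_ts = an$fp_fit$ts$beta_vel,
        true_k_pos = p$k_pos, true_k_vel = p$k_vel,
        mean_step_width = an$metrics$mean_step_width,
        step_width_variability = an$metrics$step_width_variability,
        stride_frequency = an$metrics$stride_frequency)
      if (!is.null(an$muscle_fit)) {
        row$beta_gm <- an$muscle_fit$beta_gm
        row$beta_al <- an$muscle_fit$beta_al
        row$r2_muscle <- an$muscle_fit$r2
        row$z_muscle <- fisher_transform(an$muscle_fit$r2)
      }
      rows <- rbind(rows, row)
      if (keep_fits) fits[[paste(p$participant, cond, spd, sep = "_")]] <- an
    }
  }
  rownames(rows) <- NULL
  if (keep_fits) attr(rows, "fits") <- fits
  rows
}
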