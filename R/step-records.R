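#' Extract per-step outcome and predictor records from a trial
#'
#' Builds one record per step (toe-off to heel strike of the swinging
#' foot), pooling both legs in a common "leg frame" in which lateral is
#' positive, so left and right steps enter the regression models together:
#'
#' * `fp` — mediolateral foot placement / signed step width: the swinging
#'   foot's position at its midstance minus the contralateral (stance)
#'   foot's position at its own midstance.
#' * `fp2` — the swinging foot's position at midstance minus the CoM
#'   position at the step's toe-off (the muscle model's outcome).
#' * `com_pos[i]`, `com_vel[i]`, i = 1..51 — the CoM position (relative to
#'   the stance foot at its midstance) and CoM velocity, time-normalized
#'   over the step window; i = 25 is mid-swing, i = 51 terminal swing.
#'
#' Midstance is the temporal midpoint of a foot's stance phase
#' (configurable via `midstance_frac`); since the foot is stationary during
#' stance the extracted position is insensitive to the exact instant.
#' Kinematic channels (50 Hz) are linearly interpolated onto the event
#' times defined on the force timeline; the forward-difference velocity is
#' interpolated on half-sample-shifted timestamps (its natural centering).
#' Incomplete boundary steps are dropped; when `n_strides` is given, only
#' the final `2 * n_strides` complete steps are kept.
#'
#' @param trial a `trial_timeseries` (from [simulate_trial()] or
#'   [read_trial()]), or any list with a `kinematics` data.frame holding
#'   `time`, `com_ml`, `foot_l_ml`, `foot_r_ml`.
#' @param events a [gait_events()] object on the same time axis.
#' @param com optional replacement CoM series, data.frame `time`, `com_ml`
#'   (e.g. from [compute_com()] on segment data); defaults to the trial's
#'   kinematic CoM channel.
#' @param n_strides keep only the final `n_strides` strides (2 steps each);
#'   `NULL` keeps all complete steps.
#' @param midstance_frac fraction of stance defining midstance (default 0.5).
#' @return object of class `step_records`: list with `steps` (data.frame:
#'   `step`, `leg`, `t_to`, `t_hs`, `fp`, `fp2`, `stride_duration`),
#'   `com_pos` and `com_vel` (matrices, steps x 51).
#' @export
extract_step_records <- function(trial, events, com = NULL, n_strides = NULL,
                                 midstance_frac = 0.5) {
  kin <- trial$kinematics
  stopifnot(is.data.frame(kin),
            all(c("time", "foot_l_ml", "foot_r_ml") %in% names(kin)))
  if (is.null(com)) com <- kin[, c("time", "com_ml")]
  stopifnot(all(c("time", "com_ml") %in% names(com)))
  dt <- stats::median(diff(com$time))
  vel <- com_velocity(com$com_ml, dt = dt)
  nv <- length(vel) - 1L
  vel_t <- com$time[seq_len(nv)] + dt / 2   # forward differences sit mid-interval

  # one-sided terminal-velocity estimate: the CoM acceleration jumps at
  # heel strike when support transfers, so differentiating across t_hs is
  # biased by the new support. A least-squares quartic over the last
  # ~0.22 s of pre-contact CoM samples, evaluated at t_hs, is one-sided,
  # accurate for the smooth swing trajectory and tolerant of within-stance
  # process noise.
  terminal_velocity <- function(t_to, t_hs, span = 0.22, deg = 4L) {
    i <- which(com$time >= max(t_to, t_hs - span) & com$time <= t_hs + 1e-12)
    if (length(i) < deg + 1L) return(NULL)
    tt <- com$time[i] - t_hs
    co <- stats::lm.fit(outer(tt, 0:deg, `^`), com$com_ml[i])$coefficients
    unname(co[2])
  }

  foot_of <- list(L = kin$foot_l_ml, R = kin$foot_r_ml)
  stw_of <- list(L = event_windows(events, "L", "stance"),
                 R = event_windows(events, "R", "stance"))
  midstance_pos <- function(leg, t_ref) {
    # stance window of `leg` containing (or starting at) t_ref
    stw <- stw_of[[leg]]
    row <- which(stw$start <= t_ref + 1e-9 & stw$end >= t_ref - 1e-9)
    if (!length(row)) return(NULL)
    tm <- stw$start[row[1]] + midstance_frac * (stw$end[row[1]] - stw$start[row[1]])
    c(pos = interp_at(kin$time, foot_of[[leg]], tm), t_mid = tm)
  }

  recs <- NULL; cp <- NULL; cv <- NULL
  for (leg in c("L", "R")) {
    other <- if (leg == "R") "L" else "R"
    s_lf <- if (leg == "R") 1 else -1
    steps <- event_windows(events, leg, "step")
    hs_leg <- events$events$time[events$events$leg == leg &
                                   events$events$type == "heel_strike"]
    for (i in seq_len(nrow(steps))) {
      t_to <- steps$start[i]; t_hs <- steps$end[i]
      own <- midstance_pos(leg, t_hs + 1e-6)       # stance begun at this HS
      st_mid <- midstance_pos(other, (t_to + t_hs) / 2)
      if (is.null(own) || is.null(st_mid)) next
      fp <- s_lf * (own["pos"] - st_mid["pos"])
      com_to <- interp_at(com$time, com$com_ml, t_to)
      fp2 <- s_lf * (own["pos"] - com_to)
      pos_i <- s_lf * (normalize_step(com$time, com$com_ml, c(t_to, t_hs)) -
                         st_mid["pos"])
      vel_i <- s_lf * normalize_step(vel_t, vel[seq_len(nv)], c(t_to, t_hs))
      v51 <- terminal_velocity(t_to, t_hs)
      if (!is.null(v51)) vel_i[length(vel_i)] <- s_lf * v51
      prev_hs <- hs_leg[hs_leg < t_hs - 1e-9]
      stride_dur <- if (length(prev_hs)) t_hs - max(prev_hs) else NA_real_
      recs <- rbind(recs, data.frame(leg = leg, t_to = t_to, t_hs = t_hs,
                                     fp = unname(fp), fp2 = unname(fp2),
                                     stride_duration = stride_dur))
      cp <- rbind(cp, pos_i); cv <- rbind(cv, vel_i)
    }
  }
  if (is.null(recs)) stopf("extract_step_records: no complete steps")
  o <- order(recs$t_hs)
  recs <- recs[o, , drop = FALSE]
  cp <- cp[o, , drop = FALSE]; cv <- cv[o, , drop = FALSE]
  if (!is.null(n_strides)) {
    want <- 2L * as.integer(n_strides)
    if (nrow(recs) < want)
      warnf("extract_step_records: only %d complete steps available (%d requested)",
            nrow(recs), want)
    keep <- seq.int(max(1L, nrow(recs) - want + 1L), nrow(recs))
    recs <- recs[keep, , drop = FALSE]
    cp <- cp[keep, , drop = FALSE]; cv <- cv[keep, , drop = FALSE]
  }
  recs$step <- seq_len(nrow(recs))
  rownames(recs) <- rownames(cp) <- rownames(cv) <- NULL
  colnames(cp) <- paste0("com_pos_", seq_len(ncol(cp)))
  colnames(cv) <- paste0("com_vel_", seq_len(ncol(cv)))
  structure(list(steps = recs[, c("step", "leg", "t_to", "t_hs", "fp", "fp2",
                                  "stride_duration")],
                 com_pos = cp, com_vel = cv),
            class = "step_records")
}

#' @export
print.step_records <- function(x, ...) {
  cat("<step_records>", nrow(x$steps), "steps (",
      sum(x$steps$leg == "L"), "L /", sum(x$steps$leg == "R"), "R )\n")
  cat(sprintf("  mean step width %.3f m, sd %.4f m\n",
              mean(abs(x$steps$fp)), stats::sd(x$steps$fp)))
  invisible(x)
}

#' Flatten step records to a tidy table
#'
#' One row per step with the 51 `com_pos_i` and `com_vel_i` predictor
#' columns attached — the on-disk representation used by the pipeline.
#'
#' @param records a `step_records` object.
#' @return data.frame.
#' @export
step_records_table <- function(records) {
  cbind(records$steps, as.data.frame(records$com_pos),
        as.data.frame(records$com_vel))
}

#' Condition-level gait metrics
#'
#' Mean step width (mean absolute foot placement), step-width variability
#' (sd of foot placement) and stride frequency (mean inverse stride
#' duration) — the summary metrics compared across conditions.
#'
#' @param records a `step_records` object (or its `steps` data.frame).
#' @return named list with `mean_step_width` (m), `step_width_variability`
#'   (m), `stride_frequency` (Hz) and `n_steps`.
#' @examples
#' # two steps of widths 0.08 and 0.12 m
#' df <- data.frame(fp = c(0.08, 0.12), stride_duration = c(1.1, 1.1))
#' condition_metrics(df)
#' @export
condition_metrics <- function(records) {
  steps <- if (inherits(records, "step_records")) records$steps else records
  if (is.null(steps) || nrow(steps) < 2)
    stopf("condition_metrics: need at least 2 steps")
  sf <- steps$stride_duration[is.finite(steps$stride_duration)]
  list(mean_step_width = mean(abs(steps$fp)),
       step_width_variability = stats::sd(steps$fp),
       stride_frequency = if (length(sf)) mean(1 / sf) else NA_real_,
       n_steps = nrow(steps))
}

#' Step width estimated from the combined CoP
#'
#' During single support the combined CoP lies under the stance foot, so
#' the mean mediolateral CoP over the middle of each single-support phase
#' estimates that foot's position; the mean absolute difference between
#' consecutive stance estimates is an independent, kinematics-free
#' estimate of mean step width.
#'
#' @param forces data.frame with `time`, `fz_left`, `fz_right`, `cop_ml`.
#' @param events a [gait_events()] object.
#' @param core fraction of each stance's middle used (default 0.5).
#' @return mean step width (m).
#' @export
cop_step_width <- function(forces, events, core = 0.5) {
  est <- NULL
  for (leg in c("L", "R")) {
    stw <- event_windows(events, leg, "stance")
    for (i in seq_len(nrow(stw))) {
      lo <- stw$start[i] + (1 - core) / 2 * (stw$end[i] - stw$start[i])
      hi <- stw$end[i] - (1 - core) / 2 * (stw$end[i] - stw$start[i])
      sel <- forces$time >= lo & forces$time <= hi
      if (!any(sel)) next
      est <- rbind(est, data.frame(t = (lo + hi) / 2,
                                   pos = mean(forces$cop_ml[sel])))
    }
  }
  if (is.null(est) || nrow(est) < 2)
    stopf("cop_step_width: need at least two stance phases")
  est <- est[order(est$t), ]
  mean(abs(diff(est$pos)))
}
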