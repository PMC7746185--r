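#' Closed-form mediolateral inverted-pendulum propagation
#'
#' Propagates the lateral CoM state under the inverted-pendulum equation
#' `x'' = (g / leg_length) * (x - u)` with the support point `u` held fixed,
#' sampling the exact solution
#' `x(t) = u + (x0 - u) cosh(w t) + (v0 / w) sinh(w t)`, `w = sqrt(g / l)`,
#' on a regular grid. This is the elementary propagator the trial simulator
#' applies cell by cell (with `u` piecewise constant), so frozen-support
#' simulation and the analytic solution agree to machine precision.
#'
#' @param x0,v0 initial CoM position (m) and velocity (m/s).
#' @param u support (CoP) position (m), constant.
#' @param leg_length pendulum length (m).
#' @param duration time span (s).
#' @param dt sampling interval (s).
#' @param g gravitational acceleration (m/s^2).
#' @return data.frame with columns `time`, `x`, `v`.
#' @examples
#' integrate_pendulum(0.01, 0, 0, leg_length = 0.9, duration = 0.5)[1:3, ]
#' @export
integrate_pendulum <- function(x0, v0, u, leg_length, duration, dt = 0.005,
                               g = 9.81) {
  stopifnot(leg_length > 0, duration > 0, dt > 0)
  w <- sqrt(g / leg_length)
  t <- seq(0, duration, by = dt)
  z0 <- x0 - u
  data.frame(time = t,
             x = u + z0 * cosh(w * t) + (v0 / w) * sinh(w * t),
             v = z0 * w * sinh(w * t) + v0 * cosh(w * t))
}

# one exact propagation step over dt with constant input (support u, extra
# acceleration eta) for x'' = w^2 (x - u) - c x - d x' + eta; returns
# c(x, v). c = d = 0 reduces to the pure pendulum's cosh/sinh propagation.
# c is the stiffness of a non-stepping restoring force about the treadmill
# midline, d its damping.
pend_step <- function(x, v, u, eta, w, dt, d = 0, c_stiff = 0) {
  w2 <- w * w
  if (d == 0 && c_stiff == 0) {
    ueff <- u + eta / w2
    z <- x - ueff
    ch <- cosh(w * dt); sh <- sinh(w * dt)
    return(c(ueff + z * ch + (v / w) * sh, z * w * sh + v * ch))
  }
  A <- w2 - c_stiff
  if (abs(A) < 0.1)
    stopf("pend_step: non-stepping stiffness too close to the pendulum stiffness g/l")
  xe <- (w2 * u - eta) / A
  z <- x - xe
  disc <- d * d + 4 * A
  if (disc >= 0) {
    s <- sqrt(disc)
    r1 <- (-d + s) / 2; r2 <- (-d - s) / 2
    a <- (v - r2 * z) / (r1 - r2)
    b <- z - a
    e1 <- exp(r1 * dt); e2 <- exp(r2 * dt)
    c(xe + a * e1 + b * e2, a * r1 * e1 + b * r2 * e2)
  } else {
    mu <- -d / 2; wd <- sqrt(-disc) / 2
    S <- (v - mu * z) / wd
    em <- exp(mu * dt); co <- cos(wd * dt); si <- sin(wd * dt)
    c(xe + em * (z * co + S * si),
      em * ((mu * z + S * wd) * co + (mu * S - z * wd) * si))
  }
}

# Event schedule for one trial. Steps alternate R, L, R, ... starting with a
# right heel strike; 3 warm-up strides lead in and 1 tail stride closes the
# trial so that n_strides complete strides survive extraction.
build_schedule <- function(cfg, jitter) {
  T_str <- 1 / cfg$stride_frequency
  h2 <- T_str / 2
  d <- cfg$double_support_fraction * T_str / 2   # one transfer
  n_steps <- 2L * (cfg$n_strides + 4L)
  if (length(jitter) < n_steps) jitter <- rep_len(jitter, n_steps)
  intervals <- pmax(h2 + jitter[seq_len(n_steps)], 0.6 * h2)
  t0 <- 0.45 * T_str
  hs_time <- t0 + cumsum(c(0, intervals[-n_steps]))
  hs_leg <- rep_len(c("R", "L"), n_steps)
  to_time <- hs_time + d                        # contralateral foot lifts
  to_leg <- rep_len(c("L", "R"), n_steps)
  # the right foot is already in swing at t = 0; record its lift-off
  to0 <- max(0.02, hs_time[1] - (h2 - d))
  duration <- hs_time[n_steps] + 0.3 * T_str
  list(hs_time = hs_time, hs_leg = hs_leg,
       to_time = c(to0, to_time), to_leg = c("R", to_leg),
       h2 = h2, d = d, T_str = T_str, n_steps = n_steps,
       duration = duration)
}

# stance intervals (start = heel strike, end = toe-off) for one foot,
# including the virtual initial stance before the first recorded heel strike
stance_intervals <- function(sched, leg) {
  hs <- sched$hs_time[sched$hs_leg == leg]
  to <- sched$to_time[sched$to_leg == leg]
  if (leg == "L") hs <- c(sched$hs_time[1] - sched$h2, hs)  # initial stance
  n <- min(length(hs), length(to[to > hs[1]]))
  to <- to[to > hs[1]]
  data.frame(start = hs[seq_len(n)], end = to[seq_len(n)])
}

# Per-time-point support geometry, independent of the (yet unknown) foot
# positions: load share on the right foot and the clipped open-loop
# within-stance CoP shift of each foot, in absolute coordinates.
support_geometry <- function(t, sched, cfg) {
  n <- length(t)
  j <- findInterval(t, sched$hs_time)            # 0 before first heel strike
  share_R <- ifelse(sched$hs_leg[pmax(j, 1L)] == "R", 1, 0)
  share_R[j == 0L] <- 0                          # initial left single support
  # double-support ramp after each heel strike
  in_ds <- j >= 1L
  tds <- t - sched$hs_time[pmax(j, 1L)]
  ramp <- clip(tds / sched$d, 0, 1)
  new_R <- sched$hs_leg[pmax(j, 1L)] == "R"
  share_R[in_ds & new_R] <- ramp[in_ds & new_R]
  share_R[in_ds & !new_R] <- 1 - ramp[in_ds & !new_R]

  shift_for <- function(leg) {
    iv <- stance_intervals(sched, leg)
    k <- findInterval(t, iv$start)
    phi <- rep(0, n)
    ok <- k >= 1L & t <= iv$end[pmax(k, 1L)]
    kk <- pmax(k, 1L)
    phi[ok] <- (t[ok] - iv$start[kk[ok]]) / (iv$end[kk[ok]] - iv$start[kk[ok]])
    side <- if (leg == "R") 1 else -1
    side * clip(cfg$cop_shift_amp * sin(2 * pi * phi),
                -cfg$cop_half_width, cfg$cop_half_width)
  }
  list(share_R = share_R, shift_L = shift_for("L"), shift_R = shift_for("R"))
}

# Core dynamics pass: exact cell-by-cell propagation plus the step-to-step
# placement controller. Returns the CoM series on the force-rate grid and
# one row per placement.
sim_core <- function(cfg, w0, sched, eta, eps_fp, eps_tg) {
  w <- sqrt(9.81 / cfg$leg_length)
  dtg <- 1 / cfg$force_rate
  n_grid <- floor(sched$duration / dtg) + 1L
  grid <- (seq_len(n_grid) - 1L) * dtg
  nodes <- sort(unique(c(grid, sched$hs_time)))
  mid <- (nodes[-1] + nodes[-length(nodes)]) / 2
  geo <- support_geometry(mid, sched, cfg)
  # dynamics: single-support pendulum, support switching at heel strike;
  # the gradual double-support force transfer lives in the force channels
  stance_R <- {
    j <- findInterval(mid, sched$hs_time)
    out <- sched$hs_leg[pmax(j, 1L)] == "R"
    out[j == 0L] <- FALSE
    out
  }
  eta_cell <- eta[clip(floor(mid / dtg) + 1L, 1L, length(eta))]
  is_grid <- c(TRUE, nodes[-1] %in% grid)
  grid_of_node <- cumsum(is_grid)
  # heel-strike lookup: node index -> step index (0 if none)
  hs_at <- integer(length(nodes))
  hs_at[match(sched$hs_time, nodes)] <- seq_len(sched$n_steps)

  W2 <- cfg$nominal_step_width / 2
  pL <- -W2; pR <- W2
  x <- 0
  v <- -w * tanh(w * sched$h2 / 2) * W2
  com <- numeric(n_grid); com[1] <- x
  pl_time <- numeric(sched$n_steps); pl_leg <- character(sched$n_steps)
  pl_pos <- numeric(sched$n_steps); pl_fp <- numeric(sched$n_steps)
  pl_y <- numeric(sched$n_steps); pl_v <- numeric(sched$n_steps)
  lam <- if (cfg$condition == "fp_constrained") cfg$fp_constraint_weight else 0

  for (k in seq_along(mid)) {
    jhs <- hs_at[k]
    if (jhs > 0L) {                              # heel strike: place the foot
      leg <- sched$hs_leg[jhs]
      s_sw <- if (leg == "R") 1 else -1
      p_st <- if (leg == "R") pL else pR
      y_lf <- s_sw * (x - p_st)
      v_lf <- s_sw * v
      if (abs(y_lf) > 1)
        stopf(paste0("simulate_trial: CoM diverged from the stance foot ",
                     "(|y| = %.2f m) at t = %.2f s; gain combination ",
                     "k_pos = %.3f, k_vel = %.3f is unstable at stride ",
                     "frequency %.3f Hz"),
              abs(y_lf), nodes[k], cfg$k_pos, cfg$k_vel, cfg$stride_frequency)
      fp_ctrl <- w0 + cfg$k_pos * y_lf + cfg$k_vel * v_lf + eps_fp[jhs]
      p_new <- p_st + s_sw * fp_ctrl
      if (lam > 0)                 # target lines fixed in the treadmill frame
        p_new <- (1 - lam) * p_new + lam * (s_sw * W2 + eps_tg[jhs])
      if (leg == "R") pR <- p_new else pL <- p_new
      pl_time[jhs] <- nodes[k]; pl_leg[jhs] <- leg
      pl_pos[jhs] <- p_new
      pl_fp[jhs] <- s_sw * (p_new - p_st)
      pl_y[jhs] <- y_lf; pl_v[jhs] <- v_lf
    }
    u <- if (stance_R[k]) pR + geo$shift_R[k] else pL + geo$shift_L[k]
    st <- pend_step(x, v, u, eta_cell[k], w, nodes[k + 1] - nodes[k],
                    d = cfg$nonstep_damping, c_stiff = cfg$nonstep_stiffness)
    x <- st[1]; v <- st[2]
    if (is_grid[k + 1]) com[grid_of_node[k + 1]] <- x
  }
  list(grid = grid, com = com,
       placements = data.frame(step = seq_len(sched$n_steps), time = pl_time,
                               leg = pl_leg, pos = pl_pos, fp_lf = pl_fp,
                               y_lf = pl_y, v_lf = pl_v))
}

# Solve for the controller offset that realizes the target mean step width:
# the deterministic realized width is affine in the offset, so two noiseless
# probe runs identify it exactly.
calibrate_offset <- function(cfg) {
  w <- sqrt(9.81 / cfg$leg_length)
  probe_cfg <- cfg
  probe_cfg$n_strides <- 8L
  sched <- build_schedule(probe_cfg, 0)
  n_eta <- floor(sched$duration * cfg$force_rate) + 2L
  zero <- numeric(max(n_eta, sched$n_steps))
  kappa <- cfg$k_pos + cfg$k_vel * w * tanh(w * sched$h2 / 2)
  w0a <- cfg$nominal_step_width * (2 - kappa) / 2
  realized <- function(w0) {
    pl <- sim_core(probe_cfg, w0, sched, zero, zero, zero)$placements
    mean(abs(pl$fp_lf[pl$step > 8]))
  }
  r1 <- realized(w0a); r2 <- realized(w0a * 1.2)
  slope <- (r2 - r1) / (0.2 * w0a)
  if (!is.finite(slope) || abs(slope) < 1e-9) return(w0a)
  w0a + (cfg$nominal_step_width - r1) / slope
}

#' Simulate one synthetic walking trial
#'
#' Generates a full multichannel trial — per-belt vertical forces and the
#' combined CoP at the force rate, mediolateral CoM and foot-marker
#' positions at the kinematic rate, and four-channel hip ab-/adductor EMG at
#' the EMG rate — from a lateral inverted-pendulum walker with a known
#' linear step-to-step foot placement controller. All ground truth needed to
#' verify the downstream analysis (controller gains, exact event times, the
#' exact CoM series, per-step placements and imposed EMG burst amplitudes)
#' is returned alongside the channels.
#'
#' Within stance the CoM obeys `x'' = (g/l)(x - u)` where `u` is the loaded
#' feet's weighted CoP: the stance-foot position plus an open-loop
#' within-stance mediolateral CoP excursion clipped to
#' `+/- cop_half_width`. During each double-support interval the load (and
#' with it the combined CoP) transfers linearly between belts, producing the
#' butterfly-shaped combined CoP trace. At every heel strike the new foot
#' position follows the placement controller (see [sim_config()]); in
#' `fp_constrained` mode the placement is pulled toward fixed target lines
#' with weight `fp_constraint_weight`. Gluteus medius (gm) and adductor
#' longus (al) bursts are centered in the 60--80% window of each leg's
#' stride and scale positively (gm) / negatively (al) with the ensuing
#' step's lateral placement deviation.
#'
#' @param config a [sim_config()] object.
#' @param with_emg generate the EMG channels (default `TRUE`; skipping them
#'   speeds up simulations that only exercise the mechanical pipeline).
#' @return a list of class `sim_trial` with elements
#'   \describe{
#'     \item{trial}{class `trial_timeseries`: `forces` (time, fz_left,
#'       fz_right, cop_ml, cop_ap), `kinematics` (time, com_ml, foot_l_ml,
#'       foot_r_ml), `emg` (time, gm_l, gm_r, al_l, al_r or `NULL`), and
#'       `meta` (labels, rates, belt speed, mass).}
#'     \item{truth}{class `sim_truth`: controller gains, exact heel-strike /
#'       toe-off times per leg, the exact 200 Hz CoM series, per-step
#'       placements (absolute and leg frame), per-stride EMG burst
#'       amplitudes, and the calibrated controller offset.}
#'   }
#' @examples
#' st <- simulate_trial(sim_config(n_strides = 10, seed = 3), with_emg = FALSE)
#' head(st$truth$placements)
#' @export
simulate_trial <- function(config, with_emg = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  ratio <- cfg$force_rate / cfg$kin_rate
  if (abs(ratio - round(ratio)) > 1e-9)
    stopf("simulate_trial: force_rate must be an integer multiple of kin_rate")
  ratio <- as.integer(round(ratio))

  w0 <- calibrate_offset(cfg)

  with_local_seed(cfg$seed, {
    sched <- build_schedule(cfg, stats::rnorm(2L * (cfg$n_strides + 4L),
                                              0, cfg$stride_time_jitter_sd))
    n_eta <- floor(sched$duration * cfg$force_rate) + 2L
    eta <- stats::rnorm(n_eta, 0, cfg$process_noise_sd)
    eps_fp <- stats::rnorm(sched$n_steps, 0, cfg$fp_noise_sd)
    eps_tg <- stats::rnorm(sched$n_steps, 0, cfg$fp_target_noise_sd)

    core <- sim_core(cfg, w0, sched, eta, eps_fp, eps_tg)
    forces <- synth_forces(core, sched, cfg)
    kin <- synth_kinematics(core, sched, cfg, ratio)
    dev <- core$placements$fp_lf - mean(core$placements$fp_lf)
    emg <- if (with_emg) synth_emg(core, sched, cfg, dev) else NULL
  })

  trial <- structure(list(
    forces = forces, kinematics = kin,
    emg = if (with_emg) emg$series else NULL,
    meta = list(condition = cfg$condition, speed_mode = cfg$speed_mode,
                belt_speed = cfg$belt_speed, body_mass = cfg$body_mass,
                leg_length = cfg$leg_length,
                force_rate = cfg$force_rate, kin_rate = cfg$kin_rate,
                emg_rate = cfg$emg_rate, seed = cfg$seed,
                n_strides = cfg$n_strides)),
    class = "trial_timeseries")
  truth <- structure(list(
    true_k_pos = cfg$k_pos, true_k_vel = cfg$k_vel,
    controller_offset = w0,
    heel_strike_times = split(sched$hs_time, sched$hs_leg),
    # the prepended lift-off of the initially swinging right foot has no
    # force signature (the foot was never loaded), so it is not ground truth
    toe_off_times = split(sched$to_time[-1], sched$to_leg[-1]),
    com_series = data.frame(time = core$grid, com_ml = core$com),
    placements = core$placements,
    emg_bursts = if (with_emg) emg$bursts else NULL,
    config = cfg), class = "sim_truth")
  structure(list(trial = trial, truth = truth), class = "sim_trial")
}

# per-belt vertical forces and the combined CoP at the force rate
synth_forces <- function(core, sched, cfg) {
  t <- core$grid
  geo <- support_geometry(t, sched, cfg)
  pl <- core$placements
  pos_leg <- function(leg, p0) {
    rows <- pl[pl$leg == leg & pl$time > 0, ]
    idx <- findInterval(t, rows$time)
    c(p0, rows$pos)[idx + 1L]
  }
  W2 <- cfg$nominal_step_width / 2
  pL <- pos_leg("L", -W2); pR <- pos_leg("R", W2)
  fz_total <- cfg$body_mass * 9.81
  fz_r <- geo$share_R * fz_total
  fz_l <- fz_total - fz_r
  cop_ml <- (1 - geo$share_R) * (pL + geo$shift_L) +
    geo$share_R * (pR + geo$shift_R)
  # stylized anteroposterior CoP: each foot lands ahead, is carried back by
  # the belt, and rolls heel-to-toe; weight transfer produces the sawtooth
  step_len <- cfg$belt_speed * sched$h2
  ap_leg <- function(leg) {
    iv <- stance_intervals(sched, leg)
    k <- pmax(findInterval(t, iv$start), 1L)
    tin <- t - iv$start[k]
    phi <- clip(tin / (iv$end[k] - iv$start[k]), 0, 1)
    step_len / 2 - cfg$belt_speed * tin + 0.25 * (phi - 0.5)
  }
  cop_ap <- (1 - geo$share_R) * ap_leg("L") + geo$share_R * ap_leg("R")
  data.frame(time = t, fz_left = fz_l, fz_right = fz_r,
             cop_ml = cop_ml, cop_ap = cop_ap)
}

# CoM decimated to the kinematic rate plus foot markers (held during stance,
# cosine-blended to the new position during swing)
synth_kinematics <- function(core, sched, cfg, ratio) {
  idx <- seq(1L, length(core$grid), by = ratio)
  t <- core$grid[idx]
  pl <- core$placements
  W2 <- cfg$nominal_step_width / 2
  marker <- function(leg, p0) {
    rows <- pl[pl$leg == leg, ]
    pos_at <- c(p0, rows$pos)
    hs_at <- rows$time
    to <- sched$to_time[sched$to_leg == leg]
    out <- numeric(length(t))
    for (i in seq_along(t)) {
      k <- findInterval(t[i], hs_at)          # completed placements
      cur <- pos_at[k + 1L]
      nxt_hs <- if (k < nrow(rows)) hs_at[k + 1L] else Inf
      to_k <- to[to > (if (k >= 1L) hs_at[k] else -Inf) & to <= nxt_hs]
      if (length(to_k) && t[i] >= to_k[1] && is.finite(nxt_hs)) {
        phase <- (t[i] - to_k[1]) / (nxt_hs - to_k[1])
        tgt <- pos_at[k + 2L]
        cur <- cur + (tgt - cur) * (1 - cos(pi * phase)) / 2
      }
      out[i] <- cur
    }
    out
  }
  data.frame(time = t, com_ml = core$com[idx],
             foot_l_ml = marker("L", -W2), foot_r_ml = marker("R", W2))
}

# band-limited carriers amplitude-modulated by swing-phase bursts whose
# height tracks the ensuing step's lateral placement deviation
synth_emg <- function(core, sched, cfg, dev) {
  n <- floor(sched$duration * cfg$emg_rate) + 1L
  t <- (seq_len(n) - 1L) / cfg$emg_rate
  bp <- signal::butter(2, c(50, 150) / (cfg$emg_rate / 2), type = "pass")
  carrier <- function() {
    x <- signal::filtfilt(bp, stats::rnorm(n))
    x / stats::sd(x)
  }
  chans <- list(gm_l = carrier(), gm_r = carrier(),
                al_l = carrier(), al_r = carrier())
  tonic <- 0.05 * cfg$emg_gain
  env <- lapply(chans, function(z) rep(tonic, n))
  pl <- core$placements
  bursts <- NULL
  for (leg in c("L", "R")) {
    rows <- which(pl$leg == leg)
    hs <- pl$time[rows]
    for (k in seq_len(length(hs) - 1L)) {
      dur <- hs[k + 1L] - hs[k]
      ctr <- hs[k] + 0.7 * dur
      sdt <- 0.05 * dur
      d <- dev[rows[k + 1L]]               # ensuing step of this leg
      a_gm <- cfg$emg_gain * max(0.05, 1 + cfg$emg_coupling * d)
      a_al <- cfg$emg_gain * max(0.05, 1 - cfg$emg_coupling * d)
      i0 <- max(1L, floor((ctr - 4 * sdt) * cfg$emg_rate) + 1L)
      i1 <- min(n, ceiling((ctr + 4 * sdt) * cfg$emg_rate) + 1L)
      win <- exp(-0.5 * ((t[i0:i1] - ctr) / sdt)^2)
      gmc <- paste0("gm_", tolower(leg)); alc <- paste0("al_", tolower(leg))
      env[[gmc]][i0:i1] <- env[[gmc]][i0:i1] + a_gm * win
      env[[alc]][i0:i1] <- env[[alc]][i0:i1] + a_al * win
      bursts <- rbind(bursts,
                      data.frame(leg = leg, stride = k, center = ctr,
                                 amp_gm = a_gm, amp_al = a_al, dev = d))
    }
  }
  series <- data.frame(
    time = t,
    gm_l = env$gm_l * chans$gm_l + stats::rnorm(n, 0, cfg$emg_noise_sd),
    gm_r = env$gm_r * chans$gm_r + stats::rnorm(n, 0, cfg$emg_noise_sd),
    al_l = env$al_l * chans$al_l + stats::rnorm(n, 0, cfg$emg_noise_sd),
    al_r = env$al_r * chans$al_r + stats::rnorm(n, 0, cfg$emg_noise_sd))
  list(series = series, bursts = bursts)
}

#' Realized stride frequency from ground-truth events
#'
#' Mean inverse interval between consecutive heel strikes of one leg.
#'
#' @param truth a `sim_truth` object (or any list with
#'   `heel_strike_times`).
#' @param leg `"R"` or `"L"`.
#' @return stride frequency in Hz.
#' @export
realized_stride_frequency <- function(truth, leg = "R") {
  hs <- truth$heel_strike_times[[leg]]
  if (is.null(hs) || length(hs) < 2)
    stopf("realized_stride_frequency: need at least 2 heel strikes on leg %s",
          leg)
  mean(1 / diff(hs))
}
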