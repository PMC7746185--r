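test_that("identical configs and seeds reproduce trials bit for bit; seeds matter", {
  cfg <- sim_config(n_strides = 10, seed = 5)
  a <- simulate_trial(cfg)
  b <- simulate_trial(cfg)
  expect_identical(a, b)

  c2 <- simulate_trial(sim_config(n_strides = 10, seed = 6))
  res_a <- a$truth$placements$fp_lf - mean(a$truth$placements$fp_lf)
  res_c <- c2$truth$placements$fp_lf - mean(c2$truth$placements$fp_lf)
  expect_false(isTRUE(all.equal(res_a, res_c)))
})

test_that("frozen-support CoM follows the hyperbolic closed form", {
  x0 <- 0.013; v0 <- -0.04; u <- -0.02; ell <- 0.88
  out <- integrate_pendulum(x0, v0, u, leg_length = ell, duration = 0.5,
                            dt = 0.005)
  w <- sqrt(9.81 / ell)
  expected <- u + (x0 - u) * cosh(w * out$time) + (v0 / w) * sinh(w * out$time)
  expect_lt(max(abs(out$x - expected)), 1e-6)
  # velocity consistent with the analytic derivative
  expected_v <- (x0 - u) * w * sinh(w * out$time) + v0 * cosh(w * out$time)
  expect_lt(max(abs(out$v - expected_v)), 1e-6)
})

test_that("ankle-constrained CoP stays within the ridge half-width in single support", {
  cfg <- sim_config(n_strides = 20, seed = 3, cop_half_width = 0.005,
                    condition = "ankle_constrained")
  st <- simulate_trial(cfg, with_emg = FALSE)
  f <- st$trial$forces
  kin <- st$trial$kinematics
  total <- f$fz_left + f$fz_right
  for (leg in c("left", "right")) {
    fz <- f[[paste0("fz_", leg)]]
    ss <- fz > 0.999 * total            # single support on this belt
    foot <- approx(kin$time, kin[[paste0("foot_", substr(leg, 1, 1), "_ml")]],
                   f$time[ss], rule = 2)$y
    expect_lte(max(abs(f$cop_ml[ss] - foot)), 0.005 + 1e-9)
  }
})

test_that("per-belt forces conserve load and combined CoP stays between the feet", {
  st <- shared_trial_noemg()
  f <- st$trial$forces
  kin <- st$trial$kinematics
  m <- st$trial$meta$body_mass
  expect_lt(max(abs(f$fz_left + f$fz_right - m * 9.81)), 1e-9)
  expect_true(all(f$fz_left >= 0 & f$fz_right >= 0))
  fl <- approx(kin$time, kin$foot_l_ml, f$time, rule = 2)$y
  fr <- approx(kin$time, kin$foot_r_ml, f$time, rule = 2)$y
  hw <- st$truth$config$cop_half_width
  lo <- pmin(fl, fr) - hw; hi <- pmax(fl, fr) + hw
  expect_true(all(f$cop_ml >= lo - 1e-9 & f$cop_ml <= hi + 1e-9))
})

test_that("realized stride frequency honors the imposed metronome frequency", {
  # evenly spaced heel strikes at 1 Hz
  tr <- list(heel_strike_times = list(R = 0:10))
  expect_equal(realized_stride_frequency(tr, "R"), 1.0)

  cfg <- sim_config(n_strides = 30, seed = 2, stride_frequency = 0.9,
                    fp_noise_sd = 0, process_noise_sd = 0,
                    stride_time_jitter_sd = 0, emg_noise_sd = 0)
  st <- simulate_trial(cfg, with_emg = FALSE)
  expect_equal(realized_stride_frequency(st$truth, "R"), 0.9,
               tolerance = 1e-6 / 0.9)
  expect_equal(realized_stride_frequency(st$truth, "L"), 0.9,
               tolerance = 1e-6 / 0.9)

  expect_error(realized_stride_frequency(list(heel_strike_times = list(R = 1)),
                                         "R"),
               "at least 2")
})

test_that("unstable gain combinations raise a diagnostic naming the gains", {
  cfg <- sim_config(n_strides = 30, seed = 1, k_pos = 2.0, k_vel = 0.1)
  expect_error(simulate_trial(cfg, with_emg = FALSE),
               "k_pos = 2.000, k_vel = 0.100")
})

test_that("increasing placement noise strictly decreases terminal-swing R2", {
  levels <- c(0.001, 0.004, 0.012)
  mean_r2 <- vapply(levels, function(sd_fp) {
    r2 <- vapply(1:20, function(s) {
      cfg <- sim_config(n_strides = 40, seed = 100 + s, fp_noise_sd = sd_fp)
      st <- simulate_trial(cfg, with_emg = FALSE)
      ev <- detect_events_force(st$trial$forces)
      rec <- extract_step_records(st$trial, ev, n_strides = 40)
      fit_fp_model(rec, phases = 51)$ts$r2
    }, numeric(1))
    mean(r2)
  }, numeric(1))
  expect_true(all(diff(mean_r2) < 0))
})

test_that("target-line stepping lowers step-width variability vs steady walking", {
  for (s in c(2, 5)) {
    base <- sim_config(n_strides = 40, seed = s)
    fp <- condition_preset(base, "fp_constrained")
    sw <- function(cfg) {
      st <- simulate_trial(cfg, with_emg = FALSE)
      sd(st$truth$placements$fp_lf[-(1:6)])
    }
    expect_lt(sw(fp), sw(base))
  }
})

test_that("condition presets implement the constraint conventions", {
  base <- sim_config(seed = 1, speed_mode = "slow")
  ank <- condition_preset(base, "ankle_constrained")
  expect_equal(ank$cop_half_width, 0.005)
  expect_gt(ank$nominal_step_width, base$nominal_step_width)
  expect_gt(ank$stride_frequency, base$stride_frequency)
  expect_equal(ank$k_pos, base$k_pos)

  fpc <- condition_preset(base, "fp_constrained")
  expect_equal(fpc$fp_constraint_weight, 0.8)   # stronger binding at slow speed
  expect_gt(fpc$nonstep_damping, 0)
  expect_identical(condition_preset(base, "steady")$condition, "steady")
})

test_that("config validation rejects unphysical parameters", {
  expect_error(sim_config(n_strides = 0), "n_strides")
  expect_error(sim_config(cop_half_width = -1), "cop_half_width")
  expect_error(sim_config(fp_noise_sd = -0.1), "noise")
  expect_error(sim_config(force_rate = -5), "rates")
  # belt speed follows the leg-length normalization
  expect_equal(sim_config(leg_length = 1)$belt_speed, 1.25)
  expect_equal(sim_config(leg_length = 1, speed_mode = "slow")$belt_speed, 0.63)
})
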