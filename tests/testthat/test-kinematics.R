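# toy anthropometry where predicted masses are exactly the intercepts
toy_table <- function(masses, fractions = rep(0.5, length(masses))) {
  anthropometric_table(paste0("s", seq_along(masses)), masses,
                       rep(0, length(masses)), rep(0, length(masses)),
                       fractions)
}

toy_segments <- function(coms, lengths = rep(0.4, length(coms))) {
  # with com_fraction 0.5 and prox == dist, the segment CoM is `coms`
  data.frame(segment = paste0("s", seq_along(coms)), length = lengths,
             circumference = 0.3, prox = coms, dist = coms)
}

test_that("body CoM is the mass-weighted mean of segment CoMs", {
  # equal masses, symmetric segments
  expect_equal(as.numeric(compute_com(toy_segments(c(-0.1, 0.1)),
                                      toy_table(c(5, 5)))), 0)
  # one segment: its own CoM
  expect_equal(as.numeric(compute_com(toy_segments(0.07), toy_table(4))), 0.07)
  # hand-computed: masses 2, 3, 5 kg at 0, 0.1, 0.2 m -> 0.13 m
  expect_equal(as.numeric(compute_com(toy_segments(c(0, 0.1, 0.2)),
                                      toy_table(c(2, 3, 5)))), 0.13)
})

test_that("segment CoM respects the longitudinal fraction and regression mass", {
  tab <- anthropometric_table("shank", intercept = -0.6, coef_length = 6,
                              coef_circumference = 5, com_fraction = 0.42)
  seg <- data.frame(segment = "shank", length = 0.4, circumference = 0.35,
                    prox = 0.0, dist = 1.0)
  out <- compute_com(seg, tab)
  expect_equal(as.numeric(out), 0.42)
  expect_equal(unname(attr(out, "masses")), -0.6 + 6 * 0.4 + 5 * 0.35)
})

test_that("missing table entries and non-positive masses are named", {
  expect_error(compute_com(toy_segments(0), toy_table(c(1, 2))[2, ]), "s1")
  tab <- anthropometric_table("s1", -10, 0, 0, 0.5)
  expect_error(compute_com(toy_segments(0), tab), "non-positive.*s1")
})

test_that("total-mass conservation: concatenating segment sets preserves the CoM", {
  a_seg <- toy_segments(c(-0.2, 0.05)); a_tab <- toy_table(c(2, 7))
  b_seg <- toy_segments(c(0.1, 0.3)); b_tab <- toy_table(c(4, 1))
  b_seg$segment <- c("s3", "s4"); b_tab$segment <- c("s3", "s4")
  all_seg <- rbind(a_seg, b_seg); all_tab <- rbind(a_tab, b_tab)
  com_a <- compute_com(a_seg, a_tab); com_b <- compute_com(b_seg, b_tab)
  m_a <- sum(attr(com_a, "masses")); m_b <- sum(attr(com_b, "masses"))
  pooled <- (m_a * as.numeric(com_a) + m_b * as.numeric(com_b)) / (m_a + m_b)
  expect_equal(as.numeric(compute_com(all_seg, all_tab)), pooled)
})

test_that("com_velocity is the forward difference, length preserved", {
  expect_equal(com_velocity(rep(2, 5), dt = 0.02), rep(0, 5))
  x <- 0.02 * (0:49)
  expect_equal(com_velocity(x, dt = 0.02), rep(1, 50))
  # analytic derivative oracle for a sine, O(dt) bound
  A <- 0.03; f <- 0.9; dt <- 0.02
  t <- seq(0, 2, by = dt)
  v <- com_velocity(A * sin(2 * pi * f * t), dt = dt)
  v_true <- A * 2 * pi * f * cos(2 * pi * f * t)
  bound <- A * (2 * pi * f)^2 * dt        # |x''| * dt
  expect_lt(max(abs(v - v_true)[1:(length(t) - 1)]), bound)
  expect_error(com_velocity(c(1, 2), time = c(0, 0.02, 0.05)), "non-uniform")
  expect_error(com_velocity(1), "2 samples")
})

test_that("extracted foot placement equals truth placements exactly", {
  st <- simulate_trial(sim_config(n_strides = 30, seed = 11), with_emg = FALSE)
  ev <- detect_events_force(st$trial$forces)
  rec <- extract_step_records(st$trial, ev, n_strides = 30)
  pl <- st$truth$placements
  err <- vapply(seq_len(nrow(rec$steps)), function(i) {
    j <- which.min(abs(pl$time - rec$steps$t_hs[i]))
    abs(rec$steps$fp[i] - pl$fp_lf[j])
  }, 0)
  expect_lt(max(err), 1e-6)
  expect_equal(nrow(rec$steps), 60)       # exactly 2 * n_strides complete steps
})

test_that("mirroring the trial (x -> -x) leaves step records unchanged", {
  st <- shared_trial_noemg()
  tr <- st$trial
  mirror <- tr
  mirror$kinematics$com_ml <- -tr$kinematics$com_ml
  mirror$kinematics$foot_l_ml <- -tr$kinematics$foot_r_ml
  mirror$kinematics$foot_r_ml <- -tr$kinematics$foot_l_ml
  mirror$forces$cop_ml <- -tr$forces$cop_ml
  mirror$forces$fz_left <- tr$forces$fz_right
  mirror$forces$fz_right <- tr$forces$fz_left
  ev1 <- detect_events_force(tr$forces)
  ev2 <- detect_events_force(mirror$forces)
  r1 <- extract_step_records(tr, ev1, n_strides = 40)
  r2 <- extract_step_records(mirror, ev2, n_strides = 40)
  # legs are relabeled, but the leg-frame outcomes are identical
  expect_equal(r2$steps$fp, r1$steps$fp, tolerance = 1e-10)
  expect_equal(r2$steps$fp2, r1$steps$fp2, tolerance = 1e-10)
  expect_equal(r2$com_pos, r1$com_pos, tolerance = 1e-10)
  expect_equal(r2$com_vel, r1$com_vel, tolerance = 1e-10)
  expect_equal(r2$steps$leg, ifelse(r1$steps$leg == "L", "R", "L"))
})

test_that("translating all positions shifts the CoM but not FP or FP2", {
  st <- shared_trial_noemg()
  tr <- st$trial
  shift <- 0.42
  tr2 <- tr
  for (col in c("com_ml", "foot_l_ml", "foot_r_ml"))
    tr2$kinematics[[col]] <- tr$kinematics[[col]] + shift
  tr2$forces$cop_ml <- tr$forces$cop_ml + shift
  ev <- detect_events_force(tr$forces)    # forces' fz unchanged by translation
  r1 <- extract_step_records(tr, ev, n_strides = 40)
  r2 <- extract_step_records(tr2, ev, n_strides = 40)
  expect_equal(r2$steps$fp, r1$steps$fp, tolerance = 1e-12)
  expect_equal(r2$steps$fp2, r1$steps$fp2, tolerance = 1e-12)
  expect_equal(r2$com_pos, r1$com_pos, tolerance = 1e-10)
})

test_that("foot placement is insensitive to the exact midstance instant", {
  st <- shared_trial_noemg()
  ev <- detect_events_force(st$trial$forces)
  r45 <- extract_step_records(st$trial, ev, n_strides = 40, midstance_frac = 0.45)
  r55 <- extract_step_records(st$trial, ev, n_strides = 40, midstance_frac = 0.55)
  expect_lt(max(abs(r45$steps$fp - r55$steps$fp)), 1e-9)
})

test_that("condition metrics reproduce closed-form summaries", {
  df <- data.frame(fp = c(0.10, 0.10, 0.10), stride_duration = c(1, 1, 1))
  m <- condition_metrics(df)
  expect_equal(m$mean_step_width, 0.10)
  expect_equal(m$step_width_variability, 0)
  df2 <- data.frame(fp = c(0.08, 0.12), stride_duration = c(1.25, 1.25))
  m2 <- condition_metrics(df2)
  expect_equal(m2$mean_step_width, 0.10)
  expect_equal(m2$step_width_variability, sd(c(0.08, 0.12)))
  expect_equal(round(m2$step_width_variability, 4), 0.0283)
  expect_equal(m2$stride_frequency, 0.8)
  expect_error(condition_metrics(df[0, ]), "at least 2")
})

test_that("marker-based step width matches the CoP-based estimate", {
  st <- shared_trial_noemg()
  ev <- detect_events_force(st$trial$forces)
  rec <- extract_step_records(st$trial, ev, n_strides = 40)
  mw <- condition_metrics(rec)$mean_step_width
  cw <- cop_step_width(st$trial$forces, ev)
  expect_lt(abs(mw - cw) / mw, 0.1)
})
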