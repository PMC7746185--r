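test_that("force detector finds the rise and fall of a square-wave load", {
  t <- seq(0, 2, by = 0.005)
  f <- data.frame(time = t,
                  fz_left = ifelse(t > 0.5 & t <= 1.5, 700, 0),
                  fz_right = 350)
  ev <- detect_events_force(f, threshold = 35, onset_refine = FALSE)
  e <- ev$events[ev$events$leg == "L", ]
  expect_equal(e$type, c("heel_strike", "toe_off"))
  expect_equal(e$time[1], 0.5, tolerance = 0.01)
  expect_equal(e$time[2], 1.5, tolerance = 0.01)
})

test_that("all-zero forces raise a no-events error; a silent belt is named", {
  t <- seq(0, 2, by = 0.005)
  z <- data.frame(time = t, fz_left = 0 * t, fz_right = 0 * t)
  expect_error(detect_events_force(z, threshold = 35), "no gait events")
  one <- data.frame(time = t, fz_left = ifelse(t > 0.5 & t < 1.5, 700, 0),
                    fz_right = 0 * t)
  expect_error(detect_events_force(one, threshold = 35), "right")
})

test_that("force-threshold events match generator truth within a sample", {
  st <- shared_trial_noemg()   # seed 7
  ev <- detect_events_force(st$trial$forces)
  errs <- event_errors_samples(ev, st$truth)
  expect_gt(length(errs), 100)
  expect_lt(max(errs), 1)
})

test_that("butterfly events match truth and the force detector", {
  st <- shared_trial_noemg()
  f <- st$trial$forces
  evb <- detect_events_butterfly(f[, c("time", "cop_ml", "cop_ap")],
                                 f$fz_left + f$fz_right)
  errs <- event_errors_samples(evb, st$truth)
  expect_gte(mean(errs <= 2), 0.99)

  # cross-detector agreement
  evf <- detect_events_force(f)
  for (leg in c("L", "R")) for (ty in c("heel_strike", "toe_off")) {
    tb <- evb$events$time[evb$events$leg == leg & evb$events$type == ty]
    tf <- evf$events$time[evf$events$leg == leg & evf$events$type == ty]
    d <- vapply(tb, function(x) min(abs(tf - x)) * 200, 0)
    expect_lt(max(d), 2 + 1e-9)
  }
})

test_that("standing still yields no butterfly events, with a warning", {
  t <- seq(0, 3, by = 0.005)
  cop <- data.frame(time = t, cop_ml = 0 * t, cop_ap = 0 * t)
  expect_warning(ev <- detect_events_butterfly(cop), "reversal")
  expect_equal(nrow(ev$events), 0)
})

test_that("undefined CoP spans are rejected", {
  t <- seq(0, 1, by = 0.005)
  cop <- data.frame(time = t, cop_ml = sin(t), cop_ap = cos(t))
  expect_error(detect_events_butterfly(cop, total_force = c(0, rep(700, length(t) - 1))),
               "undefined")
})

test_that("time-shifting the signals shifts all events by exactly the offset", {
  st <- shared_trial_noemg()
  f <- st$trial$forces
  ev1 <- detect_events_force(f)
  f2 <- f; f2$time <- f$time + 0.35
  ev2 <- detect_events_force(f2)
  expect_equal(ev2$events$time, ev1$events$time + 0.35, tolerance = 1e-9)
})

test_that("a trial of n strides yields n +/- 1 heel strikes and toe-offs per leg", {
  st <- shared_trial_noemg()     # 40 analyzable strides (+4 warmup/tail)
  ev <- detect_events_force(st$trial$forces)
  n_sim <- 44
  for (leg in c("L", "R")) for (ty in c("heel_strike", "toe_off")) {
    cnt <- sum(ev$events$leg == leg & ev$events$type == ty)
    expect_gte(cnt, n_sim - 1); expect_lte(cnt, n_sim + 1)
  }
})

test_that("normalize_step maps a step window onto 51 phase points", {
  t <- seq(0, 1, by = 0.02)
  ramp <- normalize_step(t, t, c(0, 1))
  expect_equal(ramp, (0:50) / 50)
  expect_equal(normalize_step(t, rep(3.2, length(t)), c(0, 1)), rep(3.2, 51))
  # mid-swing convention: the literal 1-based index 25 of 51, i.e. phase
  # 24/50 - within one phase sample of 50% of the step
  expect_equal(ramp[25], 24 / 50)
  expect_lte(abs(ramp[25] - 0.5), 1 / 50 + 1e-12)
  expect_equal(ramp[51], 1)
})

test_that("normalized output is insensitive to the sampling rate", {
  w <- c(0.2, 0.8)
  f <- function(t) 0.03 * sin(2 * pi * 1.3 * t)
  t50 <- seq(0, 1, by = 0.02); t200 <- seq(0, 1, by = 0.005)
  a <- normalize_step(t50, f(t50), w)
  b <- normalize_step(t200, f(t200), w)
  expect_lt(max(abs(a - b)), 1e-3)
})

test_that("NaNs inside a step window are reported with their span", {
  t <- seq(0, 1, by = 0.02)
  x <- t; x[20:22] <- NA
  expect_error(normalize_step(t, x, c(0, 1)), "NaN")
})

test_that("event containers enforce per-leg alternation", {
  bad <- data.frame(leg = "L", type = c("heel_strike", "heel_strike"),
                    time = c(1, 2), sample = c(200, 400))
  expect_error(gait_events(bad, 200), "non-alternating")
})
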