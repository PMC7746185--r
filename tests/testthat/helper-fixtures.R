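# shared fixtures, built once per test run and cached

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# a mid-size steady trial with EMG, reused by several files
shared_trial <- function() {
  fixture("shared_trial", function() {
    simulate_trial(sim_config(n_strides = 40, seed = 7))
  })
}

# same trial without EMG channels, for mechanical-only tests
shared_trial_noemg <- function() {
  fixture("shared_trial_noemg", function() {
    simulate_trial(sim_config(n_strides = 40, seed = 7), with_emg = FALSE)
  })
}

# gait events detected from the shared trial's forces
shared_events <- function() {
  fixture("shared_events", function() {
    detect_events_force(shared_trial()$trial$forces)
  })
}

# match detected events to ground-truth times; returns errors in samples
event_errors_samples <- function(ev, truth, rate = 200) {
  errs <- c()
  for (leg in c("L", "R")) for (ty in c("heel_strike", "toe_off")) {
    tr <- if (ty == "heel_strike") truth$heel_strike_times[[leg]]
          else truth$toe_off_times[[leg]]
    det <- ev$events$time[ev$events$leg == leg & ev$events$type == ty]
    if (length(det))
      errs <- c(errs, vapply(det, function(x) min(abs(tr - x)) * rate, 0))
  }
  errs
}

# terminal-swing fit straight from a records object (independent of
# fit_fp_model, for cross-checks)
terminal_fit <- function(rec) {
  y <- rec$steps$fp - mean(rec$steps$fp)
  X <- cbind(rec$com_pos[, 51] - mean(rec$com_pos[, 51]),
             rec$com_vel[, 51] - mean(rec$com_vel[, 51]))
  b <- solve(crossprod(X), crossprod(X, y))
  list(beta_pos = b[1], beta_vel = b[2],
       r2 = 1 - sum((y - X %*% b)^2) / sum(y^2))
}
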