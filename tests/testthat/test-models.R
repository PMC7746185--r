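test_that("ols_demeaned solves simple designs exactly", {
  x <- rnorm(30); x <- x - mean(x)
  f <- ols_demeaned(cbind(x = x), x)
  expect_equal(unname(f$betas), 1)
  expect_equal(f$r2, 1)

  # orthogonal columns: multiple-regression betas equal univariate slopes
  set.seed(42)
  a <- rnorm(64); b <- rnorm(64)
  a <- a - mean(a)
  b <- residuals(lm(b ~ a)); b <- b - mean(b)   # orthogonalize
  y <- 2 * a - 3 * b + rnorm(64, 0, 0.1); y <- y - mean(y)
  f2 <- ols_demeaned(cbind(a = a, b = b), y)
  expect_equal(unname(f2$betas["a"]), sum(a * y) / sum(a * a), tolerance = 1e-12)
  expect_equal(unname(f2$betas["b"]), sum(b * y) / sum(b * b), tolerance = 1e-12)
})

test_that("coefficients match the normal-equations oracle over seeded designs", {
  for (s in 1:100) {
    set.seed(s)
    X <- matrix(rnorm(40), 20, 2)
    X <- sweep(X, 2, colMeans(X))
    y <- rnorm(20); y <- y - mean(y)
    f <- ols_demeaned(X, y)
    oracle <- solve(t(X) %*% X, t(X) %*% y)   # direct normal equations
    expect_lt(max(abs(f$betas - oracle)), 1e-10)
  }
})

test_that("ols_demeaned rejects bad inputs informatively", {
  x <- rnorm(10); x <- x - mean(x)
  expect_error(ols_demeaned(cbind(a = x, b = 2 * x), x), "collinear.*b")
  expect_error(ols_demeaned(cbind(x[1:3]), x[1:3] + 10), "demeaned")
  expect_error(ols_demeaned(matrix(rnorm(4), 2, 2), rnorm(2)), "n > p")
})

test_that("R2 equals the squared correlation of fitted and observed", {
  set.seed(3)
  X <- matrix(rnorm(100), 50, 2); X <- sweep(X, 2, colMeans(X))
  y <- X %*% c(1, -0.5) + rnorm(50); y <- as.numeric(y - mean(y))
  f <- ols_demeaned(X, y)
  expect_equal(f$r2, cor(f$fitted, y)^2, tolerance = 1e-12)
})

test_that("noiseless walker: terminal-swing fit returns the controller gains", {
  cfg <- sim_config(n_strides = 50, seed = 4, fp_noise_sd = 0,
                    process_noise_sd = 0)
  st <- simulate_trial(cfg, with_emg = FALSE)
  ev <- detect_events_force(st$trial$forces)
  rec <- extract_step_records(st$trial, ev, n_strides = 50)
  fit <- fit_fp_model(rec)
  expect_gte(fit$ts$r2, 0.999)
  expect_equal(fit$ts$beta_pos, cfg$k_pos, tolerance = 0.01)
  expect_equal(fit$ts$beta_vel, cfg$k_vel, tolerance = 0.01)
  # cross-check against the helper's independent solve
  tf <- terminal_fit(rec)
  expect_equal(fit$ts$beta_pos, tf$beta_pos, tolerance = 1e-10)
  expect_equal(fit$ts$r2, tf$r2, tolerance = 1e-12)
})

test_that("the R2 curve rises toward terminal swing and stays in [0, 1]", {
  st <- shared_trial_noemg()
  ev <- shared_events_noemg <- detect_events_force(st$trial$forces)
  rec <- extract_step_records(st$trial, ev, n_strides = 40)
  fit <- fit_fp_model(rec)
  expect_true(all(fit$by_phase$r2 >= 0 & fit$by_phase$r2 <= 1))
  expect_gt(fit$ts$r2, fit$by_phase$r2[1])
})

test_that("shuffled outcomes fall below the permutation null's 97.5th percentile", {
  st <- shared_trial_noemg()
  ev <- detect_events_force(st$trial$forces)
  rec <- extract_step_records(st$trial, ev, n_strides = 40)
  y <- rec$steps$fp - mean(rec$steps$fp)
  X <- cbind(rec$com_pos[, 51] - mean(rec$com_pos[, 51]),
             rec$com_vel[, 51] - mean(rec$com_vel[, 51]))
  null <- permutation_null_r2(X, y, n_perm = 200, seed = 9)
  crit <- quantile(null, 0.975)
  set.seed(31)
  r2_shuffled <- ols_demeaned(X, sample(y))$r2
  expect_lt(r2_shuffled, crit + 0.05)
  # the real fit is far above the null
  expect_gt(ols_demeaned(X, y)$r2, max(null))
})

test_that("rescaling predictors rescales betas and leaves R2 unchanged", {
  st <- shared_trial_noemg()
  ev <- detect_events_force(st$trial$forces)
  rec <- extract_step_records(st$trial, ev, n_strides = 40)
  fit_m <- fit_fp_model(rec)
  rec_cm <- rec
  rec_cm$com_pos <- rec$com_pos * 100     # meters -> centimeters
  fit_cm <- fit_fp_model(rec_cm)
  expect_equal(fit_cm$ts$beta_pos, fit_m$ts$beta_pos / 100, tolerance = 1e-10)
  expect_equal(fit_cm$ts$beta_vel, fit_m$ts$beta_vel, tolerance = 1e-10)
  expect_equal(fit_cm$by_phase$r2, fit_m$by_phase$r2, tolerance = 1e-12)
})

test_that("appending pure-noise steps does not raise expected R2", {
  set.seed(11)
  deltas <- replicate(20, {
    X <- matrix(rnorm(120), 60, 2); X <- sweep(X, 2, colMeans(X))
    y <- as.numeric(X %*% c(1, 0.5) + rnorm(60, 0, 0.5))
    Xn <- rbind(X, matrix(rnorm(40), 20, 2))
    yn <- c(y, rnorm(20, 0, 1.2))
    Xn <- sweep(Xn, 2, colMeans(Xn)); yn <- yn - mean(yn)
    y <- y - mean(y)
    ols_demeaned(Xn, yn)$r2 - ols_demeaned(X, y)$r2
  })
  expect_lt(mean(deltas), 0)
})

test_that("muscle model recovers the imposed coupling signs", {
  st <- shared_trial()
  ev <- shared_events()
  rec <- extract_step_records(st$trial, ev, n_strides = 40)
  rec <- add_emg_features(rec, extract_emg_features(st$trial, ev))
  fit <- fit_muscle_model(rec)
  expect_gt(fit$beta_gm, 0)
  expect_lt(fit$beta_al, 0)
  expect_true(fit$r2 >= 0 && fit$r2 <= 1)

  # duplicated features are a rank-deficiency error
  rec2 <- rec
  rec2$steps$emg_al_swing <- rec2$steps$emg_gm_swing
  expect_error(fit_muscle_model(rec2), "collinear")
})

test_that("fisher transform follows the multiple-correlation convention", {
  expect_equal(fisher_transform(0), 0)
  expect_equal(fisher_transform(0.64), atanh(0.8))
  expect_equal(round(fisher_transform(0.64), 4), 1.0986)
  expect_equal(fisher_transform(0.5, method = "direct"), atanh(0.5))
  grid <- seq(0, 0.95, by = 0.05)
  expect_true(all(diff(fisher_transform(grid)) > 0))
  expect_error(fisher_transform(1.2), "0, 1")
  expect_warning(fisher_transform(1), "Inf")
})

test_that("fit_fp_model enforces its minimum step count", {
  st <- shared_trial_noemg()
  ev <- detect_events_force(st$trial$forces)
  rec <- extract_step_records(st$trial, ev, n_strides = 10)
  expect_error(fit_fp_model(rec, min_steps = 50), "minimum")
  expect_s3_class(fit_fp_model(rec, min_steps = 10), "fp_model_fit")
})
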