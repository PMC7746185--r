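#' EMG envelope: high-pass, rectify, low-pass
#'
#' The standard surface-EMG conditioning chain: zero-lag high-pass at
#' `hp_cutoff` (removes movement artifact and baseline drift), full-wave
#' rectification, then zero-lag low-pass at `lp_cutoff` (the linear
#' envelope). Both stages are 2nd-order Butterworth filters applied
#' forward and backward ([signal::filtfilt()]), so the envelope has no
#' phase lag; the filter order is configurable.
#'
#' @param raw numeric EMG signal (a.u.).
#' @param rate sampling rate (Hz), >= 200.
#' @param hp_cutoff high-pass cutoff (Hz, default 20).
#' @param lp_cutoff low-pass cutoff (Hz, default 50).
#' @param order Butterworth order per stage (default 2).
#' @return numeric envelope, same length as `raw`.
#' @examples
#' t <- seq(0, 1, by = 1 / 2000)
#' env <- emg_envelope(sin(2 * pi * 100 * t), 2000)
#' mean(env)   # approx 2/pi, the rectified-sine mean
#' @export
emg_envelope <- function(raw, rate, hp_cutoff = 20, lp_cutoff = 50,
                         order = 2) {
  if (rate < 200) stopf("emg_envelope: rate must be >= 200 Hz")
  if (anyNA(raw)) {
    bad <- range(which(is.na(raw)))
    stopf("emg_envelope: NaN values in raw EMG (samples %d-%d)",
          bad[1], bad[2])
  }
  hp <- signal::butter(order, hp_cutoff / (rate / 2), type = "high")
  lp <- signal::butter(order, lp_cutoff / (rate / 2), type = "low")
  x <- signal::filtfilt(hp, raw)
  x <- abs(x)
  signal::filtfilt(lp, x)
}

#' Time-normalize a stride's envelope to 1000 samples
#'
#' @param time sample times of `envelope` (s).
#' @param envelope EMG envelope values.
#' @param window numeric length-2: stride start and end times (s),
#'   conventionally ipsilateral heel strike to heel strike.
#' @param n number of phase samples (default 1000).
#' @return numeric vector of length `n`.
#' @export
normalize_stride_emg <- function(time, envelope, window, n = 1000L) {
  stopifnot(length(window) == 2, window[2] > window[1])
  at <- seq(window[1], window[2], length.out = n)
  interp_at(time, envelope, at)
}

#' Early-swing EMG feature of one stride
#'
#' Median envelope amplitude over the early-swing window — 60--80% of the
#' stride cycle, i.e. samples 601..800 of the 1000-sample normalized
#' stride (phase interval [0.60, 0.80)) — multiplied by the duration of
#' that window in seconds (0.2 x stride duration). Units: a.u. * s.
#'
#' @param stride_envelope_1000 numeric vector of length 1000.
#' @param stride_duration_s stride duration (s).
#' @return scalar feature (a.u. * s).
#' @examples
#' swing_feature(rep(2, 1000), 1.1)   # 2 * 0.2 * 1.1
#' @export
swing_feature <- function(stride_envelope_1000, stride_duration_s) {
  if (length(stride_envelope_1000) != 1000L)
    stopf("swing_feature: expected a 1000-sample normalized stride, got %d",
          length(stride_envelope_1000))
  if (!is_number(stride_duration_s) || stride_duration_s <= 0)
    stopf("swing_feature: stride duration must be > 0")
  stats::median(stride_envelope_1000[601:800]) * 0.2 * stride_duration_s
}

#' Z-normalize features within a participant x trial
#'
#' Demean and divide by the sample standard deviation (n - 1), the
#' normalization applied to FP2 and the EMG swing features before fitting
#' the muscle model.
#'
#' @param x numeric vector, length >= 2.
#' @return numeric vector with mean 0 and sd 1.
#' @examples
#' znorm(c(1, 2, 3))
#' @export
znorm <- function(x) {
  if (length(x) < 2) stopf("znorm: need at least 2 values")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stopf("znorm: degenerate feature (sd = 0)")
  (x - mean(x)) / s
}

#' Per-step early-swing EMG features for a trial
#'
#' Processes the trial's four EMG channels (gluteus medius and adductor
#' longus, both sides) through [emg_envelope()], segments strides per leg
#' (ipsilateral heel strike to heel strike), normalizes each stride to
#' 1000 samples and computes the early-swing features. Each stride's
#' features are keyed by the heel strike that ends it — the ensuing step's
#' placement is the outcome those features predict.
#'
#' @param trial a `trial_timeseries` with an `emg` data.frame (`time`,
#'   `gm_l`, `gm_r`, `al_l`, `al_r`).
#' @param events a [gait_events()] object.
#' @param ... passed to [emg_envelope()].
#' @return data.frame: `leg`, `t_hs` (stride-ending heel strike),
#'   `stride_duration`, `emg_gm_swing`, `emg_al_swing`.
#' @export
extract_emg_features <- function(trial, events, ...) {
  emg <- trial$emg
  if (is.null(emg)) stopf("extract_emg_features: trial has no EMG channels")
  rate <- 1 / stats::median(diff(emg$time))
  env <- list(gm_l = emg_envelope(emg$gm_l, rate, ...),
              gm_r = emg_envelope(emg$gm_r, rate, ...),
              al_l = emg_envelope(emg$al_l, rate, ...),
              al_r = emg_envelope(emg$al_r, rate, ...))
  t0 <- emg$time[1]; dt <- 1 / rate
  out <- NULL
  for (leg in c("L", "R")) {
    gmc <- paste0("gm_", tolower(leg)); alc <- paste0("al_", tolower(leg))
    strides <- event_windows(events, leg, "stride")
    rows <- vector("list", nrow(strides))
    for (i in seq_len(nrow(strides))) {
      w <- c(strides$start[i], strides$end[i])
      dur <- w[2] - w[1]
      # slice the regular-rate envelope around the stride before
      # interpolating: avoids rescanning the full trial per stride
      i0 <- max(1L, floor((w[1] - t0) / dt))
      i1 <- min(nrow(emg), ceiling((w[2] - t0) / dt) + 2L)
      sl <- i0:i1
      gm1000 <- normalize_stride_emg(emg$time[sl], env[[gmc]][sl], w)
      al1000 <- normalize_stride_emg(emg$time[sl], env[[alc]][sl], w)
      rows[[i]] <- data.frame(
        leg = leg, t_hs = w[2], stride_duration = dur,
        emg_gm_swing = swing_feature(gm1000, dur),
        emg_al_swing = swing_feature(al1000, dur))
    }
    out <- rbind(out, do.call(rbind, rows))
  }
  if (is.null(out)) stopf("extract_emg_features: no complete strides")
  out
}

#' Attach EMG swing features to step records
#'
#' Matches each step (by its ending heel strike and leg) to the EMG
#' features of the stride that ends at the same heel strike.
#'
#' @param records a `step_records` object.
#' @param features output of [extract_emg_features()].
#' @param tol matching tolerance on the heel-strike time (s).
#' @return `records` with columns `emg_gm_swing`, `emg_al_swing` added to
#'   `records$steps` (NA where no stride matched).
#' @export
add_emg_features <- function(records, features, tol = 0.05) {
  st <- records$steps
  st$emg_gm_swing <- NA_real_; st$emg_al_swing <- NA_real_
  for (i in seq_len(nrow(st))) {
    cand <- features[features$leg == st$leg[i] &
                       abs(features$t_hs - st$t_hs[i]) < tol, ]
    if (nrow(cand)) {
      j <- which.min(abs(cand$t_hs - st$t_hs[i]))
      st$emg_gm_swing[i] <- cand$emg_gm_swing[j]
      st$emg_al_swing[i] <- cand$emg_al_swing[j]
    }
  }
  records$steps <- st
  records
}
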