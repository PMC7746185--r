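#' Gait events container
#'
#' Heel-strike and toe-off times per leg, detected at the force-plate rate.
#' Events are stored as a tidy table with one row per event; helper
#' accessors derive step windows (toe-off to the same foot's next heel
#' strike), stride windows (heel strike to ipsilateral heel strike) and
#' stance windows (heel strike to the same foot's toe-off).
#'
#' @param events data.frame with columns `leg` ("L"/"R"), `type`
#'   ("heel_strike"/"toe_off"), `time` (s) and `sample` (1-based index at
#'   `rate`).
#' @param rate sampling rate (Hz) the `sample` column refers to.
#' @return object of class `gait_events`.
#' @export
gait_events <- function(events, rate) {
  stopifnot(is.data.frame(events),
            all(c("leg", "type", "time", "sample") %in% names(events)))
  events <- events[order(events$time), , drop = FALSE]
  rownames(events) <- NULL
  for (leg in c("L", "R")) {
    e <- events[events$leg == leg, ]
    if (nrow(e) > 1 && any(diff(e$time) <= 0))
      stopf("gait_events: events of leg %s are not strictly increasing", leg)
    tt <- e$type
    if (length(tt) > 1 && any(tt[-1] == tt[-length(tt)]))
      stopf("gait_events: non-alternating %s events on leg %s",
            tt[which(tt[-1] == tt[-length(tt)])[1]], leg)
  }
  structure(list(events = events, rate = rate), class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  tb <- table(x$events$leg, x$events$type)
  cat("<gait_events> at", x$rate, "Hz\n")
  print(tb)
  invisible(x)
}

#' Step, stride and stance windows from detected events
#'
#' A step runs from a foot's toe-off to that foot's next heel strike (the
#' swing of that foot); a stride from a foot's heel strike to its next heel
#' strike; stance from heel strike to the same foot's toe-off.
#'
#' @param ev a [gait_events()] object.
#' @param leg "L" or "R": the swinging/reference foot.
#' @param what "step", "stride" or "stance".
#' @return data.frame with columns `start`, `end` (s) and `leg`.
#' @export
event_windows <- function(ev, leg, what = c("step", "stride", "stance")) {
  what <- match.arg(what)
  e <- ev$events[ev$events$leg == leg, ]
  hs <- e$time[e$type == "heel_strike"]
  to <- e$time[e$type == "toe_off"]
  out <- switch(what,
    step = {
      pairs <- lapply(to, function(t0) {
        nxt <- hs[hs > t0]
        if (length(nxt)) c(t0, nxt[1]) else NULL
      })
      do.call(rbind, pairs)
    },
    stride = if (length(hs) > 1) cbind(hs[-length(hs)], hs[-1]) else NULL,
    stance = {
      pairs <- lapply(hs, function(t0) {
        nxt <- to[to > t0]
        if (length(nxt)) c(t0, nxt[1]) else NULL
      })
      do.call(rbind, pairs)
    })
  if (is.null(out)) return(data.frame(start = numeric(0), end = numeric(0),
                                      leg = character(0)))
  data.frame(start = out[, 1], end = out[, 2], leg = leg)
}

#' Detect gait events from per-belt vertical forces
#'
#' Heel strike is the upward crossing of a force threshold on a belt's
#' vertical force, toe-off the downward crossing. Crossing times are refined
#' by linear interpolation between the bracketing samples and debounced by a
#' minimum inter-event gap per belt.
#'
#' @param forces data.frame with columns `time`, `fz_left`, `fz_right` (N).
#' @param threshold force threshold in N, or `NULL` to use
#'   `threshold_frac` of the total load (median of `fz_left + fz_right`).
#' @param threshold_frac fraction of body weight used when `threshold` is
#'   `NULL` (default 0.05).
#' @param min_gap minimum time between consecutive events on one belt (s).
#' @param onset_refine extrapolate the local force ramp to zero load, so
#'   the reported time estimates the true contact change rather than the
#'   (slightly later / earlier) threshold crossing. Default `TRUE`.
#' @return a [gait_events()] object (rate inferred from `time`).
#' @examples
#' t <- seq(0, 2, by = 0.005)
#' f <- data.frame(time = t, fz_left = ifelse(t > 0.5 & t < 1.5, 700, 0),
#'                 fz_right = 350)
#' detect_events_force(f, threshold = 35)$events
#' @export
detect_events_force <- function(forces, threshold = NULL,
                                threshold_frac = 0.05, min_gap = 0.2,
                                onset_refine = TRUE) {
  stopifnot(is.data.frame(forces),
            all(c("time", "fz_left", "fz_right") %in% names(forces)))
  t <- forces$time
  rate <- 1 / stats::median(diff(t))
  if (is.null(threshold)) {
    total <- forces$fz_left + forces$fz_right
    threshold <- threshold_frac * stats::median(total)
  }
  if (!is_number(threshold) || threshold <= 0)
    stopf("detect_events_force: threshold must be > 0")
  one_belt <- function(fz, leg) {
    if (all(fz < threshold)) {
      if (all(fz == 0))
        return(NULL)
      stopf("detect_events_force: belt %s never crosses the threshold", leg)
    }
    above <- fz >= threshold
    up <- which(!above[-length(above)] & above[-1])
    down <- which(above[-length(above)] & !above[-1])
    refine <- function(i, rising) {
      f0 <- fz[i]; f1 <- fz[i + 1]
      tc <- t[i] + (threshold - f0) / (f1 - f0) * (t[i + 1] - t[i])
      if (!onset_refine) return(tc)
      # extrapolate the loading/unloading ramp to zero force: the crossing
      # of a finite threshold lags the true contact change by
      # threshold / slope
      slope <- (f1 - f0) / (t[i + 1] - t[i])
      if (abs(slope) < 1e-6) return(tc)
      tc - threshold / slope    # falling slopes project forward
    }
    ev <- rbind(
      if (length(up)) data.frame(leg = leg, type = "heel_strike",
                                 time = vapply(up, refine, 0, TRUE)),
      if (length(down)) data.frame(leg = leg, type = "toe_off",
                                   time = vapply(down, refine, 0, FALSE)))
    if (is.null(ev)) return(NULL)
    ev <- ev[order(ev$time), ]
    # debounce: drop events following their predecessor too closely
    keep <- c(TRUE, diff(ev$time) >= min_gap / 2)
    ev[keep, ]
  }
  silent <- c("left", "right")[c(all(forces$fz_left == 0),
                                 all(forces$fz_right == 0))]
  evs <- rbind(one_belt(forces$fz_left, "L"), one_belt(forces$fz_right, "R"))
  if (is.null(evs) || nrow(evs) == 0) stopf("detect_events_force: no gait events")
  if (length(silent))
    stopf("detect_events_force: belt %s carries no load",
          paste(silent, collapse = ", "))
  evs$sample <- round((evs$time - t[1]) * rate) + 1L
  gait_events(evs, rate)
}

#' Detect gait events from the butterfly pattern of the combined CoP
#'
#' During treadmill walking the combined center of pressure traces a
#' butterfly: in single support it travels backward under the stance foot,
#' and at each weight transfer it sweeps forward and sideways to the newly
#' loaded foot. Heel strikes are therefore detected at local minima of the
#' anteroposterior CoP (onset of the forward transfer sweep) and toe-offs at
#' the subsequent local maxima (end of the sweep); the leg is assigned from
#' the direction of the mediolateral CoP sweep between the two reversals.
#'
#' @param cop data.frame with columns `time`, `cop_ml`, `cop_ap` (m).
#' @param total_force optional vector of total vertical force (N); the CoP
#'   is only defined while it is positive, and undefined spans raise an
#'   error.
#' @param smooth_n width (samples) of the running-mean pre-smoothing.
#' @param prominence minimum anteroposterior prominence (m) of a reversal;
#'   smaller reversals are dropped with a warning.
#' @param min_gap minimum time between consecutive reversals (s).
#' @return a [gait_events()] object.
#' @export
detect_events_butterfly <- function(cop, total_force = NULL, smooth_n = 5,
                                    prominence = 0.05, min_gap = 0.2) {
  stopifnot(is.data.frame(cop),
            all(c("time", "cop_ml", "cop_ap") %in% names(cop)))
  t <- cop$time
  rate <- 1 / stats::median(diff(t))
  if (!is.null(total_force) && any(total_force <= 0))
    stopf("detect_events_butterfly: CoP undefined while total force <= 0 (%d samples)",
          sum(total_force <= 0))
  sm <- function(x) as.numeric(stats::filter(x, rep(1 / smooth_n, smooth_n),
                                             sides = 2))
  ap <- sm(cop$cop_ap); ml <- sm(cop$cop_ml)
  ap[is.na(ap)] <- cop$cop_ap[is.na(ap)]
  ml[is.na(ml)] <- cop$cop_ml[is.na(ml)]
  d <- diff(ap)
  sgn <- sign(d); sgn[sgn == 0] <- 1
  turns <- which(diff(sgn) != 0) + 1L       # local extrema of the AP trace
  if (!length(turns)) {
    warnf("detect_events_butterfly: no CoP reversals found (standing still?)")
    return(gait_events(data.frame(leg = character(0), type = character(0),
                                  time = numeric(0), sample = integer(0)),
                       rate))
  }
  # remove low-prominence wiggles pairwise until all remaining reversals
  # bound an AP travel of at least `prominence`
  dropped <- 0L
  repeat {
    if (length(turns) < 2) break
    trav <- abs(diff(ap[turns]))
    small <- which(trav < prominence)
    if (!length(small)) break
    i <- small[which.min(trav[small])]
    turns <- turns[-c(i, i + 1L)]
    dropped <- dropped + 2L
  }
  if (dropped > 0)
    warnf("detect_events_butterfly: %d low-prominence reversals dropped",
          dropped)
  kind <- ifelse(d[pmax(turns - 1L, 1L)] < 0, "min", "max")
  # refine each reversal on the unsmoothed trace (smoothing an asymmetric
  # vertex biases its location toward the shallow limb)
  raw <- cop$cop_ap
  turns <- vapply(seq_along(turns), function(i) {
    lo <- max(1L, turns[i] - 3L); hi <- min(length(raw), turns[i] + 3L)
    seg <- raw[lo:hi]
    lo - 1L + if (kind[i] == "min") which.min(seg) else which.max(seg)
  }, integer(1))
  # heel strike at AP minima; toe-off at the following AP maximum
  res <- NULL
  for (i in seq_along(turns)) {
    if (kind[i] != "min" || i == length(turns)) next
    j <- i + 1L
    if (kind[j] != "max") next
    if (abs(ap[turns[j]] - ap[turns[i]]) < prominence) next
    sweep_dir <- ml[turns[j]] - ml[turns[i]]
    leg <- if (sweep_dir > 0) "R" else "L"
    other <- if (leg == "R") "L" else "R"
    res <- rbind(res,
                 data.frame(leg = leg, type = "heel_strike", time = t[turns[i]]),
                 data.frame(leg = other, type = "toe_off", time = t[turns[j]]))
  }
  if (is.null(res)) {
    warnf("detect_events_butterfly: no usable reversal pairs")
    return(gait_events(data.frame(leg = character(0), type = character(0),
                                  time = numeric(0), sample = integer(0)),
                       rate))
  }
  res$sample <- round((res$time - t[1]) * rate) + 1L
  gait_events(res, rate)
}

#' Time-normalize a series over a step window to 51 phase samples
#'
#' Linearly interpolates a sampled channel onto 51 equally spaced time
#' points spanning a step (toe-off to heel strike). Phase indices follow the
#' convention i = 1..51 with mid-swing at i = 25 and terminal swing at
#' i = 51.
#'
#' @param time sample times of `series` (s).
#' @param series channel values.
#' @param window numeric length-2: step start and end times (s).
#' @param n number of phase samples (default 51).
#' @return numeric vector of length `n`.
#' @examples
#' normalize_step(seq(0, 1, 0.02), seq(0, 1, 0.02), c(0, 1))[c(1, 25, 51)]
#' @export
normalize_step <- function(time, series, window, n = 51L) {
  stopifnot(length(window) == 2, window[2] > window[1], n >= 2)
  inside <- time >= window[1] & time <= window[2]
  if (sum(inside) < 2 &&
      (window[2] - window[1]) < 2 * stats::median(diff(time)))
    stopf("normalize_step: step window [%.3f, %.3f] shorter than 2 samples",
          window[1], window[2])
  if (anyNA(series[inside])) {
    bad <- range(time[inside][is.na(series[inside])])
    stopf("normalize_step: NaN values inside the step window (%.3f-%.3f s)",
          bad[1], bad[2])
  }
  at <- seq(window[1], window[2], length.out = n)
  interp_at(time, series, at)
}
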