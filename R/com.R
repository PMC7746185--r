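#' Segmental anthropometric table
#'
#' Per-segment regression coefficients used to predict segment mass from
#' the segment's length and circumference, plus the location of the segment
#' CoM as a fraction of the segment's longitudinal axis (from the proximal
#' end). Tables are gender-specific in the source literature; a table is a
#' plain data.frame so study-specific coefficient sets can be supplied.
#'
#' `default_anthropometry()` returns a compact synthetic default covering
#' the major segments with plausible magnitudes; it is a placeholder for a
#' laboratory's own calibrated coefficients, not a published table.
#'
#' @param segment segment name.
#' @param intercept,coef_length,coef_circumference linear-regression
#'   coefficients: `mass = intercept + coef_length * length +
#'   coef_circumference * circumference` (mass kg, lengths m).
#' @param com_fraction segment CoM position as a fraction in `[0, 1]` of
#'   the longitudinal axis.
#' @return data.frame with one row per segment.
#' @export
anthropometric_table <- function(segment, intercept, coef_length,
                                 coef_circumference, com_fraction) {
  tab <- data.frame(segment = as.character(segment),
                    intercept = intercept,
                    coef_length = coef_length,
                    coef_circumference = coef_circumference,
                    com_fraction = com_fraction)
  if (any(tab$com_fraction < 0 | tab$com_fraction > 1))
    stopf("anthropometric_table: com_fraction must lie in [0, 1]")
  tab
}

#' @rdname anthropometric_table
#' @export
default_anthropometry <- function() {
  anthropometric_table(
    segment = c("trunk", "pelvis", "thigh", "shank", "foot",
                "upper_arm", "forearm"),
    intercept = c(-5.0, -2.0, -1.5, -0.6, -0.2, -0.4, -0.2),
    coef_length = c(30, 18, 12, 6, 4, 4, 3),
    coef_circumference = c(25, 20, 10, 5, 2, 3, 2),
    com_fraction = c(0.45, 0.50, 0.43, 0.42, 0.50, 0.44, 0.42))
}

#' Whole-body center of mass from segment kinematics
#'
#' Each segment's mass is predicted by the linear regression in the
#' anthropometric table from its length and circumference; the segment CoM
#' sits at `com_fraction` of the way from the proximal to the distal
#' endpoint; the body CoM is the mass-weighted mean of the segment CoMs.
#'
#' @param segments data.frame with one row per segment and columns
#'   `segment`, `length` (m), `circumference` (m), plus the proximal /
#'   distal endpoint coordinates. Endpoints may be time series: supply
#'   `prox` and `dist` as numeric columns (single axis) or matrices in
#'   list-columns; here the mediolateral axis is the one analyzed, so
#'   numeric columns are the common case.
#' @param anthropometry an [anthropometric_table()].
#' @return if endpoints are scalars, a single CoM coordinate; if they are
#'   matrices (segments x time in `prox`/`dist` attributes), a vector over
#'   time. Masses are attached as attribute `masses`.
#' @examples
#' tab <- anthropometric_table(c("a", "b"), c(0, 0), c(10, 10), c(0, 0),
#'                             c(0.5, 0.5))
#' segs <- data.frame(segment = c("a", "b"), length = c(0.4, 0.4),
#'                    circumference = c(0.3, 0.3),
#'                    prox = c(-0.1, 0.1), dist = c(-0.1, 0.1))
#' compute_com(segs, tab)   # equal masses, symmetric: 0
#' @export
compute_com <- function(segments, anthropometry) {
  stopifnot(is.data.frame(segments),
            all(c("segment", "length", "circumference") %in% names(segments)))
  idx <- match(segments$segment, anthropometry$segment)
  if (anyNA(idx))
    stopf("compute_com: no anthropometric entry for segment(s): %s",
          paste(segments$segment[is.na(idx)], collapse = ", "))
  an <- anthropometry[idx, ]
  mass <- an$intercept + an$coef_length * segments$length +
    an$coef_circumference * segments$circumference
  if (any(mass <= 0))
    stopf("compute_com: non-positive predicted mass for segment(s): %s",
          paste(segments$segment[mass <= 0], collapse = ", "))
  prox <- segments$prox
  dist <- segments$dist
  if (is.list(prox)) prox <- do.call(rbind, prox)
  if (is.list(dist)) dist <- do.call(rbind, dist)
  seg_com <- prox + an$com_fraction * (dist - prox)
  out <- if (is.matrix(seg_com)) {
    as.numeric(crossprod(mass, seg_com)) / sum(mass)
  } else {
    sum(mass * seg_com) / sum(mass)
  }
  attr(out, "masses") <- stats::setNames(mass, segments$segment)
  out
}

#' CoM velocity by forward differences
#'
#' The velocity estimate at sample k is `(x[k+1] - x[k]) / dt`; the last
#' value is repeated so the series keeps its length. Forward differences
#' are centered half a sample late; downstream interpolation onto event
#' times accounts for that half-sample offset.
#'
#' @param com numeric CoM position series (m).
#' @param dt sampling interval (s); alternatively supply `time` to check
#'   uniformity.
#' @param time optional sample times; must be uniform to `tol`.
#' @param tol relative tolerance on timestamp uniformity.
#' @return numeric velocity series (m/s), same length as `com`.
#' @examples
#' com_velocity(c(0, 0.02, 0.04, 0.06), dt = 0.02)
#' @export
com_velocity <- function(com, dt = NULL, time = NULL, tol = 1e-6) {
  if (length(com) < 2) stopf("com_velocity: need at least 2 samples")
  if (is.null(dt)) {
    if (is.null(time)) stopf("com_velocity: supply dt or time")
    d <- diff(time)
    if (max(abs(d - mean(d))) > tol * mean(d))
      stopf("com_velocity: non-uniform timestamps (spread %.3g s)",
            max(abs(d - mean(d))))
    dt <- mean(d)
  }
  v <- diff(com) / dt
  c(v, v[length(v)])
}
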