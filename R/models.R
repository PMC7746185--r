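#' Least squares on demeaned variables
#'
#' Ordinary least squares without an intercept, for variables that have
#' already been demeaned (per participant x condition x trial); demeaning
#' absorbs the intercept, so the centered and uncentered R^2 coincide.
#' Inputs are checked for centering, and rank deficiency is reported with
#' the offending columns.
#'
#' @param X numeric matrix n x p of demeaned predictors.
#' @param y numeric demeaned outcome, length n.
#' @param center_tol tolerance on |mean| relative to the sd for the
#'   demeaning check.
#' @return list with `betas` (length p), `r2`, `residuals`, `fitted`, `n`.
#' @examples
#' x <- scale(rnorm(20), scale = FALSE)
#' ols_demeaned(cbind(x), as.numeric(x))$betas   # exactly 1
#' @export
ols_demeaned <- function(X, y, center_tol = 1e-8) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stopf("ols_demeaned: X and y sizes differ")
  if (n <= p) stopf("ols_demeaned: need n > p (n = %d, p = %d)", n, p)
  scl <- pmax(apply(X, 2, stats::sd), 1e-12)
  if (any(abs(colMeans(X)) > center_tol * pmax(scl, 1)) ||
      abs(mean(y)) > center_tol * max(stats::sd(y), 1))
    stopf("ols_demeaned: variables must be demeaned first")
  qr_x <- qr(X)
  if (qr_x$rank < p) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):p]]
    if (is.null(dropped)) dropped <- qr_x$pivot[(qr_x$rank + 1):p]
    stopf("ols_demeaned: design is rank deficient (collinear columns: %s)",
          paste(dropped, collapse = ", "))
  }
  betas <- qr.coef(qr_x, y)
  fitted <- drop(X %*% betas)
  res <- y - fitted
  sst <- sum(y^2)                     # y demeaned: TSS about zero
  r2 <- if (sst > 0) 1 - sum(res^2) / sst else NA_real_
  list(betas = betas, r2 = r2, residuals = res, fitted = fitted, n = n)
}

#' Fit the foot placement model across swing phases
#'
#' For each phase i = 1..51 of the normalized step, regresses the demeaned
#' foot placement FP on the demeaned CoM position and CoM velocity at that
#' phase, across steps:
#' `FP = beta_pos * CoM_pos(i) + beta_vel * CoM_vel(i) + error(i)`.
#' The relative explained variance R^2(i) is the degree of foot placement
#' control at phase i; mid-swing (i = 25) and terminal swing (i = 51) are
#' the phases tested statistically.
#'
#' @param records a `step_records` object (see [extract_step_records()]).
#' @param phases integer vector of phases to fit (default all 51).
#' @param min_steps minimum number of steps required (default 50).
#' @return object of class `fp_model_fit`: data.frame `by_phase` with
#'   columns `phase`, `beta_pos`, `beta_vel`, `r2`, plus `n_steps` and the
#'   `mid`/`ts` rows for convenience.
#' @export
fit_fp_model <- function(records, phases = 1:51, min_steps = 50) {
  st <- records$steps
  n <- nrow(st)
  if (n < min_steps)
    stopf("fit_fp_model: %d steps < required minimum %d", n, min_steps)
  y <- st$fp - mean(st$fp)
  out <- data.frame(phase = phases, beta_pos = NA_real_,
                    beta_vel = NA_real_, r2 = NA_real_)
  degenerate <- integer(0)
  for (k in seq_along(phases)) {
    i <- phases[k]
    X <- cbind(pos = records$com_pos[, i] - mean(records$com_pos[, i]),
               vel = records$com_vel[, i] - mean(records$com_vel[, i]))
    f <- tryCatch(ols_demeaned(X, y), error = function(e) NULL)
    if (is.null(f)) { degenerate <- c(degenerate, i); next }
    out$beta_pos[k] <- f$betas["pos"]
    out$beta_vel[k] <- f$betas["vel"]
    out$r2[k] <- f$r2
  }
  if (length(degenerate))
    warnf("fit_fp_model: degenerate predictors at phase(s) %s",
          paste(degenerate, collapse = ", "))
  structure(list(by_phase = out, n_steps = n,
                 mid = out[out$phase == 25, ],
                 ts = out[out$phase == 51, ]),
            class = "fp_model_fit")
}

#' @export
print.fp_model_fit <- function(x, ...) {
  cat("<fp_model_fit>", x$n_steps, "steps\n")
  if (nrow(x$mid))
    cat(sprintf("  mid-swing (i=25): beta_pos %.3f, beta_vel %.3f, R2 %.3f\n",
                x$mid$beta_pos, x$mid$beta_vel, x$mid$r2))
  if (nrow(x$ts))
    cat(sprintf("  terminal (i=51):  beta_pos %.3f, beta_vel %.3f, R2 %.3f\n",
                x$ts$beta_pos, x$ts$beta_vel, x$ts$r2))
  invisible(x)
}

#' Fit the muscle model
#'
#' Regresses the z-normalized foot placement relative to the CoM at
#' toe-off (FP2) on the z-normalized early-swing gluteus medius and
#' adductor longus features:
#' `FP2 = beta_gm * EMG_gm_swing + beta_al * EMG_al_swing + error`.
#' Standardized coefficients; R^2 is the active contribution to
#' step-by-step foot placement variability.
#'
#' @param records a `step_records` object with EMG features attached
#'   (see [add_emg_features()]).
#' @param min_steps minimum number of complete steps (default 50).
#' @return object of class `muscle_model_fit`: list with `beta_gm`,
#'   `beta_al`, `r2`, `n_steps`.
#' @export
fit_muscle_model <- function(records, min_steps = 50) {
  st <- records$steps
  need <- c("emg_gm_swing", "emg_al_swing")
  if (!all(need %in% names(st)))
    stopf("fit_muscle_model: EMG swing features missing; run add_emg_features()")
  ok <- stats::complete.cases(st[, c("fp2", need)])
  st <- st[ok, ]
  if (nrow(st) < min_steps)
    stopf("fit_muscle_model: %d usable steps < required minimum %d",
          nrow(st), min_steps)
  y <- znorm(st$fp2)
  X <- cbind(gm = znorm(st$emg_gm_swing), al = znorm(st$emg_al_swing))
  f <- ols_demeaned(X, y)
  structure(list(beta_gm = unname(f$betas["gm"]),
                 beta_al = unname(f$betas["al"]),
                 r2 = f$r2, n_steps = nrow(st)),
            class = "muscle_model_fit")
}

#' @export
print.muscle_model_fit <- function(x, ...) {
  cat(sprintf("<muscle_model_fit> %d steps: beta_gm %.3f, beta_al %.3f, R2 %.4f\n",
              x$n_steps, x$beta_gm, x$beta_al, x$r2))
  invisible(x)
}

#' Fisher transformation of an R-squared value
#'
#' Variance-stabilizing transform applied to R^2 before group statistics.
#' Two conventions are offered: `"sqrt"` (the default) applies atanh to
#' the multiple correlation `sqrt(R^2)`, i.e. the classical Fisher z of a
#' correlation coefficient; `"direct"` applies atanh to R^2 itself.
#'
#' @param r2 numeric in `[0, 1)`; exactly 1 is flagged as infinite.
#' @param method `"sqrt"` or `"direct"`.
#' @return transformed value(s).
#' @examples
#' fisher_transform(0.64)          # atanh(0.8)
#' @export
fisher_transform <- function(r2, method = c("sqrt", "direct")) {
  method <- match.arg(method)
  if (any(r2 < 0 | r2 > 1, na.rm = TRUE))
    stopf("fisher_transform: r2 must lie in [0, 1]")
  if (any(r2 == 1, na.rm = TRUE))
    warnf("fisher_transform: r2 = 1 maps to +Inf")
  if (method == "sqrt") atanh(sqrt(r2)) else atanh(r2)
}

#' Permutation null for the R-squared of a regression
#'
#' Shuffles the outcome across steps `n_perm` times and refits, giving the
#' null distribution of R^2 when the outcome is unrelated to the
#' predictors; used to judge whether an observed R^2 exceeds chance.
#'
#' @param X demeaned predictor matrix.
#' @param y demeaned outcome.
#' @param n_perm number of permutations (default 200).
#' @param seed RNG seed.
#' @return numeric vector of `n_perm` null R^2 values.
#' @export
permutation_null_r2 <- function(X, y, n_perm = 200, seed = 1) {
  X <- as.matrix(X)
  with_local_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      ols_demeaned(X, sample(y))$r2
    }, numeric(1))
  })
}
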