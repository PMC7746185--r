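#' One-sample t-test with optional JZS Bayes factor
#'
#' Classical one-sample t-test against zero plus, optionally, the
#' Jeffreys--Zellner--Siow Bayes factor BF10 with a Cauchy prior of scale
#' `rscale` on the standardized effect (default `sqrt(2)/2`, the common
#' default of Bayesian t-test software), computed by adaptive quadrature
#' of the marginal likelihood.
#'
#' @param values numeric vector, n >= 3.
#' @param alternative "two.sided", "greater" or "less".
#' @param bf compute BF10 (default TRUE).
#' @param rscale Cauchy prior scale.
#' @return list with `t`, `df`, `p`, `mean`, `n` and (if requested)
#'   `bf10`.
#' @examples
#' one_sample_test(c(0.8, 1.1, 0.9, 1.2, 1.0))
#' @export
one_sample_test <- function(values, alternative = "two.sided", bf = TRUE,
                            rscale = sqrt(2) / 2) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3) stopf("one_sample_test: need at least 3 finite values")
  if (stats::sd(values) == 0)
    stopf("one_sample_test: zero variance")
  tt <- stats::t.test(values, mu = 0, alternative = alternative)
  out <- list(t = unname(tt$statistic), df = unname(tt$parameter),
              p = tt$p.value, mean = mean(values), n = n)
  if (bf) out$bf10 <- bf10_jzs(out$t, n, rscale = rscale)
  out
}

#' JZS Bayes factor for a one-sample t statistic
#'
#' Marginal-likelihood ratio of the alternative (Cauchy prior with scale
#' `rscale` on the standardized effect size) against the point null,
#' following the standard JZS formulation; the prior on the effect is
#' integrated out numerically.
#'
#' @param t observed t statistic.
#' @param n sample size.
#' @param rscale Cauchy prior scale (default `sqrt(2)/2`).
#' @param rel.tol quadrature tolerance passed to [stats::integrate()].
#' @return BF10 (evidence for the alternative over the null).
#' @export
bf10_jzs <- function(t, n, rscale = sqrt(2) / 2, rel.tol = 1e-10) {
  stopifnot(n >= 2, rscale > 0)
  nu <- n - 1
  like <- function(g) {
    a <- 1 + n * g * rscale^2
    a^(-0.5) * (1 + t^2 / (a * nu))^(-(nu + 1) / 2) *
      (2 * pi)^(-0.5) * g^(-1.5) * exp(-1 / (2 * g))
  }
  num <- stats::integrate(like, 0, Inf, rel.tol = rel.tol)$value
  den <- (1 + t^2 / nu)^(-(nu + 1) / 2)
  num / den
}

#' Repeated-measures 2 x 2 decomposition (condition x speed)
#'
#' Frequentist analysis of a complete 2 x 2 within-participant design via
#' difference contrasts: each participant contributes one value per cell,
#' and the two main effects and the interaction are each reduced to one
#' within-participant contrast tested against zero with a paired
#' (one-sample) t-test. Planned post-hoc comparisons of constrained vs
#' steady are run per speed, one-tailed where the hypothesis under test is
#' directional.
#'
#' Contrast conventions: the condition effect is `condition_b - condition_a`
#' averaged over speeds; the speed effect is `speed_b - speed_a` averaged
#' over conditions; the interaction is the condition effect at `speed_b`
#' minus the condition effect at `speed_a`.
#'
#' @param data data.frame with columns `participant`, `condition`,
#'   `speed`, and the outcome named by `outcome`.
#' @param outcome name of the outcome column.
#' @param condition_levels length-2 character: reference (steady) level
#'   first, constrained level second.
#' @param speed_levels length-2 character: reference speed first.
#' @param posthoc_alternative alternative hypothesis for the per-speed
#'   post-hoc tests ("two.sided", "greater", "less"), stated for the
#'   contrast `constrained - steady`.
#' @param bf also report JZS Bayes factors.
#' @return object of class `rm22`: list of test results (`condition`,
#'   `speed`, `interaction`, `posthoc` per speed) plus cell means.
#' @export
rm_2x2 <- function(data, outcome, condition_levels, speed_levels,
                   posthoc_alternative = "two.sided", bf = FALSE) {
  need <- c("participant", "condition", "speed", outcome)
  if (!all(need %in% names(data)))
    stopf("rm_2x2: missing columns: %s",
          paste(setdiff(need, names(data)), collapse = ", "))
  d <- data[data$condition %in% condition_levels &
              data$speed %in% speed_levels, need]
  # build the four cells explicitly
  cell <- function(cond, spd) {
    x <- d[d$condition == cond & d$speed == spd, ]
    stats::setNames(x[[outcome]], x$participant)
  }
  c00 <- cell(condition_levels[1], speed_levels[1])
  c01 <- cell(condition_levels[1], speed_levels[2])
  c10 <- cell(condition_levels[2], speed_levels[1])
  c11 <- cell(condition_levels[2], speed_levels[2])
  ids <- Reduce(intersect, lapply(list(c00, c01, c10, c11), names))
  missing_ids <- setdiff(unique(as.character(d$participant)), ids)
  if (length(missing_ids))
    stopf("rm_2x2: incomplete cells for participant(s): %s",
          paste(missing_ids, collapse = ", "))
  if (length(ids) < 3) stopf("rm_2x2: need at least 3 complete participants")
  c00 <- c00[ids]; c01 <- c01[ids]; c10 <- c10[ids]; c11 <- c11[ids]
  cond_eff <- ((c10 - c00) + (c11 - c01)) / 2
  speed_eff <- ((c01 - c00) + (c11 - c10)) / 2
  inter <- (c11 - c01) - (c10 - c00)
  res <- list(
    condition = one_sample_test(cond_eff, bf = bf),
    speed = one_sample_test(speed_eff, bf = bf),
    interaction = one_sample_test(inter, bf = bf),
    posthoc = list())
  for (i in 1:2) {
    diff_i <- (if (i == 1) c10 - c00 else c11 - c01)
    res$posthoc[[speed_levels[i]]] <-
      one_sample_test(diff_i, alternative = posthoc_alternative, bf = bf)
  }
  res$cells <- data.frame(
    condition = rep(condition_levels, each = 2),
    speed = rep(speed_levels, 2),
    mean = c(mean(c00), mean(c01), mean(c10), mean(c11)),
    sd = c(stats::sd(c00), stats::sd(c01), stats::sd(c10), stats::sd(c11)))
  res$n <- length(ids)
  res$outcome <- outcome
  class(res) <- "rm22"
  res
}

#' @export
print.rm22 <- function(x, ...) {
  cat("<rm_2x2>", x$outcome, "-", x$n, "participants\n")
  fmt <- function(nm, r)
    cat(sprintf("  %-12s t(%d) = %6.2f, p = %.4g%s\n", nm, r$df, r$t, r$p,
                if (!is.null(r$bf10)) sprintf(", BF10 = %.3g", r$bf10) else ""))
  fmt("condition", x$condition); fmt("speed", x$speed)
  fmt("interaction", x$interaction)
  for (nm in names(x$posthoc)) fmt(paste0("posthoc@", nm), x$posthoc[[nm]])
  invisible(x)
}
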