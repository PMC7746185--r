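clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# run code with a temporary RNG state so seeded generators do not
# disturb the caller's random stream
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Linear interpolation of a sampled channel at arbitrary times
#'
#' Thin wrapper around [stats::approx()] with rule = 2 (constant
#' extrapolation at the ends), used to map 50 Hz kinematic channels onto
#' event times defined on the 200 Hz force timeline.
#'
#' @param time sample times (s), strictly increasing.
#' @param x channel values.
#' @param at times to interpolate at (s).
#' @return numeric vector of interpolated values.
#' @keywords internal
interp_at <- function(time, x, at) {
  stats::approx(time, x, xout = at, rule = 2)$y
}
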