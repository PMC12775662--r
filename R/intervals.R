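#' Number of interval draws needed to cover the horizon
#'
#' A horizon of `horizon_L` years contains on average `horizon_L / theta`
#' use intervals; drawing twice that many, `ceiling(2 * horizon_L / theta)`,
#' makes the cumulative time exceed the horizon in all but pathological
#' draws (the samplers extend the sequence if it does not).
#'
#' @param horizon_L Modelled time horizon, years (> 0).
#' @param theta Mean use interval, years (> 0).
#' @return Integer draw count, >= 1.
#' @examples
#' required_draw_count(1000, 20) # 100
#' required_draw_count(1000, 3)  # 667
#' @export
required_draw_count <- function(horizon_L, theta) {
  stop_unless(is_scalar_num(horizon_L) && horizon_L > 0, "`horizon_L` must be > 0")
  stop_unless(is_scalar_num(theta) && theta > 0, "`theta` must be > 0")
  max(1L, as.integer(ceiling(2 * horizon_L / theta)))
}

#' Sample use intervals from a positive-truncated normal distribution
#'
#' Draws independent intervals between successive uses of the skill from
#' `Normal(theta, (nu * theta)^2)` conditioned on being strictly positive.
#' Positivity is enforced by rejection (negative or zero draws are redrawn),
#' which realises the truncated law exactly; clipping would pile probability
#' mass at short intervals. With `nu = 0` every interval equals `theta`.
#'
#' @param theta Mean use interval, years (> 0).
#' @param nu Variability: interval standard deviation is `nu * theta` (>= 0).
#' @param count Number of intervals to draw (>= 1).
#' @param seed Optional integer seed giving a dedicated, reproducible random
#'   stream; `NULL` (default) draws from the current RNG state.
#' @return An `interval_sequence`: list with elements `intervals` (numeric
#'   vector, all > 0), `theta`, `nu` and `stream_id` (the seed or `NA`).
#' @examples
#' s <- sample_intervals(theta = 4, nu = 0.5, count = 10, seed = 42)
#' s$intervals
#' @export
sample_intervals <- function(theta, nu, count, seed = NULL) {
  stop_unless(is_scalar_num(theta) && theta > 0, "`theta` must be > 0")
  stop_unless(is_scalar_num(nu) && nu >= 0, "`nu` must be >= 0")
  stop_unless(is_scalar_num(count) && count >= 1, "`count` must be >= 1")
  draws <- with_seed(seed, draw_positive_normal(as.integer(count), theta, nu * theta))
  structure(
    list(intervals = draws, theta = theta, nu = nu,
         stream_id = if (is.null(seed)) NA_integer_ else as.integer(seed)),
    class = "interval_sequence"
  )
}

#' @export
print.interval_sequence <- function(x, ...) {
  cat(sprintf("interval_sequence: %d draws from positive Normal(%g, (%g*%g)^2)\n",
              length(x$intervals), x$theta, x$nu, x$theta))
  print(utils::head(x$intervals, 10))
  if (length(x$intervals) > 10) cat("...\n")
  invisible(x)
}

# Vectorised rejection sampler for N(mean, sd^2) truncated to (0, Inf).
# Acceptance probability is 1 - pnorm(0, mean, sd) >= 1/2 whenever mean > 0,
# so the redraw loop terminates quickly even at large nu.
draw_positive_normal <- function(n, mean, sd) {
  if (sd == 0) return(rep.int(mean, n))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out <= 0)
  while (length(bad) > 0L) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= 0]
  }
  out
}
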