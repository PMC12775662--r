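#' Probability that a single interval exceeds the maximum time
#'
#' Closed-form per-interval discontinuity probability: the upper-tail mass
#' of `Normal(theta, (nu * theta)^2)` beyond the maximum unused-retention
#' time, `0.5 * (1 - erf((dt_max - theta) / (theta * nu * sqrt(2))))`,
#' evaluated with [stats::pnorm()]. By default the *untruncated* tail is
#' used, matching the definition of the closed form; setting
#' `truncation_corrected = TRUE` renormalises by the positive-support mass
#' `P(X > 0)` for sensitivity analysis against the simulator, which samples
#' the truncated law.
#'
#' At `nu = 0` the distribution is degenerate at `theta` and the limit is a
#' step: 0 if `theta <= dt_max`, 1 otherwise.
#'
#' @param theta Mean use interval, years (> 0). Vectorised.
#' @param nu Variability (>= 0). Vectorised with `theta`.
#' @param tau Forgetting time, years (> 0).
#' @param eta_max Maximum number of experts (>= 1).
#' @param retention_threshold Minimum expert count for retention (default 1).
#' @param truncation_corrected Renormalise the tail by `P(X > 0)`.
#' @return Probability in \[0, 1\] that one interval exceeds the maximum time.
#' @examples
#' discontinuity_probability(theta = 4, nu = 0.3, tau = 4, eta_max = 9)
#' @export
discontinuity_probability <- function(theta, nu, tau, eta_max,
                                      retention_threshold = 1,
                                      truncation_corrected = FALSE) {
  stop_unless(is.numeric(theta) && all(theta > 0), "`theta` must be > 0")
  stop_unless(is.numeric(nu) && all(nu >= 0), "`nu` must be >= 0")
  dtm <- delta_t_max(tau, eta_max, retention_threshold)
  sd <- nu * theta
  p <- ifelse(sd == 0,
              as.numeric(theta > dtm),
              stats::pnorm(dtm, mean = theta, sd = sd, lower.tail = FALSE))
  if (truncation_corrected) {
    pos_mass <- ifelse(sd == 0, 1,
                       stats::pnorm(0, mean = theta, sd = sd, lower.tail = FALSE))
    p <- pmin(1, p / pos_mass)
  }
  p
}

#' Closed-form retention probability over the horizon
#'
#' The skill is retained if none of the horizon's use intervals exceeds the
#' maximum unused-retention time. Taking the number of intervals as the
#' real-valued ratio `horizon_L / theta` and intervals as independent, the
#' retention probability is `(1 - p_d)^(L / theta)`, evaluated in log space
#' so that tiny `p_d` with large exponents does not underflow.
#'
#' @param params A [model_params()] object.
#' @param truncation_corrected Passed to [discontinuity_probability()].
#' @return An `analytical_result`: list with `delta_t_max` (years), `p_d`,
#'   `n_intervals` (= `horizon_L / theta`, real-valued) and `p_r`.
#' @examples
#' p <- model_params(theta = 4, nu = 0.3, tau = 4, eta_max = 9)
#' retention_probability_analytic(p)$p_r  # about 0.992
#' @export
retention_probability_analytic <- function(params, truncation_corrected = FALSE) {
  stopifnot(inherits(params, "model_params"))
  dtm <- delta_t_max(params$tau, params$eta_max, params$retention_threshold)
  p_d <- discontinuity_probability(params$theta, params$nu,
                                   params$tau, params$eta_max,
                                   params$retention_threshold,
                                   truncation_corrected)
  n_int <- params$horizon_L / params$theta
  structure(
    list(delta_t_max = dtm, p_d = p_d, n_intervals = n_int,
         p_r = p_retention_value(p_d, n_int),
         truncation_corrected = truncation_corrected),
    class = "analytical_result"
  )
}

#' @export
print.analytical_result <- function(x, ...) {
  cat("Closed-form retention result\n")
  cat(sprintf("  max unused-retention time: %.4g yr\n", x$delta_t_max))
  cat(sprintf("  per-interval discontinuity P_d = %.4g over %.4g intervals\n",
              x$p_d, x$n_intervals))
  cat(sprintf("  retention probability P_r = %.6g\n", x$p_r))
  invisible(x)
}

# (1 - p_d)^n in log space; vectorised. p_d = 1 maps to 0, p_d = 0 to 1.
p_retention_value <- function(p_d, n_intervals) {
  ifelse(p_d >= 1, 0, exp(n_intervals * log1p(-p_d)))
}

# Vectorised closed-form P_r over (theta, nu) vectors at fixed tau, eta_max.
# Fast path for grids; no params object construction per cell.
p_retention_vec <- function(theta, nu, tau, eta_max, L = 1000,
                            retention_threshold = 1,
                            truncation_corrected = FALSE) {
  p_d <- discontinuity_probability(theta, nu, tau, eta_max,
                                   retention_threshold, truncation_corrected)
  p_retention_value(p_d, L / theta)
}
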