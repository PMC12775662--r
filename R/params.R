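#' Model parameters for the skill-retention model
#'
#' Bundles one point of the model's parameter space together with the fixed
#' simulation settings. The model tracks the number of "experts" -- group
#' members currently able to deploy a collectively held skill. Between uses
#' the expert count decays exponentially with e-folding time `tau`; each use
#' instantly restores it to `eta_max`; the skill is permanently lost once the
#' count drops below `retention_threshold`.
#'
#' The reference sweep ranges are theta in \[1, 20\] years, nu in \[0, 2\],
#' eta_max in \[3, 60\] experts and tau in \[1, 16\] years. Values outside
#' these ranges are permitted (they are sweep bounds, not mathematical
#' constraints) but raise a warning.
#'
#' @param theta Mean use interval, years. Must be > 0.
#' @param nu Interval variability: dimensionless scaling of the interval
#'   standard deviation, `sd = nu * theta`. Must be >= 0.
#' @param eta_max Maximum number of experts, individuals. Must be >= 1.
#' @param tau Forgetting time, years: time for the expert count to fall to
#'   `1/e` of `eta_max`. Must be > 0.
#' @param horizon_L Modelled time horizon, years (default 1000).
#' @param n_sequences_K Number of independent temporal sequences per
#'   Monte-Carlo estimate (default 111).
#' @param retention_threshold Minimum expert count for the skill to count as
#'   retained (default 1 person).
#'
#' @return An object of class `model_params`: a named list of the validated
#'   parameters.
#' @examples
#' p <- model_params(theta = 4, nu = 0.3, tau = 4, eta_max = 9)
#' delta_t_max(p$tau, p$eta_max)
#' @export
model_params <- function(theta, nu, eta_max, tau,
                         horizon_L = 1000,
                         n_sequences_K = 111,
                         retention_threshold = 1) {
  stop_unless(is_scalar_num(theta) && theta > 0, "`theta` must be a single number > 0")
  stop_unless(is_scalar_num(nu) && nu >= 0, "`nu` must be a single number >= 0")
  stop_unless(is_scalar_num(eta_max) && eta_max >= 1, "`eta_max` must be >= 1")
  stop_unless(is_scalar_num(tau) && tau > 0, "`tau` must be > 0")
  stop_unless(is_scalar_num(horizon_L) && horizon_L > 0, "`horizon_L` must be > 0")
  stop_unless(is_scalar_num(n_sequences_K) && n_sequences_K >= 1,
              "`n_sequences_K` must be >= 1")
  stop_unless(is_scalar_num(retention_threshold) && retention_threshold > 0,
              "`retention_threshold` must be > 0")

  warn_outside_range(theta, 1, 20, "theta")
  warn_outside_range(nu, 0, 2, "nu")
  warn_outside_range(eta_max, 3, 60, "eta_max")
  warn_outside_range(tau, 1, 16, "tau")

  structure(
    list(theta = theta, nu = nu, eta_max = eta_max, tau = tau,
         horizon_L = horizon_L,
         n_sequences_K = as.integer(n_sequences_K),
         retention_threshold = retention_threshold),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat("Skill-retention model parameters\n")
  cat(sprintf("  theta (mean use interval): %g yr\n", x$theta))
  cat(sprintf("  nu    (variability)      : %g\n", x$nu))
  cat(sprintf("  eta_max (expert pool)    : %g\n", x$eta_max))
  cat(sprintf("  tau   (forgetting time)  : %g yr\n", x$tau))
  cat(sprintf("  horizon L = %g yr, K = %d sequences, threshold = %g expert(s)\n",
              x$horizon_L, x$n_sequences_K, x$retention_threshold))
  cat(sprintf("  max unused-retention time: %.4g yr\n",
              delta_t_max(x$tau, x$eta_max, x$retention_threshold)))
  invisible(x)
}

#' Experts remaining after an unused interval
#'
#' Exponential forgetting law: starting from a full pool of `eta_max`
#' experts, after `dt` years without a use of the skill
#' `eta_max * exp(-dt / tau)` experts remain. The count is continuous; use
#' [expert_count_display()] to report whole individuals.
#'
#' @param eta_max Maximum number of experts (>= 1).
#' @param tau Forgetting time, years (> 0).
#' @param dt Elapsed time since the last use, years (>= 0). Vectorised.
#' @return Continuous expert count, same length as `dt`.
#' @examples
#' experts_remaining(20, 2, 2)   # 7.36: "seven individuals" after floor
#' experts_remaining(100, 5, 5)  # one forgetting time: 100/e
#' @seealso [delta_t_max()], [expert_count_display()]
#' @export
experts_remaining <- function(eta_max, tau, dt) {
  stop_unless(is_scalar_num(eta_max) && eta_max >= 1, "`eta_max` must be >= 1")
  stop_unless(is_scalar_num(tau) && tau > 0, "`tau` must be > 0")
  stop_unless(is.numeric(dt) && all(is.finite(dt)) && all(dt >= 0),
              "`dt` must be non-negative")
  eta_max * exp(-dt / tau)
}

#' Report a continuous expert count as whole individuals
#'
#' Reporting convention: the number of people who can still deploy the skill
#' is the floor of the continuous count (7.36 experts means seven
#' individuals).
#'
#' @param continuous_count Non-negative numeric vector.
#' @return Integer vector, `floor(continuous_count)`.
#' @export
expert_count_display <- function(continuous_count) {
  stop_unless(is.numeric(continuous_count) && all(is.finite(continuous_count)) &&
                all(continuous_count >= 0),
              "`continuous_count` must be non-negative")
  as.integer(floor(continuous_count))
}

#' Maximum time a skill survives without use
#'
#' The longest interval the group can go without using the skill before the
#' expert count drops below the retention threshold. For threshold m it is
#' `tau * log(eta_max / m)`; with the default threshold of one person this is
#' `tau * log(eta_max)`. Linear in `tau`, logarithmic in `eta_max`.
#'
#' @param tau Forgetting time, years (> 0). Vectorised.
#' @param eta_max Maximum number of experts (>= 1). Vectorised.
#' @param retention_threshold Minimum expert count for retention (default 1).
#' @return Maximum unused-retention time, years.
#' @examples
#' delta_t_max(4, 43)  # 15.04: about 15 years
#' delta_t_max(1, 1)   # 0: a lone expert pool is lost without immediate use
#' @export
delta_t_max <- function(tau, eta_max, retention_threshold = 1) {
  stop_unless(is.numeric(tau) && all(tau > 0), "`tau` must be > 0")
  stop_unless(is.numeric(eta_max) && all(eta_max >= 1), "`eta_max` must be >= 1")
  stop_unless(is_scalar_num(retention_threshold) && retention_threshold > 0,
              "`retention_threshold` must be > 0")
  stop_unless(all(eta_max >= retention_threshold),
              "`eta_max` must be >= `retention_threshold`")
  tau * log(eta_max / retention_threshold)
}

# -- internal validation helpers ---------------------------------------------

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stop_unless <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

warn_outside_range <- function(value, lo, hi, name) {
  if (value < lo || value > hi) {
    warning(sprintf("`%s` = %g is outside the reference sweep range [%g, %g]",
                    name, value, lo, hi), call. = FALSE)
  }
}
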