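#' Construct a skill-retention decay dataset
#'
#' Holds (time since last practice, fraction of skill retained) pairs of the
#' kind reported by procedural-skill retention studies, to which an
#' exponential forgetting curve can be fitted.
#'
#' @param times Elapsed times since last practice, years, >= 0.
#' @param retention Retention fractions in (0, 1].
#' @param labels Optional character labels per observation.
#' @return A `decay_dataset` (data frame with columns `time`, `retention`
#'   and optionally `label`).
#' @export
decay_dataset <- function(times, retention, labels = NULL) {
  stop_unless(is.numeric(times) && is.numeric(retention) &&
                length(times) == length(retention) && length(times) >= 3,
              "`times` and `retention` must be equal-length numeric, >= 3 points")
  stop_unless(all(is.finite(times)) && all(times >= 0),
              "`times` must be non-negative")
  stop_unless(all(is.finite(retention)) && all(retention > 0) && all(retention <= 1),
              "`retention` must lie in (0, 1]")
  d <- data.frame(time = as.numeric(times), retention = as.numeric(retention))
  if (!is.null(labels)) {
    stop_unless(length(labels) == length(times), "`labels` length mismatch")
    d$label <- as.character(labels)
  }
  class(d) <- c("decay_dataset", "data.frame")
  d
}

#' Generate synthetic exponential-decay retention data
#'
#' Emulates the structure of skill-retention study data: retention
#' `exp(-t / tau_true)` plus additive Gaussian noise, clamped into (0, 1]
#' (sub-zero values are set to the smallest positive double so the result
#' remains a valid retention fraction).
#'
#' @param tau_true True forgetting time, years (> 0).
#' @param times Measurement times, years, >= 0 (length >= 3).
#' @param noise_sd Standard deviation of the additive noise (>= 0).
#' @param seed Optional integer seed.
#' @return A [decay_dataset()].
#' @examples
#' d <- generate_decay_data(2, times = 0:19, noise_sd = 0.05, seed = 1)
#' fit_forgetting_time(d, n_boot = 0)$tau
#' @export
generate_decay_data <- function(tau_true, times, noise_sd, seed = NULL) {
  stop_unless(is_scalar_num(tau_true) && tau_true > 0, "`tau_true` must be > 0")
  stop_unless(is.numeric(times) && length(times) >= 3 && all(times >= 0),
              "`times` must be >= 3 non-negative values")
  stop_unless(is_scalar_num(noise_sd) && noise_sd >= 0, "`noise_sd` must be >= 0")
  r <- with_seed(seed, exp(-times / tau_true) +
                   stats::rnorm(length(times), 0, noise_sd))
  r <- pmin(1, pmax(r, .Machine$double.xmin))
  decay_dataset(times, r)
}

#' Estimate the forgetting time from decay data
#'
#' Fits the exponential forgetting curve `r(t) = A * exp(-t / tau)` to
#' (time, retention) data by nonlinear least squares on the original scale
#' (Levenberg-Marquardt via [minpack.lm::nlsLM()]), initialised from a
#' log-linear regression. By default the amplitude is fixed at `A = 1`
#' (full retention at zero elapsed time); set `fit_amplitude = TRUE` to
#' estimate it. A case-resampling bootstrap provides a percentile
#' confidence interval for tau.
#'
#' Fitting on the original scale (rather than regressing `log r` on `t`)
#' keeps noisy near-zero retention values from dominating the fit.
#'
#' @param data A [decay_dataset()] or a data frame with columns `time` and
#'   `retention`.
#' @param fit_amplitude Estimate the amplitude A instead of fixing it at 1.
#' @param n_boot Bootstrap replicates for the tau confidence interval
#'   (default 1000; 0 skips the bootstrap).
#' @param conf_level Confidence level for the interval (default 0.95).
#' @param seed Integer seed for the bootstrap resampling (default 1).
#' @return A `decay_fit`: list with `tau` (years), `amplitude`,
#'   `residual_sse`, `ci_tau` (length 2, `NA` if `n_boot = 0`), `n_points`,
#'   `fit_amplitude`, `n_boot`.
#' @examples
#' d <- generate_decay_data(5, times = seq(0, 20), noise_sd = 0, seed = 1)
#' fit_forgetting_time(d, n_boot = 0)
#' @export
fit_forgetting_time <- function(data, fit_amplitude = FALSE, n_boot = 1000,
                                conf_level = 0.95, seed = 1L) {
  if (!inherits(data, "decay_dataset")) {
    stop_unless(is.data.frame(data) && all(c("time", "retention") %in% names(data)),
                "`data` must be a decay_dataset or have columns time, retention")
    data <- decay_dataset(data$time, data$retention)
  }
  stop_unless(length(unique(data$time)) >= 2,
              "need at least two distinct measurement times")

  fit <- fit_decay_once(data$time, data$retention, fit_amplitude)

  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    n <- nrow(data)
    idx <- with_seed(seed, matrix(sample.int(n, n * n_boot, replace = TRUE),
                                  nrow = n_boot))
    taus <- rep(NA_real_, n_boot)
    for (b in seq_len(n_boot)) {
      taus[b] <- tryCatch(
        fit_decay_once(data$time[idx[b, ]], data$retention[idx[b, ]],
                       fit_amplitude)$tau,
        error = function(e) NA_real_)
    }
    alpha <- (1 - conf_level) / 2
    ci <- unname(stats::quantile(taus, c(alpha, 1 - alpha), na.rm = TRUE))
  }

  structure(
    list(tau = fit$tau, amplitude = fit$amplitude,
         residual_sse = fit$sse, ci_tau = ci,
         n_points = nrow(data), fit_amplitude = fit_amplitude,
         n_boot = as.integer(n_boot), conf_level = conf_level),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("exponential forgetting fit: tau = %.4g yr (A = %.4g, SSE = %.4g)\n",
              x$tau, x$amplitude, x$residual_sse))
  if (!anyNA(x$ci_tau)) {
    cat(sprintf("  %g%% bootstrap CI for tau: [%.4g, %.4g] (%d reps)\n",
                100 * x$conf_level, x$ci_tau[1], x$ci_tau[2], x$n_boot))
  }
  invisible(x)
}

# One nonlinear least-squares fit of r = A * exp(-t / tau); A fixed to 1
# unless fit_amplitude. Initialised from the log-linear slope, which must be
# negative for tau to be identifiable.
fit_decay_once <- function(time, retention, fit_amplitude) {
  slope <- stats::coef(stats::lm(log(retention) ~ time))[["time"]]
  if (!is.finite(slope) || slope >= 0) {
    stop("forgetting time is non-identifiable: retention does not decay with time",
         call. = FALSE)
  }
  tau0 <- -1 / slope
  df <- data.frame(t = time, r = retention)
  if (fit_amplitude) {
    m <- minpack.lm::nlsLM(r ~ A * exp(-t / tau), data = df,
                           start = list(tau = tau0, A = 1),
                           lower = c(tau = 1e-9, A = 0),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
    est <- stats::coef(m)
    list(tau = unname(est["tau"]), amplitude = unname(est["A"]),
         sse = sum(stats::resid(m)^2))
  } else {
    m <- minpack.lm::nlsLM(r ~ exp(-t / tau), data = df,
                           start = list(tau = tau0),
                           lower = c(tau = 1e-9),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
    list(tau = unname(stats::coef(m)["tau"]), amplitude = 1,
         sse = sum(stats::resid(m)^2))
  }
}
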