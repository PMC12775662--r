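#' Simulate one temporal sequence of skill use, decay and recovery
#'
#' Runs a single renewal sequence: the expert pool starts full at
#' `eta_max`; intervals between uses are drawn from the positive-truncated
#' normal law; a use before the pool decays below the retention threshold
#' resets it to `eta_max`; an interval longer than the maximum
#' unused-retention time [delta_t_max()] loses the skill permanently. The
#' sequence ends at the first loss or once cumulative time exceeds the
#' horizon.
#'
#' The comparison is strict: an interval exactly equal to the maximum time
#' leaves the pool at the threshold and the skill is retained.
#'
#' @param params A [model_params()] object.
#' @param seed Optional integer seed for a dedicated random stream; `NULL`
#'   draws from the current RNG state.
#' @return A `sequence_outcome`: list with `lost` (logical), `loss_time`
#'   (years, `NA` if retained; the instant the expert count crosses the
#'   threshold, i.e. time of last use + maximum time), `n_uses` (number of
#'   uses before termination) and `end_time` (years).
#' @examples
#' p <- model_params(theta = 4, nu = 0.3, tau = 4, eta_max = 9)
#' run_sequence(p, seed = 1)
#' @export
run_sequence <- function(params, seed = NULL) {
  stopifnot(inherits(params, "model_params"))
  with_seed(seed, run_sequence_impl(params))
}

# Draws from the *current* RNG state. Vectorised over batches of
# required_draw_count() intervals; extends with further batches in the rare
# event that neither a loss nor horizon coverage occurs within a batch.
run_sequence_impl <- function(params) {
  dtm <- delta_t_max(params$tau, params$eta_max, params$retention_threshold)
  L <- params$horizon_L
  batch <- required_draw_count(L, params$theta)
  sd <- params$nu * params$theta

  t_now <- 0
  uses <- 0L
  repeat {
    dts <- draw_positive_normal(batch, params$theta, sd)
    cum <- t_now + cumsum(dts)
    fatal <- which(dts > dtm)
    first_fatal <- if (length(fatal)) fatal[1L] else NA_integer_
    over <- which(cum > L)
    first_over <- if (length(over)) over[1L] else NA_integer_

    if (!is.na(first_fatal) && (is.na(first_over) || first_fatal <= first_over)) {
      # loss check (interval too long) precedes the horizon check
      t_prev <- cum[first_fatal] - dts[first_fatal]
      loss_time <- t_prev + dtm
      return(new_sequence_outcome(lost = TRUE, loss_time = loss_time,
                                  n_uses = uses + first_fatal - 1L,
                                  end_time = loss_time))
    }
    if (!is.na(first_over)) {
      return(new_sequence_outcome(lost = FALSE, loss_time = NA_real_,
                                  n_uses = uses + first_over,
                                  end_time = cum[first_over]))
    }
    # horizon not yet covered: append further draws (possible when many
    # short intervals are drawn; the 2L/theta count only suffices on average)
    t_now <- cum[batch]
    uses <- uses + batch
  }
}

new_sequence_outcome <- function(lost, loss_time, n_uses, end_time) {
  structure(list(lost = lost, loss_time = loss_time,
                 n_uses = as.integer(n_uses), end_time = end_time),
            class = "sequence_outcome")
}

#' @export
print.sequence_outcome <- function(x, ...) {
  if (x$lost) {
    cat(sprintf("sequence outcome: LOST at t = %.2f yr after %d use(s)\n",
                x$loss_time, x$n_uses))
  } else {
    cat(sprintf("sequence outcome: retained to t = %.2f yr (%d uses)\n",
                x$end_time, x$n_uses))
  }
  invisible(x)
}

#' Monte-Carlo estimate of the retention probability
#'
#' Runs `n_sequences_K` independent temporal sequences (one child random
#' stream each, all derived from `seed`) and estimates the probability that
#' the skill survives to the horizon as `1 - n_losses / K`, with the
#' binomial standard error `sqrt(p * (1 - p) / K)`.
#'
#' @param params A [model_params()] object.
#' @param seed Integer seed for the top-level random stream (default 1).
#' @param keep_outcomes If `TRUE`, attach the list of per-sequence
#'   [run_sequence()] outcomes.
#' @return A `retention_estimate`: list with `p_r`, `n_losses`,
#'   `n_sequences`, `std_error`, `seed` and (optionally) `outcomes`.
#' @examples
#' p <- model_params(theta = 4, nu = 0.3, tau = 4, eta_max = 9)
#' estimate_retention(p, seed = 1)
#' @export
estimate_retention <- function(params, seed = 1L, keep_outcomes = FALSE) {
  stopifnot(inherits(params, "model_params"))
  K <- params$n_sequences_K
  streams <- rng_streams(seed, K)

  old <- rng_snapshot()
  on.exit(rng_restore(old), add = TRUE)
  outcomes <- vector("list", K)
  for (k in seq_len(K)) {
    rng_set_state(streams[[k]])
    outcomes[[k]] <- run_sequence_impl(params)
  }

  n_losses <- sum(vapply(outcomes, function(o) o$lost, logical(1)))
  p_r <- 1 - n_losses / K
  structure(
    list(p_r = p_r,
         n_losses = as.integer(n_losses),
         n_sequences = K,
         std_error = sqrt(p_r * (1 - p_r) / K),
         seed = as.integer(seed),
         outcomes = if (keep_outcomes) outcomes else NULL),
    class = "retention_estimate"
  )
}

#' @export
print.retention_estimate <- function(x, ...) {
  cat(sprintf("Monte-Carlo retention estimate: P_r = %.4f (SE %.4f)\n",
              x$p_r, x$std_error))
  cat(sprintf("  %d losses in %d sequences, seed %d\n",
              x$n_losses, x$n_sequences, x$seed))
  invisible(x)
}
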