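# Shared helpers: independent slow-path oracles the fast implementation is
# checked against.

# Classify one fixed interval list by the expert-count rule (eta dropping
# below the threshold), stepping interval by interval. Independent of the
# engine's "interval > delta_t_max" shortcut.
oracle_classify_intervals <- function(intervals, params) {
  t_now <- 0
  for (dt in intervals) {
    eta <- experts_remaining(params$eta_max, params$tau, dt)
    if (eta < params$retention_threshold) return(list(lost = TRUE, t_last_use = t_now))
    t_now <- t_now + dt
    if (t_now > params$horizon_L) return(list(lost = FALSE, t_last_use = t_now))
  }
  list(lost = NA, t_last_use = t_now)  # ran out of draws before resolving
}

# Closed-form retention probability computed independently (direct normal
# tail + power), for cross-checking the analytical module on small cases.
oracle_p_retention <- function(theta, nu, tau, eta_max, L = 1000) {
  dtm <- tau * log(eta_max)
  sd <- nu * theta
  p_d <- ifelse(sd == 0, as.numeric(theta > dtm),
                1 - stats::pnorm((dtm - theta) / sd))
  ifelse(p_d >= 1, 0, (1 - p_d)^(L / theta))
}

# Reference sweep point: forgetting time 4 yr, expert pool 43.
fig_grid <- function(nu_values, n_theta = 50, engine = "analytical", ...) {
  sweep_grid(grid_spec(seq(1, 20, length.out = n_theta), nu_values,
                       tau = 4, eta_max = 43, engine = engine, ...))
}
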