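#' Specify a retention-probability grid over (theta, nu)
#'
#' @param theta_values Strictly increasing mean use intervals, years.
#' @param nu_values Strictly increasing variability values.
#' @param tau Forgetting time, years.
#' @param eta_max Maximum number of experts.
#' @param L Time horizon, years (default 1000).
#' @param K Sequences per Monte-Carlo cell (numerical engine, default 111).
#' @param engine `"analytical"` (closed form, deterministic) or
#'   `"numerical"` (Monte-Carlo).
#' @param seed Seed for the numerical engine (default 1; ignored by the
#'   analytical engine).
#' @return A `grid_spec` object.
#' @examples
#' gs <- grid_spec(seq(1, 20, length.out = 50), seq(0, 2, length.out = 50),
#'                 tau = 4, eta_max = 43)
#' @export
grid_spec <- function(theta_values, nu_values, tau, eta_max,
                      L = 1000, K = 111,
                      engine = c("analytical", "numerical"),
                      seed = 1L) {
  engine <- match.arg(engine)
  stop_unless(is.numeric(theta_values) && length(theta_values) >= 1 &&
                all(theta_values > 0) &&
                (length(theta_values) == 1 || all(diff(theta_values) > 0)),
              "`theta_values` must be positive and strictly increasing")
  stop_unless(is.numeric(nu_values) && length(nu_values) >= 1 &&
                all(nu_values >= 0) &&
                (length(nu_values) == 1 || all(diff(nu_values) > 0)),
              "`nu_values` must be non-negative and strictly increasing")
  stop_unless(is_scalar_num(tau) && tau > 0, "`tau` must be > 0")
  stop_unless(is_scalar_num(eta_max) && eta_max >= 1, "`eta_max` must be >= 1")
  stop_unless(is_scalar_num(L) && L > 0, "`L` must be > 0")
  stop_unless(is_scalar_num(K) && K >= 1, "`K` must be >= 1")
  structure(
    list(theta_values = theta_values, nu_values = nu_values,
         tau = tau, eta_max = eta_max, L = L, K = as.integer(K),
         engine = engine, seed = as.integer(seed)),
    class = "grid_spec"
  )
}

#' Evaluate the retention probability over a (theta, nu) grid
#'
#' Computes P_r for every grid cell with the engine named in the spec. The
#' analytical engine is exact and vectorised; the numerical engine runs one
#' seeded Monte-Carlo estimate of K sequences per cell (cell seeds derived
#' deterministically from the spec seed, so results are reproducible and
#' independent of evaluation order).
#'
#' @param spec A [grid_spec()].
#' @return A `retention_grid`: list with `spec`, `p_r` (matrix, rows = nu
#'   values, columns = theta values) and `delta_t_max` (years, for the fixed
#'   tau and eta_max).
#' @examples
#' g <- sweep_grid(grid_spec(seq(1, 20, length.out = 20),
#'                           seq(0, 2, length.out = 20),
#'                           tau = 4, eta_max = 43))
#' range(g$p_r)
#' @export
sweep_grid <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  th <- spec$theta_values
  nv <- spec$nu_values
  dtm <- delta_t_max(spec$tau, spec$eta_max)

  if (spec$engine == "analytical") {
    m <- outer(nv, th, function(v, t)
      p_retention_vec(t, v, spec$tau, spec$eta_max, spec$L))
  } else {
    cell_seeds <- matrix(derive_seeds(spec$seed, length(nv) * length(th)),
                         nrow = length(nv))
    m <- matrix(NA_real_, nrow = length(nv), ncol = length(th))
    for (i in seq_along(nv)) {
      for (j in seq_along(th)) {
        p <- suppressWarnings(
          model_params(theta = th[j], nu = nv[i],
                       eta_max = spec$eta_max, tau = spec$tau,
                       horizon_L = spec$L, n_sequences_K = spec$K))
        m[i, j] <- estimate_retention(p, seed = cell_seeds[i, j])$p_r
      }
    }
  }
  dimnames(m) <- list(nu = signif(nv, 8), theta = signif(th, 8))
  structure(list(spec = spec, p_r = m, delta_t_max = dtm),
            class = "retention_grid")
}

#' @export
print.retention_grid <- function(x, ...) {
  cat(sprintf("retention_grid: %d x %d (%s engine), tau = %g, eta_max = %g\n",
              nrow(x$p_r), ncol(x$p_r), x$spec$engine, x$spec$tau, x$spec$eta_max))
  cat(sprintf("  theta in [%g, %g], nu in [%g, %g]; max unused time %.3g yr\n",
              min(x$spec$theta_values), max(x$spec$theta_values),
              min(x$spec$nu_values), max(x$spec$nu_values), x$delta_t_max))
  cat(sprintf("  P_r range [%.3g, %.3g]\n", min(x$p_r), max(x$p_r)))
  invisible(x)
}

#' Tidy a retention grid into a long data frame
#'
#' @param x A `retention_grid`.
#' @param row.names,optional,... Ignored (S3 signature).
#' @return Data frame with columns engine, tau, eta_max, theta, nu, p_r,
#'   delta_t_max, K, seed -- one row per grid cell.
#' @export
as.data.frame.retention_grid <- function(x, row.names = NULL, optional = FALSE, ...) {
  s <- x$spec
  cells <- expand.grid(nu = s$nu_values, theta = s$theta_values,
                       KEEP.OUT.ATTRS = FALSE)
  data.frame(engine = s$engine, tau = s$tau, eta_max = s$eta_max,
             theta = cells$theta, nu = cells$nu,
             p_r = as.vector(x$p_r),
             delta_t_max = x$delta_t_max,
             K = if (s$engine == "numerical") s$K else NA_integer_,
             seed = if (s$engine == "numerical") s$seed else NA_integer_)
}

#' Classify grid cells as loss or retention
#'
#' A cell is a *loss* cell when its retention probability is below
#' `loss_cut`, otherwise a *retention* cell. Cells with probability strictly
#' inside `transition_band` are additionally counted as *transition* cells
#' (informational; they are still loss or retention per the cut). A panel is
#' *loss-majority* when loss cells outnumber retention cells.
#'
#' @param grid A [sweep_grid()] result.
#' @param loss_cut Loss/retention cut on P_r (default 0.5).
#' @param transition_band Length-2 band on P_r (default `c(0.05, 0.95)`).
#' @return A `panel_summary`: tau, eta_max, cell counts, `loss_majority`.
#' @export
classify_cells <- function(grid, loss_cut = 0.5, transition_band = c(0.05, 0.95)) {
  stopifnot(inherits(grid, "retention_grid"))
  stop_unless(is_scalar_num(loss_cut) && loss_cut >= 0 && loss_cut <= 1,
              "`loss_cut` must be in [0, 1]")
  stop_unless(is.numeric(transition_band) && length(transition_band) == 2 &&
                all(transition_band >= 0) && all(transition_band <= 1) &&
                transition_band[1] < transition_band[2],
              "`transition_band` must be an increasing pair in [0, 1]")
  p <- grid$p_r
  n_loss <- sum(p < loss_cut)
  n_ret <- sum(p >= loss_cut)
  n_trans <- sum(p > transition_band[1] & p < transition_band[2])
  structure(
    list(tau = grid$spec$tau, eta_max = grid$spec$eta_max,
         n_cells = length(p),
         n_loss_cells = n_loss, n_retention_cells = n_ret,
         n_transition_cells = n_trans,
         loss_majority = n_loss > n_ret,
         loss_cut = loss_cut, transition_band = transition_band),
    class = "panel_summary"
  )
}

#' @export
print.panel_summary <- function(x, ...) {
  cat(sprintf("panel (tau = %g, eta_max = %g): %d loss / %d retention / %d transition of %d cells%s\n",
              x$tau, x$eta_max, x$n_loss_cells, x$n_retention_cells,
              x$n_transition_cells, x$n_cells,
              if (x$loss_majority) " [loss-majority]" else ""))
  invisible(x)
}

#' Count loss-majority panels across (tau, eta_max) combinations
#'
#' Builds one retention grid over (theta, nu) for every pair of `tau_values`
#' and `eta_values`, classifies cells at `loss_cut`, and counts the panels
#' in which loss cells outnumber retention cells. Defaults reproduce the
#' reference sweep: tau in \{1, 2, 4, 8, 16\} years crossed with eta_max in
#' \{3, 6, 12, 24, 48, 60\} experts, a 50 x 50 grid with theta from 1 to 20
#' years and nu from 0.1 to 2 (the variability range the simulations use).
#'
#' @param tau_values Forgetting times, years.
#' @param eta_values Maximum expert-pool sizes.
#' @param theta_values Grid of mean use intervals.
#' @param nu_values Grid of variability values.
#' @param engine `"analytical"` or `"numerical"`.
#' @param L,K,seed,loss_cut Passed through to [grid_spec()] /
#'   [classify_cells()].
#' @return Integer count of loss-majority panels, with a `"panels"`
#'   attribute: data frame (tau, eta_max, n_loss, n_retention, n_transition,
#'   loss_majority).
#' @examples
#' count_loss_majority_panels(tau_values = c(1, 4), eta_values = c(3, 43),
#'                            theta_values = seq(1, 20, length.out = 10),
#'                            nu_values = seq(0.1, 2, length.out = 10))
#' @export
count_loss_majority_panels <- function(tau_values = c(1, 2, 4, 8, 16),
                                       eta_values = c(3, 6, 12, 24, 48, 60),
                                       theta_values = seq(1, 20, length.out = 50),
                                       nu_values = seq(0.1, 2, length.out = 50),
                                       engine = c("analytical", "numerical"),
                                       L = 1000, K = 111, seed = 1L,
                                       loss_cut = 0.5) {
  engine <- match.arg(engine)
  stop_unless(length(tau_values) >= 1 && length(eta_values) >= 1,
              "value lists must be non-empty")
  combos <- expand.grid(tau = tau_values, eta_max = eta_values,
                        KEEP.OUT.ATTRS = FALSE)
  panel_seeds <- derive_seeds(seed, nrow(combos))
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    gs <- grid_spec(theta_values, nu_values,
                    tau = combos$tau[i], eta_max = combos$eta_max[i],
                    L = L, K = K, engine = engine, seed = panel_seeds[i])
    cls <- classify_cells(sweep_grid(gs), loss_cut = loss_cut)
    data.frame(tau = cls$tau, eta_max = cls$eta_max,
               n_loss = cls$n_loss_cells,
               n_retention = cls$n_retention_cells,
               n_transition = cls$n_transition_cells,
               loss_majority = cls$loss_majority)
  })
  panels <- do.call(rbind, rows)
  structure(sum(panels$loss_majority), panels = panels)
}

#' Extract the retention/loss boundary of a grid
#'
#' For each variability row of the grid, the mean use interval at which the
#' retention probability first crosses `level`, linearly interpolated
#' between the bracketing grid columns. Rows that never cross within the
#' theta range report `NA`. Non-monotone rows (possible with the
#' Monte-Carlo engine) use the first crossing and are flagged.
#'
#' @param grid A [sweep_grid()] result.
#' @param level Probability level to cross (default 0.5).
#' @return Data frame with columns `nu`, `boundary_theta` (years, `NA` if no
#'   crossing) and `flagged` (non-monotone row).
#' @examples
#' g <- sweep_grid(grid_spec(seq(1, 20, length.out = 50), c(0, 0.32, 0.88, 2),
#'                           tau = 4, eta_max = 43))
#' find_boundary(g)
#' @export
find_boundary <- function(grid, level = 0.5) {
  stopifnot(inherits(grid, "retention_grid"))
  stop_unless(is_scalar_num(level) && level > 0 && level < 1,
              "`level` must be in (0, 1)")
  th <- grid$spec$theta_values
  out <- lapply(seq_along(grid$spec$nu_values), function(i) {
    p <- grid$p_r[i, ]
    flagged <- any(diff(p) > 1e-9)  # rises beyond numerical noise
    below <- which(p < level)
    j <- if (length(below)) below[1L] else NA_integer_
    boundary <- if (is.na(j) || j == 1L) {
      NA_real_  # no crossing inside the theta range
    } else {
      # linear interpolation between the bracketing cells
      th[j - 1L] + (th[j] - th[j - 1L]) * (p[j - 1L] - level) / (p[j - 1L] - p[j])
    }
    data.frame(nu = grid$spec$nu_values[i], boundary_theta = boundary,
               flagged = flagged)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cross-validate the Monte-Carlo engine against the closed form
#'
#' For each parameter point, compares the Monte-Carlo retention estimate
#' (K sequences) with the closed-form probability. A point is flagged when
#' the absolute discrepancy exceeds `3 * SE + slack`, where SE is the
#' binomial standard error of a K-sequence estimate at the closed-form
#' probability.
#'
#' @param param_points Data frame with columns theta, nu, tau, eta_max.
#' @param K Sequences per Monte-Carlo estimate (default 111).
#' @param seed Top-level seed (default 1).
#' @param L Horizon, years (default 1000).
#' @param slack Additive discrepancy allowance beyond 3 SE (default 0.02),
#'   absorbing the closed form's untruncated-tail and fixed-interval-count
#'   approximations.
#' @return A `cross_validation` data frame: per-point p_r from both engines,
#'   discrepancy, SE, `flagged`; attributes `pass_fraction`, `K`, `seed`.
#' @examples
#' pts <- data.frame(theta = c(4, 6), nu = c(0.3, 0.5),
#'                   tau = c(4, 4), eta_max = c(9, 43))
#' cross_validate(pts, seed = 7)
#' @export
cross_validate <- function(param_points, K = 111, seed = 1L, L = 1000,
                           slack = 0.02) {
  stop_unless(is.data.frame(param_points) &&
                all(c("theta", "nu", "tau", "eta_max") %in% names(param_points)) &&
                nrow(param_points) >= 1,
              "`param_points` needs columns theta, nu, tau, eta_max")
  seeds <- derive_seeds(seed, nrow(param_points))
  rows <- lapply(seq_len(nrow(param_points)), function(i) {
    pt <- param_points[i, ]
    p <- suppressWarnings(
      model_params(theta = pt$theta, nu = pt$nu, eta_max = pt$eta_max,
                   tau = pt$tau, horizon_L = L, n_sequences_K = K))
    p_ana <- retention_probability_analytic(p)$p_r
    p_num <- estimate_retention(p, seed = seeds[i])$p_r
    se <- sqrt(p_ana * (1 - p_ana) / K)
    data.frame(theta = pt$theta, nu = pt$nu, tau = pt$tau, eta_max = pt$eta_max,
               p_r_numerical = p_num, p_r_analytic = p_ana,
               discrepancy = abs(p_num - p_ana), std_error = se,
               flagged = abs(p_num - p_ana) > 3 * se + slack)
  })
  res <- do.call(rbind, rows)
  structure(res, class = c("cross_validation", "data.frame"),
            pass_fraction = mean(!res$flagged), K = K, seed = as.integer(seed))
}

#' @export
print.cross_validation <- function(x, ...) {
  cat(sprintf("cross-validation of %d parameter points (K = %d, seed = %d)\n",
              nrow(x), attr(x, "K"), attr(x, "seed")))
  cat(sprintf("  within 3 SE + slack: %.1f%%; max discrepancy %.4f\n",
              100 * attr(x, "pass_fraction"), max(x$discrepancy)))
  NextMethod()
  invisible(x)
}

#' Sample random parameter points within the reference sweep ranges
#'
#' Uniform draws over theta in \[1, 20\], nu in \[0.1, 2\], tau in \[1, 16\]
#' and eta_max in \{3, ..., 60\}, for use with [cross_validate()].
#'
#' @param n Number of points.
#' @param seed Integer seed.
#' @return Data frame with columns theta, nu, tau, eta_max.
#' @export
sample_parameter_points <- function(n, seed = 1L) {
  stop_unless(is_scalar_num(n) && n >= 1, "`n` must be >= 1")
  with_seed(seed, data.frame(
    theta = stats::runif(n, 1, 20),
    nu = stats::runif(n, 0.1, 2),
    tau = stats::runif(n, 1, 16),
    eta_max = sample(3:60, n, replace = TRUE)
  ))
}
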