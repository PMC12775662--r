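test_that("an analytical zero-variability row is a step at the maximum time", {
  g <- sweep_grid(grid_spec(1:20, 0, tau = 4, eta_max = 43))
  dtm <- delta_t_max(4, 43)  # ~ 15.04
  expect_identical(unname(g$p_r[1, g$spec$theta_values <= dtm]),
                   rep(1, sum(1:20 <= dtm)))
  expect_identical(unname(g$p_r[1, g$spec$theta_values > dtm]),
                   rep(0, sum(1:20 > dtm)))
  expect_equal(g$delta_t_max, dtm)
})

test_that("both engines coincide on a deterministic 1x1 grid", {
  for (theta in c(4, 16)) {
    ga <- sweep_grid(grid_spec(theta, 0, tau = 4, eta_max = 43, engine = "analytical"))
    gn <- sweep_grid(grid_spec(theta, 0, tau = 4, eta_max = 43, engine = "numerical",
                               seed = 8))
    expect_identical(ga$p_r[1, 1], gn$p_r[1, 1])
  }
})

test_that("a single analytical cell matches the closed-form module", {
  g <- sweep_grid(grid_spec(4, 0.3, tau = 4, eta_max = 9))
  p <- model_params(theta = 4, nu = 0.3, tau = 4, eta_max = 9)
  expect_equal(g$p_r[1, 1], retention_probability_analytic(p)$p_r,
               tolerance = 1e-12)
})

test_that("numerical grids are reproducible and tidy output has the full schema", {
  gs <- grid_spec(c(2, 6), c(0.5, 1.5), tau = 2, eta_max = 12,
                  engine = "numerical", seed = 31, K = 111)
  g1 <- sweep_grid(gs)
  g2 <- sweep_grid(gs)
  expect_identical(g1$p_r, g2$p_r)
  df <- as.data.frame(g1)
  expect_identical(nrow(df), 4L)
  expect_named(df, c("engine", "tau", "eta_max", "theta", "nu", "p_r",
                     "delta_t_max", "K", "seed"))
  expect_true(all(df$p_r >= 0 & df$p_r <= 1))
})

test_that("cell classification counts losses, retentions and the transition band", {
  g <- fig_grid(nu_values = seq(0, 2, length.out = 50))
  cls <- classify_cells(g)
  expect_identical(cls$n_loss_cells + cls$n_retention_cells, cls$n_cells)
  expect_identical(cls$loss_majority, cls$n_loss_cells > cls$n_retention_cells)
  expect_gt(cls$n_transition_cells, 0)

  all_ret <- sweep_grid(grid_spec(1:5, 0, tau = 4, eta_max = 43))
  c1 <- classify_cells(all_ret)
  expect_identical(c1$n_loss_cells, 0L)
  expect_false(c1$loss_majority)

  all_loss <- sweep_grid(grid_spec(16:20, 0, tau = 4, eta_max = 43))
  c0 <- classify_cells(all_loss)
  expect_identical(c0$n_retention_cells, 0L)
  expect_true(c0$loss_majority)

  expect_error(classify_cells(g, loss_cut = 1.5), "loss_cut")
})

test_that("a panel whose maximum time undercuts nearly all use intervals is loss-majority", {
  # dtmax(1, 3) ~ 1.1 yr < almost every theta in [1, 20]: brute-force check
  n <- count_loss_majority_panels(tau_values = 1, eta_values = 3,
                                  theta_values = seq(1, 20, length.out = 20),
                                  nu_values = seq(0.1, 2, length.out = 20))
  expect_identical(as.integer(n), 1L)
  brute <- mean(outer(seq(0.1, 2, length.out = 20), seq(1, 20, length.out = 20),
                      function(v, t) oracle_p_retention(t, v, 1, 3)) < 0.5)
  expect_gt(brute, 0.5)
})

test_that("panel tallies carry a per-panel summary that adds up", {
  n <- count_loss_majority_panels(tau_values = c(1, 16), eta_values = c(3, 60),
                                  theta_values = seq(1, 20, length.out = 15),
                                  nu_values = seq(0.1, 2, length.out = 15))
  panels <- attr(n, "panels")
  expect_identical(nrow(panels), 4L)
  expect_true(all(panels$n_loss + panels$n_retention == 225L))
  expect_identical(as.integer(n), sum(panels$loss_majority))
  # slow decay + everyone expert is the retention-friendly corner
  friendly <- panels[panels$tau == 16 & panels$eta_max == 60, ]
  expect_false(friendly$loss_majority)
})

test_that("boundary extraction interpolates the 0.5 crossing per variability row", {
  g <- fig_grid(nu_values = c(0, 0.32, 0.88, 2))
  b <- find_boundary(g)
  expect_identical(nrow(b), 4L)
  # near-deterministic row: boundary at the ~15.04-year maximum time
  expect_equal(b$boundary_theta[b$nu == 0], 15, tolerance = 0.05)
  expect_true(b$boundary_theta[b$nu == 0.32] > 7 &&
                b$boundary_theta[b$nu == 0.32] < 10)
  expect_false(any(b$flagged))
  # interpolated boundary should agree with a direct root solve
  root <- uniroot(function(t) oracle_p_retention(t, 0.32, 4, 43) - 0.5,
                  c(1, 20))$root
  expect_equal(b$boundary_theta[b$nu == 0.32], root, tolerance = 0.2)
})

test_that("rows without a crossing report NA", {
  # dtmax(16, 60) ~ 65 yr >> 20 yr: retention everywhere at tiny nu
  g <- sweep_grid(grid_spec(seq(1, 20, length.out = 30), 0.01,
                            tau = 16, eta_max = 60))
  b <- find_boundary(g)
  expect_true(is.na(b$boundary_theta))
})

test_that("cross-validation agrees exactly at zero variability and within tolerance elsewhere", {
  pts0 <- data.frame(theta = c(4, 16), nu = c(0, 0), tau = c(4, 4),
                     eta_max = c(43, 43))
  cv0 <- cross_validate(pts0, seed = 4)
  expect_identical(cv0$discrepancy, c(0, 0))
  expect_false(any(cv0$flagged))

  pts <- sample_parameter_points(12, seed = 91)
  cv <- cross_validate(pts, seed = 92)
  expect_gte(attr(cv, "pass_fraction"), 11 / 12)
  expect_true(all(cv$p_r_numerical >= 0 & cv$p_r_numerical <= 1))
})

test_that("analytical grids are monotone across the parameter plane", {
  set.seed(55)
  for (i in 1:6) {
    tau <- runif(1, 1, 16)
    eta <- sample(3:60, 1)
    g <- sweep_grid(grid_spec(seq(1, 20, length.out = 25),
                              seq(0, 2, length.out = 25),
                              tau = tau, eta_max = eta))
    # non-increasing along theta (columns) and nu (rows), up to the
    # numerical noise floor of the deep-loss region
    expect_true(all(apply(g$p_r, 1, diff) <= 1e-9))
    expect_true(all(apply(g$p_r, 2, diff) <= 1e-9))
  }
})

test_that("the transition zone widens (in forgetting-time units) as variability increases", {
  # at fixed theta = 4 and an 8-expert pool, the span of tau over which
  # P_r climbs from 0.05 to 0.95 grows with nu
  p_r_at_tau <- function(tau, nu) {
    p <- suppressWarnings(model_params(theta = 4, nu = nu, tau = tau, eta_max = 8))
    retention_probability_analytic(p)$p_r
  }
  tau_width <- function(nu) {
    hi <- uniroot(function(ta) p_r_at_tau(ta, nu) - 0.95, c(0.05, 100))$root
    lo <- uniroot(function(ta) p_r_at_tau(ta, nu) - 0.05, c(0.05, 100))$root
    hi - lo
  }
  widths <- vapply(c(0.1, 0.3, 0.6, 1.2, 2), tau_width, numeric(1))
  expect_true(all(diff(widths) > 0))
})

test_that("doubling the variability takes roughly four times the experts to retain", {
  # pool size whose 0.5-level retention holds at theta = 4, tau = 4
  eta_needed <- function(nu) {
    exp(uniroot(function(log_e) {
      p <- suppressWarnings(model_params(theta = 4, nu = nu, tau = 4,
                                         eta_max = exp(log_e)))
      retention_probability_analytic(p)$p_r - 0.5
    }, c(log(1.01), 30))$root)
  }
  e_low <- eta_needed(0.6)
  e_high <- eta_needed(1.2)
  expect_equal(e_low, 14, tolerance = 0.1)  # ~14 experts suffice at nu = 0.6
  expect_gt(e_high / e_low, 3.5)            # doubling nu: ~4-5x the experts
  expect_lt(e_high / e_low, 6)
})
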