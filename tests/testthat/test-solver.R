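test_that("zero drift with symmetric constant bounds splits evenly", {
  p <- gap_params(alpha = 0, beta = 0.05, theta_crit = 8, b0 = 1,
                  mu_nd = 0.2, sigma_nd = 0, variant = "var_drift_const_bound")
  s <- solve_fpt(p, condition(4, 120), t_max = 20)
  expect_equal(s$p_go, 0.5, tolerance = 1e-3)
  expect_lt(s$p_censored, 1e-4)
})

test_that("constant-coefficient solution converges to the closed form", {
  # P(upper) = 1/(1+exp(-2 mu B)), mean FPT = (B/mu) tanh(mu B)
  p <- unit_const_params()
  cnd <- condition(4, 120)
  p_true <- 1 / (1 + exp(-2))
  m_true <- tanh(1)
  err <- sapply(list(c(0.01, 0.02), c(0.005, 0.01)), function(g) {
    s <- solve_fpt(p, cnd, dt = g[1], dx = g[2], t_max = 12)
    mean_dt <- sum(s$time_grid * s$go_density) * s$dt / s$p_go
    c(abs(s$p_go - p_true), abs(mean_dt - m_true) / m_true)
  })
  expect_lt(err[1, 2], 1e-3)        # p_go within 1e-3 at the default grid
  expect_lt(err[2, 2], 0.01)        # mean decision time within 1%
  expect_true(all(err[, 2] <= err[, 1] + 1e-12))  # finer grid is closer
})

test_that("solutions conserve probability mass", {
  grid <- condition_grid(c(4, 6), c(90, 150))
  for (cnd in grid) {
    s <- solve_fpt(truth_params(), cnd)
    expect_equal(s$p_go + s$p_stay, 1, tolerance = 1e-3)
    expect_true(all(s$go_density >= 0))
    expect_equal(sum(s$go_density) * s$dt, s$p_go, tolerance = 1e-3)
    expect_equal(sum(s$rt_density_observed) * s$dt, s$p_go, tolerance = 1e-3)
  }
})

test_that("extreme drift magnitudes are refused, not silently mangled", {
  p <- gap_params(alpha = 5, beta = 1, theta_crit = 2, b0 = 2, k = 1, tau = 4,
                  mu_nd = 0.3, sigma_nd = 0.05)
  expect_error(solve_fpt(p, condition(4, 150)), "grid resolution")
})

test_that("go probability is monotone in both gap dimensions", {
  p <- truth_params()
  tab <- predict_conditions(p, condition_grid(c(4, 5, 6), c(90, 120, 150)),
                            dt = 0.01, dx = 0.02)
  m <- matrix(tab$p_go, 3, 3, byrow = TRUE)  # rows: tta0, cols: d0
  expect_true(all(diff(m) > -1e-6))          # non-decreasing in tta0
  expect_true(all(t(diff(t(m))) > -1e-6))    # non-decreasing in d0
})

test_that("non-decision convolution shifts, smooths and conserves mass", {
  p_shift <- gap_params(alpha = 1, beta = 0, theta_crit = 8, b0 = 2, k = 1,
                        tau = 4, mu_nd = 0.3, sigma_nd = 0)
  dt <- 0.005
  dens <- rep(0, 400)
  dens[100] <- 1 / dt  # point mass at t = 0.5
  out <- convolve_nondecision(dens, dt, p_shift)
  expect_equal(out$grid[which.max(out$density)], 0.8, tolerance = 1e-9)
  expect_equal(sum(out$density) * dt, 1, tolerance = 1e-3)

  p_sm <- gap_params(alpha = 1, beta = 0, theta_crit = 8, b0 = 2, k = 1,
                     tau = 4, mu_nd = 0.3, sigma_nd = 0.05)
  out2 <- convolve_nondecision(dens, dt, p_sm)
  expect_equal(sum(out2$density) * dt, 1, tolerance = 1e-3)
  # delta * normal = normal(0.8, 0.05); check density shape at a few points
  ref <- dnorm(out2$grid, 0.8, 0.05)
  expect_lt(max(abs(out2$density - ref)) / max(ref), 0.02)
})

test_that("predicted summaries read quantiles off the observed-RT CDF", {
  # uniform observed density on [0, 1]: quantile at level q is q
  sol <- structure(list(p_go = 1, rt_grid = seq(0.005, 1, by = 0.005),
                        rt_density_observed = rep(1, 200), dt = 0.005),
                   class = "fpt_solution")
  ps <- predicted_summary(sol, c(0.1, 0.5, 0.9))
  expect_equal(unname(ps$rt_quantiles[2]), 0.5, tolerance = 0.01)

  # normal(0.8, 0.05) observed density: level 0.9 at 0.8 + 1.2816 * 0.05
  grid <- seq(0.005, 1.5, by = 0.005)
  sol2 <- structure(list(p_go = 1, rt_grid = grid,
                         rt_density_observed = dnorm(grid, 0.8, 0.05),
                         dt = 0.005), class = "fpt_solution")
  ps2 <- predicted_summary(sol2, c(0.9))
  expect_equal(unname(ps2$rt_quantiles[1]), qnorm(0.9, 0.8, 0.05),
               tolerance = 0.005)

  # degenerate: no go mass -> quantiles flagged undefined
  sol3 <- structure(list(p_go = 0, rt_grid = grid,
                         rt_density_observed = rep(0, length(grid)),
                         dt = 0.005), class = "fpt_solution")
  ps3 <- predicted_summary(sol3, c(0.5))
  expect_equal(ps3$p_go, 0)
  expect_true(is.na(ps3$rt_quantiles[1]))
})

test_that("trial simulation is seed-reproducible and matches symmetry", {
  p <- gap_params(alpha = 0, beta = 0.05, theta_crit = 8, b0 = 1,
                  mu_nd = 0.2, sigma_nd = 0.02, variant = "var_drift_const_bound")
  cnd <- condition(5, 120)
  a <- simulate_trials(p, cnd, 2000, dt = 0.005, seed = 123, t_max = 15)
  b <- simulate_trials(p, cnd, 2000, dt = 0.005, seed = 123, t_max = 15)
  expect_identical(a, b)
  se <- sqrt(0.25 / 2000)
  expect_lt(abs(mean(a$decision == "go") - 0.5), 3 * se)
  expect_true(all(is.na(a$rt[a$decision == "stay"])))
  expect_true(all(!is.na(a$rt[a$decision == "go"])))
})

test_that("FPT solutions export to CSV", {
  s <- solve_fpt(truth_params(), condition(4, 120), dt = 0.01, dx = 0.02)
  path <- tempfile(fileext = ".csv")
  fpt_to_csv(s, path)
  df <- read.csv(path)
  expect_named(df, c("t", "go_density", "rt_density_observed"))
  expect_equal(sum(df$rt_density_observed) * 0.01, s$p_go, tolerance = 1e-3)
})
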