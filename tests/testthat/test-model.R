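test_that("drift follows the combined-gap rule and its variants", {
  cnd <- condition(4, 120)
  p0 <- gap_params(alpha = 0, beta = 0.05, theta_crit = 8, b0 = 2,
                   k = 2, tau = 4, mu_nd = 0.3, sigma_nd = 0.05)
  expect_equal(drift_rate(p0, cnd, c(0, 1, 3)), c(0, 0, 0))

  p <- gap_params(alpha = 1, beta = 0.05, theta_crit = 8, b0 = 2,
                  k = 2, tau = 4, mu_nd = 0.3, sigma_nd = 0.05)
  # TTA = 4, d = 120 at t = 0: 1 * (4 + 6 - 8) = 2
  expect_equal(drift_rate(p, cnd, 0), 2)
  # sign-change point: TTA + beta d = theta_crit
  pz <- gap_params(alpha = 1.3, beta = 0.05, theta_crit = 10, b0 = 2,
                   k = 2, tau = 4, mu_nd = 0.3, sigma_nd = 0.05)
  expect_equal(drift_rate(pz, cnd, 0), 0)

  # constant-drift variant ignores the kinematics
  pc <- gap_params(drift_const = 0.7, b0 = 2, mu_nd = 0.3, sigma_nd = 0.05,
                   variant = "const_drift_const_bound")
  expect_equal(drift_rate(pc, cnd, c(0, 2, 3.9)), rep(0.7, 3))
})

test_that("drift is affine in t before arrival", {
  p <- truth_params()
  cnd <- condition(5, 150)
  d <- drift_rate(p, cnd, c(0, 1, 2))
  expect_equal(d[2] - d[1], d[3] - d[2], tolerance = 1e-12)
})

test_that("boundary gain is the logistic of TTA and scales the bound", {
  p <- gap_params(alpha = 1, beta = 0.05, theta_crit = 8, b0 = 2,
                  k = 2, tau = 4, mu_nd = 0.3, sigma_nd = 0.05)
  expect_equal(boundary_gain(p, 4), 0.5)
  expect_equal(boundary_gain(p, 5), 1 / (1 + exp(-2)))
  expect_equal(boundary_gain(p, 1e6), 1)
  expect_equal(boundary_gain(p, -1e6), 0)
  # strictly increasing in TTA
  tta <- seq(-3, 10, by = 0.25)
  expect_true(all(diff(boundary_gain(p, tta)) > 0))

  cnd <- condition(5, 120)  # tta_at(., 1) = 4 = tau
  expect_equal(boundary_at(p, cnd, 1), 1)           # b0/2 at TTA = tau
  expect_equal(boundary_at(p, cnd, 0), 2 * 1 / (1 + exp(-2)))
  # boundary is non-increasing in t for the full model
  t <- seq(0, 5, by = 0.1)
  expect_true(all(diff(boundary_at(p, cnd, t)) < 0))

  pc <- gap_params(alpha = 1, beta = 0.05, theta_crit = 8, b0 = 2,
                   mu_nd = 0.3, sigma_nd = 0.05,
                   variant = "var_drift_const_bound")
  expect_equal(boundary_at(pc, cnd, t), rep(2, length(t)))
})

test_that("k -> 0+ collapses the full boundary onto a constant b0/2", {
  pfull <- gap_params(alpha = 1, beta = 0.05, theta_crit = 8, b0 = 2,
                      k = 1e-9, tau = 4, mu_nd = 0.3, sigma_nd = 0.05)
  phalf <- gap_params(alpha = 1, beta = 0.05, theta_crit = 8, b0 = 1,
                      mu_nd = 0.3, sigma_nd = 0.05,
                      variant = "var_drift_const_bound")
  cnd <- condition(6, 150)
  t <- seq(0, 6, by = 0.5)
  expect_true(all(abs(boundary_at(pfull, cnd, t) - boundary_at(phalf, cnd, t)) < 1e-6))
})

test_that("parameter invariants are enforced", {
  expect_error(gap_params(alpha = -1, beta = 0, theta_crit = 8, b0 = 2,
                          k = 1, tau = 4, mu_nd = 0.3, sigma_nd = 0.1), "alpha")
  expect_error(gap_params(alpha = 1, beta = 0, theta_crit = 8, b0 = 0,
                          k = 1, tau = 4, mu_nd = 0.3, sigma_nd = 0.1), "b0")
  expect_error(gap_params(alpha = 1, beta = 0, theta_crit = 8, b0 = 2,
                          k = 0, tau = 4, mu_nd = 0.3, sigma_nd = 0.1), "k")
  expect_error(gap_params(alpha = 1, beta = 0, theta_crit = 8, b0 = 2,
                          k = 1, tau = 4, mu_nd = 0.3, sigma_nd = -0.1), "sigma_nd")
  expect_error(gap_params(b0 = 2, mu_nd = 0.3, sigma_nd = 0.1,
                          variant = "const_drift_const_bound"), "drift_const")
})

test_that("free parameter counts match the variant definitions", {
  expect_length(free_param_names("full"), 8)
  expect_length(free_param_names("var_drift_const_bound"), 6)
  expect_length(free_param_names("const_drift_const_bound"), 4)
})

test_that("parameters survive a JSON round trip", {
  p <- truth_params()
  q <- params_from_json(params_to_json(p))
  expect_equal(params_to_vec(q), params_to_vec(p))
  expect_equal(q$variant, p$variant)
})

test_that("non-decision sampling honors the truncated normal contract", {
  p <- gap_params(alpha = 1, beta = 0, theta_crit = 8, b0 = 2, k = 1, tau = 4,
                  mu_nd = 0.3, sigma_nd = 0)
  expect_equal(sample_nondecision_time(p, 5), rep(0.3, 5))

  p2 <- gap_params(alpha = 1, beta = 0, theta_crit = 8, b0 = 2, k = 1, tau = 4,
                   mu_nd = 0.3, sigma_nd = 0.05)
  x <- sample_nondecision_time(p2, 1e5, seed = 99)
  expect_lt(abs(mean(x) - 0.3), 0.01)

  p3 <- gap_params(alpha = 1, beta = 0, theta_crit = 8, b0 = 2, k = 1, tau = 4,
                   mu_nd = 0, sigma_nd = 0.1)
  expect_true(all(sample_nondecision_time(p3, 1e4, seed = 1) >= 0))

  # same seed, same draws
  expect_equal(sample_nondecision_time(p2, 10, seed = 5),
               sample_nondecision_time(p2, 10, seed = 5))
})
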