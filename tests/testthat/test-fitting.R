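make_trials <- function(decisions, rts, tta = 4, d = 120, id = "p1") {
  data.frame(participant_id = id, tta_condition = tta, d_condition = d,
             decision = decisions, rt = rts)
}

test_that("condition summaries count, quantile and flag correctly", {
  tr <- make_trials(c(rep("go", 6), rep("stay", 4)),
                    c(seq(0.5, 1.0, by = 0.1), rep(NA, 4)))
  s <- summarize_conditions(tr)
  expect_equal(s$n_trials, 10)
  expect_equal(s$n_go, 6)
  expect_equal(s$p_go, 0.6)
  expect_true(s$quantiles_valid)
  expect_equal(s$q_0.5, 0.75)  # linear interpolation of order statistics
  # quantile columns non-decreasing across levels
  q <- as.numeric(s[1, paste0("q_", c(0.1, 0.3, 0.5, 0.7, 0.9))])
  expect_true(all(diff(q) >= 0))

  s3 <- summarize_conditions(make_trials(c("go", "go", "go", "stay"),
                                         c(0.5, 0.6, 0.7, NA)))
  expect_false(s3$quantiles_valid)

  s0 <- summarize_conditions(make_trials(rep("stay", 5), rep(NA, 5)))
  expect_equal(s0$p_go, 0)
  expect_true(is.na(s0$q_0.5))
  empty <- data.frame(tta_condition = numeric(0), d_condition = numeric(0),
                      decision = character(0), rt = numeric(0))
  expect_error(summarize_conditions(empty), "no trials")
})

test_that("summaries are invariant to trial order and participant labels", {
  set.seed(42)
  tr <- data.frame(
    participant_id = sample(c("a", "b"), 60, TRUE),
    tta_condition = sample(c(4, 6), 60, TRUE),
    d_condition = sample(c(90, 150), 60, TRUE),
    decision = sample(c("go", "stay"), 60, TRUE), rt = NA_real_)
  tr$rt[tr$decision == "go"] <- runif(sum(tr$decision == "go"), 0.4, 1.5)
  a <- summarize_conditions(tr)
  b <- summarize_conditions(tr[sample(nrow(tr)), ])
  expect_equal(a, b)
  tr2 <- tr; tr2$participant_id <- chartr("ab", "xy", tr2$participant_id)
  expect_equal(summarize_conditions(tr2), a)
})

test_that("the weighted least-sum score matches its formula", {
  gs <- noise_free_summaries(dt = 0.01, dx = 0.02)
  p <- truth_params()
  # predicted == observed -> zero
  expect_lt(wls_loss(p, gs, dt = 0.01, dx = 0.02), 1e-8)
  # doubling both weights doubles the loss
  gs2 <- gs; gs2$p_go <- gs2$p_go + 0.03
  l1 <- wls_loss(p, gs2, weights = c(p = 2, q = 1), dt = 0.01, dx = 0.02)
  l2 <- wls_loss(p, gs2, weights = c(p = 4, q = 2), dt = 0.01, dx = 0.02)
  expect_equal(l2, 2 * l1, tolerance = 1e-12)
  # perturbing one observed quantile by delta adds w_q * n_go * delta^2
  delta <- 0.07
  gs3 <- gs; gs3$q_0.5[5] <- gs3$q_0.5[5] + delta
  l3 <- wls_loss(p, gs3, dt = 0.01, dx = 0.02)
  expect_equal(l3, 1 * gs$n_go[5] * delta^2, tolerance = 1e-6)
})

test_that("a single freed parameter is recovered from noise-free targets", {
  truth <- truth_params()
  gs <- noise_free_summaries(dt = 0.01, dx = 0.02)
  fixed <- params_to_vec(truth)
  fit <- fit_model(gs, "full",
                   fixed = fixed[setdiff(names(fixed), "theta_crit")],
                   settings = de_settings(pop_size = 12, max_gen = 25),
                   seed = 3, dt = 0.01, dx = 0.02)
  expect_lt(abs(fit$params$theta_crit - truth$theta_crit) / truth$theta_crit,
            0.02)
  expect_equal(fit$params$alpha, truth$alpha)  # fixed stays fixed
})

test_that("fits are reproducible and respect their bounds", {
  gs <- noise_free_summaries(dt = 0.01, dx = 0.02)
  st <- de_settings(pop_size = 8, max_gen = 4)
  f1 <- fit_model(gs, "const_drift_const_bound", settings = st, seed = 11,
                  dt = 0.01, dx = 0.02)
  f2 <- fit_model(gs, "const_drift_const_bound", settings = st, seed = 11,
                  dt = 0.01, dx = 0.02)
  expect_equal(params_to_vec(f1$params), params_to_vec(f2$params))
  expect_equal(f1$loss, f2$loss)
  v <- params_to_vec(f1$params)
  for (nm in names(v)) {
    b <- f1$search_bounds[[nm]]
    expect_gte(v[[nm]], b[1]); expect_lte(v[[nm]], b[2])
  }
  # reported loss is the recomputed loss
  expect_equal(wls_loss(f1$params, gs, dt = 0.01, dx = 0.02), f1$loss,
               tolerance = 1e-9)
})

test_that("per-participant fitting maps participants to fits", {
  set.seed(8)
  mk <- function(id) {
    n <- 40
    data.frame(participant_id = id,
               tta_condition = sample(c(4, 5, 6), n, TRUE),
               d_condition = sample(c(90, 120, 150), n, TRUE),
               decision = sample(c("go", "stay"), n, TRUE),
               rt = NA_real_) -> tr
    tr$rt[tr$decision == "go"] <- runif(sum(tr$decision == "go"), 0.4, 1.5)
    tr
  }
  tr <- rbind(mk("p1"), mk("p2"))
  st <- de_settings(pop_size = 8, max_gen = 3)
  fits <- fit_per_participant(tr, variant = "const_drift_const_bound",
                              seed = 5, settings = st, dt = 0.01, dx = 0.02)
  expect_named(fits, c("p1", "p2"))
  # duplicated participant under a new id fits identically with equal seeds
  tr_dup <- tr[tr$participant_id == "p1", ]
  f_a <- fit_model(summarize_conditions(tr_dup), "const_drift_const_bound",
                   settings = st, seed = 21, dt = 0.01, dx = 0.02)
  tr_dup$participant_id <- "zz"
  f_b <- fit_model(summarize_conditions(tr_dup), "const_drift_const_bound",
                   settings = st, seed = 21, dt = 0.01, dx = 0.02)
  expect_equal(params_to_vec(f_a$params), params_to_vec(f_b$params))
  # participants with too few conditions are skipped and reported
  tr_one <- mk("p3"); tr_one$tta_condition <- 4; tr_one$d_condition <- 90
  expect_message(
    fits2 <- fit_per_participant(rbind(tr, tr_one),
                                 variant = "const_drift_const_bound",
                                 seed = 5, settings = st,
                                 dt = 0.01, dx = 0.02),
    "skipped")
  expect_false("p3" %in% names(fits2))
})

test_that("the full model fits no worse than its nested restrictions", {
  gs <- noise_free_summaries(dt = 0.01, dx = 0.02)
  st <- de_settings(pop_size = 24, max_gen = 25)
  losses <- sapply(c("full", "var_drift_const_bound", "const_drift_const_bound"),
    function(v) fit_model(gs, v, settings = st, seed = 14,
                          dt = 0.01, dx = 0.02, polish = TRUE)$loss)
  expect_lte(losses[["full"]], losses[["var_drift_const_bound"]])
  expect_lte(losses[["full"]], losses[["const_drift_const_bound"]])
})

test_that("fit results serialize to JSON", {
  gs <- noise_free_summaries(dt = 0.01, dx = 0.02)
  f <- fit_model(gs, "const_drift_const_bound",
                 settings = de_settings(pop_size = 8, max_gen = 3), seed = 2,
                 dt = 0.01, dx = 0.02)
  path <- tempfile(fileext = ".json")
  fit_to_json(f, path)
  x <- jsonlite::fromJSON(path)
  expect_equal(x$variant, "const_drift_const_bound")
  expect_equal(x$loss, f$loss)
  expect_equal(x$params$b0, f$params$b0)
})
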