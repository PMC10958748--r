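# Shared fixtures built in code.

# Group-mean parameters of the synthetic population (full model).
truth_params <- function() default_group_params()

# A homogeneous population (all participants at the group means).
homogeneous_spec <- function(n = 16) {
  population_spec(n_participants = n,
                  sds = setNames(rep(0, 8), free_param_names("full")))
}

# Constant-coefficient model: drift 1, bounds +/- 1, no non-decision time.
unit_const_params <- function() {
  gap_params(drift_const = 1, b0 = 1, mu_nd = 0, sigma_nd = 0,
             variant = "const_drift_const_bound")
}

# Noise-free fitting targets: the model's own per-condition predictions,
# packaged as a gap_summaries data frame with plausible trial counts.
noise_free_summaries <- function(p = truth_params(),
                                 grid = condition_grid(c(4, 5, 6), c(90, 120, 150)),
                                 n_per_condition = 213,
                                 levels = c(0.1, 0.3, 0.5, 0.7, 0.9),
                                 dt = 0.005, dx = 0.01) {
  pred <- predict_conditions(p, grid, levels, dt, dx)
  out <- data.frame(tta0 = pred$tta0, d0 = pred$d0,
                    n_trials = n_per_condition,
                    n_go = round(pred$p_go * n_per_condition),
                    p_go = pred$p_go, mean_go_rt = pred$mean_rt,
                    quantiles_valid = round(pred$p_go * n_per_condition) >= 4)
  for (lv in levels) out[[paste0("q_", lv)]] <- pred[[paste0("q_", lv)]]
  attr(out, "levels") <- levels
  class(out) <- c("gap_summaries", class(out))
  out
}

# Empirical KS distance between a model CDF (grid, cdf) and a sample.
ks_distance <- function(grid, cdf, sample) {
  f <- approx(grid, cdf, xout = sort(sample), rule = 2, ties = "ordered")$y
  n <- length(sample)
  max(abs(f - (seq_len(n) - 0.5) / n))
}
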