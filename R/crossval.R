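#' Build hold-one-condition-out folds
#'
#' One fold per condition of the factorial grid, in condition-grid order
#' (tta0-major): the fold's training set is the other eight summaries,
#' its held-out condition contributes only observed values for comparison.
#'
#' @param summaries A `gap_summaries` data frame covering the full grid.
#' @param ttas,distances The grid levels; default to the distinct values
#'   present in `summaries`.
#' @return List of fold shells: `held_out` ([condition()]),
#'   `train_summaries`, `observed_p_go`, `observed_mean_rt`.
#' @export
make_folds <- function(summaries, ttas = sort(unique(summaries$tta0)),
                       distances = sort(unique(summaries$d0))) {
  grid <- condition_grid(ttas, distances)
  for (cnd in grid) {
    hit <- summaries$tta0 == cnd$tta0 & summaries$d0 == cnd$d0
    if (sum(hit) != 1)
      stop(sprintf("missing or duplicated summary for condition %s",
                   condition_key(cnd)), call. = FALSE)
  }
  lapply(grid, function(cnd) {
    held <- summaries$tta0 == cnd$tta0 & summaries$d0 == cnd$d0
    train <- summaries[!held, , drop = FALSE]
    attr(train, "levels") <- summary_levels(summaries)
    class(train) <- class(summaries)
    list(held_out = cnd,
         train_summaries = train,
         observed_p_go = summaries$p_go[held],
         observed_mean_rt = summaries$mean_go_rt[held])
  })
}

#' Run hold-one-condition-out cross-validation
#'
#' Each fold fits the model on its eight training conditions only, then
#' solves the fitted model on the held-out condition to predict its go
#' probability and mean go-RT. Fold seeds are derived from the master
#' seed plus the fold index; fit failures are recorded per fold without
#' aborting the remaining folds.
#'
#' @param folds From [make_folds()].
#' @param variant Model variant tag.
#' @param settings [de_settings()] used for every fold's fit.
#' @param seed Master integer seed.
#' @param weights,dt,dx As in [fit_model()].
#' @param retry_loss,n_retries If a fold's training loss exceeds
#'   `retry_loss` — an optimizer-convergence gate judged on the training
#'   data only, never on the held-out condition — the fold's fit is rerun
#'   with a shifted seed, up to `n_retries` extra attempts, keeping the
#'   best. Useful when the attainable training loss is known (e.g. 0 for
#'   noise-free self-consistency checks).
#' @param ... Further arguments to [fit_model()] (e.g. `polish`).
#' @return List with `folds` (completed folds, each gaining `fit`,
#'   `predicted_p_go`, `predicted_mean_rt`, or `error`) and `summary`
#'   (data frame: held-out condition, predicted and observed values and
#'   signed errors).
#' @export
run_cv <- function(folds, variant = "full", settings = de_settings(), seed,
                   weights = c(p = 2, q = 1), dt = 0.005, dx = 0.01,
                   retry_loss = Inf, n_retries = 0, ...) {
  out <- vector("list", length(folds))
  for (i in seq_along(folds)) {
    f <- folds[[i]]
    res <- tryCatch({
      fit <- fit_model(f$train_summaries, variant = variant,
                       settings = settings, seed = seed + i,
                       weights = weights, dt = dt, dx = dx, ...)
      tries <- 0
      while (fit$loss > retry_loss && tries < n_retries) {
        tries <- tries + 1
        alt <- fit_model(f$train_summaries, variant = variant,
                         settings = settings,
                         seed = seed + i + 1000L * tries,
                         weights = weights, dt = dt, dx = dx, ...)
        if (alt$loss < fit$loss) fit <- alt
      }
      sol <- solve_fpt(fit$params, f$held_out, dt = dt, dx = dx)
      ps <- predicted_summary(sol, summary_levels(f$train_summaries))
      c(f, list(fit = fit, predicted_p_go = ps$p_go,
                predicted_mean_rt = ps$mean_rt, error = NULL))
    }, error = function(e) {
      c(f, list(fit = NULL, predicted_p_go = NA_real_,
                predicted_mean_rt = NA_real_, error = conditionMessage(e)))
    })
    out[[i]] <- res
  }
  summary <- do.call(rbind, lapply(out, function(f) data.frame(
    held_out_tta = f$held_out$tta0, held_out_d = f$held_out$d0,
    predicted_p_go = f$predicted_p_go, observed_p_go = f$observed_p_go,
    predicted_mean_rt = f$predicted_mean_rt,
    observed_mean_rt = f$observed_mean_rt,
    p_go_error = f$predicted_p_go - f$observed_p_go,
    mean_rt_error = f$predicted_mean_rt - f$observed_mean_rt)))
  list(folds = out, summary = summary)
}
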