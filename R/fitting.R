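DEFAULT_QUANTILE_LEVELS <- c(0.1, 0.3, 0.5, 0.7, 0.9)

#' Summarize trials into per-condition fitting targets
#'
#' One row per condition present in the data: trial counts, go
#' probability, mean go-RT, and go-RT quantiles at the requested levels.
#' Quantiles are flagged invalid for conditions with fewer than `min_go`
#' go decisions, mirroring the convention of omitting response times for
#' sparsely populated cells.
#'
#' @param trials Data frame with columns `tta_condition`, `d_condition`,
#'   `decision` ("go"/"stay") and `rt` (seconds, NA for stays). Excluded
#'   trials are assumed to be already removed.
#' @param levels Quantile probabilities.
#' @param min_go Minimum number of go trials for valid quantiles.
#' @return A data frame of class `gap_summaries` with columns `tta0`, `d0`,
#'   `n_trials`, `n_go`, `p_go`, `mean_go_rt`, `quantiles_valid` and one
#'   `q_<level>` column per level; the levels are kept in
#'   `attr(, "levels")`.
#' @export
summarize_conditions <- function(trials, levels = DEFAULT_QUANTILE_LEVELS,
                                 min_go = 4) {
  if (nrow(trials) == 0) stop("no trials to summarize", call. = FALSE)
  key <- interaction(trials$tta_condition, trials$d_condition, drop = TRUE)
  rows <- lapply(split(trials, key), function(g) {
    go <- g$decision == "go"
    rts <- g$rt[go & !is.na(g$rt)]
    n_go <- sum(go)
    valid <- n_go >= min_go
    q <- if (valid) quantile(rts, levels, names = FALSE, type = 7)
         else rep(NA_real_, length(levels))
    out <- data.frame(tta0 = g$tta_condition[1], d0 = g$d_condition[1],
                      n_trials = nrow(g), n_go = n_go, p_go = n_go / nrow(g),
                      mean_go_rt = if (n_go > 0) mean(rts) else NA_real_,
                      quantiles_valid = valid)
    for (i in seq_along(levels)) out[[paste0("q_", levels[i])]] <- q[i]
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$tta0, out$d0), ]
  rownames(out) <- NULL
  attr(out, "levels") <- levels
  class(out) <- c("gap_summaries", class(out))
  out
}

#' Group-averaged fitting targets
#'
#' Per condition: go probability as the unweighted mean of within-
#' participant go probabilities, mean go-RT as the mean of within-
#' participant mean RTs, and vincentized go-RT quantiles (per-participant
#' quantile functions averaged across participants; participants without
#' go responses in a condition are dropped from that condition's
#' vincentization).
#'
#' @param trials Data frame as in [summarize_conditions()], additionally
#'   with `participant_id`.
#' @inheritParams summarize_conditions
#' @return A `gap_summaries` data frame (see [summarize_conditions()]);
#'   `n_trials`/`n_go` are totals across participants and serve as loss
#'   weights.
#' @export
group_summaries <- function(trials, levels = DEFAULT_QUANTILE_LEVELS,
                            min_go = 4) {
  if (nrow(trials) == 0) stop("no trials to summarize", call. = FALSE)
  key <- interaction(trials$tta_condition, trials$d_condition, drop = TRUE)
  rows <- lapply(split(trials, key), function(g) {
    by_pp <- split(g, g$participant_id, drop = TRUE)
    p_gos <- vapply(by_pp, function(h) mean(h$decision == "go"), numeric(1))
    qs <- lapply(by_pp, function(h) {
      rts <- h$rt[h$decision == "go" & !is.na(h$rt)]
      if (length(rts) == 0) NULL else participant_quantiles(rts, levels)
    })
    qs <- qs[!vapply(qs, is.null, logical(1))]
    rt_means <- vapply(by_pp, function(h) {
      rts <- h$rt[h$decision == "go" & !is.na(h$rt)]
      if (length(rts) == 0) NA_real_ else mean(rts)
    }, numeric(1))
    n_go <- sum(g$decision == "go")
    valid <- n_go >= min_go && length(qs) > 0
    q <- if (valid) colMeans(do.call(rbind, qs)) else rep(NA_real_, length(levels))
    out <- data.frame(tta0 = g$tta_condition[1], d0 = g$d_condition[1],
                      n_trials = nrow(g), n_go = n_go,
                      p_go = mean(p_gos),
                      mean_go_rt = if (all(is.na(rt_means))) NA_real_
                                   else mean(rt_means, na.rm = TRUE),
                      quantiles_valid = valid)
    for (i in seq_along(levels)) out[[paste0("q_", levels[i])]] <- q[i]
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$tta0, out$d0), ]
  rownames(out) <- NULL
  attr(out, "levels") <- levels
  class(out) <- c("gap_summaries", class(out))
  out
}

summary_levels <- function(summaries)
  attr(summaries, "levels") %||% DEFAULT_QUANTILE_LEVELS

#' Weighted least-sum fitting score
#'
#' For each condition: `w_p * n_trials * (p_go_obs - p_go_pred)^2 +
#' w_q * n_go * sum_levels (q_obs - q_pred)^2`. Quantile terms are dropped
#' where the observed quantiles are invalid or the predicted go
#' probability is below `1e-4`. Stay decisions enter only through the go
#' probability (no stay-RT information exists).
#'
#' @param p A [gap_params()].
#' @param summaries A `gap_summaries` data frame.
#' @param weights Named vector `c(p = ..., q = ...)`.
#' @param dt,dx Solver grid settings.
#' @return Non-negative scalar loss; deterministic given the grid.
#' @export
wls_loss <- function(p, summaries, weights = c(p = 2, q = 1),
                     dt = 0.005, dx = 0.01) {
  levels <- summary_levels(summaries)
  qmat <- as.matrix(summaries[, paste0("q_", levels), drop = FALSE])
  obs <- cbind(summaries$n_trials, summaries$n_go, summaries$p_go,
               as.numeric(summaries$quantiles_valid), qmat)
  variant_code <- match(p$variant, MODEL_VARIANTS) - 1L
  num <- function(x) if (is.finite(x)) x else 0
  wls_loss_cpp(summaries$tta0, summaries$d0, obs, levels,
               num(p$alpha), num(p$beta), num(p$theta_crit), p$b0,
               num(p$k), num(p$tau), p$mu_nd, p$sigma_nd,
               num(p$drift_const), variant_code,
               weights[["p"]], weights[["q"]], dt, dx)
}

# Single-condition predicted summary through the compiled path (used in
# the optimization hot loop; equivalent to solve_fpt + predicted_summary).
fast_summary <- function(p, cnd, dt, dx, levels) {
  nt <- ceiling(cnd$tta0 / dt)
  tt <- dt * (0:nt)
  mu <- drift_rate(p, cnd, tt)
  if (max(abs(mu)) * dx >= 2)
    stop("grid resolution insufficient for this drift magnitude; ",
         "decrease dx or restrict the parameters", call. = FALSE)
  solve_summary_cpp(mu, boundary_at(p, cnd, tt), dt, dx, p$b0,
                    p$mu_nd, p$sigma_nd, levels)
}

#' Default parameter search bounds
#'
#' Spans the physically plausible range for the 3x3 design (TTA 4-6 s,
#' go-RTs under 2 s).
#'
#' @param variant A model variant tag.
#' @return Named list of `c(lower, upper)` per free parameter.
#' @export
default_search_bounds <- function(variant = "full") {
  all <- list(alpha = c(0, 5), beta = c(0, 1), theta_crit = c(2, 20),
              b0 = c(0.5, 5), k = c(0.05, 5), tau = c(1, 10),
              mu_nd = c(0, 1.5), sigma_nd = c(0.01, 0.5),
              drift_const = c(-5, 5))
  all[free_param_names(variant)]
}

#' Fit a model variant to condition summaries
#'
#' Differential-evolution minimization of [wls_loss()] within box bounds.
#'
#' @param summaries A `gap_summaries` data frame.
#' @param variant Model variant tag.
#' @param bounds Named list of `c(lower, upper)`; defaults to
#'   [default_search_bounds()].
#' @param weights Loss weights, see [wls_loss()].
#' @param settings [de_settings()].
#' @param seed Integer seed (required; fits are reproducible).
#' @param dt,dx Solver grid used during fitting.
#' @param fixed Optional named numeric vector of parameters held at the
#'   given values instead of being searched.
#' @param polish If `TRUE`, refine the differential-evolution solution with
#'   a bounded Nelder-Mead pass (useful when the evaluation budget is
#'   tight); the refinement is deterministic given the DE result.
#' @return An object of class `gap_fit`: `params`, `variant`, `loss`,
#'   `n_evaluations`, `converged`, `seed`, `search_bounds`, `weights`,
#'   grid settings.
#' @export
fit_model <- function(summaries, variant = "full",
                      bounds = default_search_bounds(variant),
                      weights = c(p = 2, q = 1),
                      settings = de_settings(), seed,
                      dt = 0.005, dx = 0.01, fixed = NULL, polish = FALSE) {
  nm <- free_param_names(variant)
  stopifnot(setequal(names(bounds), nm))
  if (!is.null(fixed)) stopifnot(all(names(fixed) %in% nm))
  free <- setdiff(nm, names(fixed))
  if (length(free) == 0) stop("no free parameters left to fit", call. = FALSE)
  bounds <- bounds[free]
  lower <- vapply(bounds, `[`, numeric(1), 1)
  upper <- vapply(bounds, `[`, numeric(1), 2)
  assemble <- function(v) {
    full <- setNames(numeric(length(nm)), nm)
    full[free] <- v
    if (!is.null(fixed)) full[names(fixed)] <- fixed
    full
  }
  obj <- function(v) wls_loss(vec_to_params(assemble(v), variant), summaries,
                              weights = weights, dt = dt, dx = dx)
  res <- de_optimize(obj, lower, upper, settings = settings, seed = seed)
  if (polish && length(free) > 1) {
    pen_obj <- function(v) {
      if (any(v < lower) || any(v > upper)) return(1e12)
      out <- tryCatch(obj(v), error = function(e) 1e12)
      if (!is.finite(out)) 1e12 else out
    }
    # simplex descent, then quasi-Newton sharpening within the box
    loc <- stats::optim(res$par, pen_obj, method = "Nelder-Mead",
                        control = list(maxit = 800, reltol = 1e-9,
                                       parscale = upper - lower))
    if (loc$value < res$value) {
      res$par <- loc$par
      res$value <- loc$value
    }
    res$n_evaluations <- res$n_evaluations + loc$counts[["function"]]
    bfg <- tryCatch(
      stats::optim(res$par, pen_obj, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 200, factr = 1e4,
                                  parscale = upper - lower)),
      error = function(e) NULL)
    if (!is.null(bfg) && bfg$value < res$value) {
      res$par <- bfg$par
      res$value <- bfg$value
      res$n_evaluations <- res$n_evaluations + bfg$counts[["function"]]
    }
  }
  structure(list(params = vec_to_params(assemble(res$par), variant),
                 variant = variant,
                 loss = res$value, n_evaluations = res$n_evaluations,
                 generations = res$generations, converged = res$converged,
                 seed = seed, search_bounds = bounds, weights = weights,
                 dt = dt, dx = dx),
            class = "gap_fit")
}

#' @export
print.gap_fit <- function(x, ...) {
  cat(sprintf("Gap-acceptance model fit (%s): loss %.4g after %d evaluations%s\n",
              x$variant, x$loss, x$n_evaluations,
              if (x$converged) " (converged)" else ""))
  print(x$params)
  invisible(x)
}

#' Fit each participant individually
#'
#' @param trials Trial data frame with `participant_id` (excluded trials
#'   removed).
#' @param ... Passed to [fit_model()]; per-participant seeds are derived as
#'   `seed + participant index`.
#' @inheritParams fit_model
#' @param min_conditions Participants with fewer distinct conditions are
#'   skipped (reported in the `skipped` attribute).
#' @return Named list of `gap_fit`, one per fitted participant.
#' @export
fit_per_participant <- function(trials, variant = "full", seed,
                                levels = DEFAULT_QUANTILE_LEVELS,
                                min_conditions = 2, ...) {
  by_pp <- split(trials, trials$participant_id, drop = TRUE)
  skipped <- character(0)
  fits <- list()
  for (i in seq_along(by_pp)) {
    id <- names(by_pp)[i]
    g <- by_pp[[i]]
    ncond <- nrow(unique(g[, c("tta_condition", "d_condition")]))
    if (ncond < min_conditions) { skipped <- c(skipped, id); next }
    s <- summarize_conditions(g, levels = levels)
    fits[[id]] <- fit_model(s, variant = variant, seed = seed + i, ...)
  }
  if (length(skipped))
    message("skipped participants with too few conditions: ",
            paste(skipped, collapse = ", "))
  attr(fits, "skipped") <- skipped
  fits
}

#' Serialize a fit as JSON
#'
#' @param fit A `gap_fit`.
#' @param path Optional output path.
#' @export
fit_to_json <- function(fit, path = NULL) {
  x <- list(variant = fit$variant,
            params = as.list(params_to_vec(fit$params)),
            loss = fit$loss, n_evaluations = fit$n_evaluations,
            converged = fit$converged, seed = fit$seed,
            search_bounds = fit$search_bounds,
            weights = as.list(fit$weights), dt = fit$dt, dx = fit$dx)
  if (is.null(path)) return(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Model-predicted summaries for a set of conditions
#'
#' @param p A [gap_params()].
#' @param grid List of conditions.
#' @param levels Quantile probabilities.
#' @param dt,dx Solver grid.
#' @return Data frame with `tta0`, `d0`, `p_go`, `mean_rt` and quantile
#'   columns.
#' @export
predict_conditions <- function(p, grid, levels = DEFAULT_QUANTILE_LEVELS,
                               dt = 0.005, dx = 0.01) {
  rows <- lapply(grid, function(cnd) {
    sol <- solve_fpt(p, cnd, dt = dt, dx = dx)
    ps <- predicted_summary(sol, levels)
    out <- data.frame(tta0 = cnd$tta0, d0 = cnd$d0, p_go = ps$p_go,
                      mean_rt = ps$mean_rt)
    for (i in seq_along(levels))
      out[[paste0("q_", levels[i])]] <- unname(ps$rt_quantiles[i])
    out
  })
  do.call(rbind, rows)
}
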