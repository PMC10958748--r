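#' Instantaneous drift rate
#'
#' For the full and `var_drift_const_bound` variants the drift is
#' `alpha * ((TTA(t) + beta * d(t)) - theta_crit)`; TTA and distance are
#' clamped at zero past arrival so the perceptual input never flips sign in
#' the censoring tail. The `const_drift_const_bound` variant returns its
#' free constant drift.
#'
#' @param p A [gap_params()].
#' @param cnd A [condition()].
#' @param t Time since vehicle appearance, seconds (vectorized, >= 0).
#' @return Drift in evidence units per second.
#' @export
drift_rate <- function(p, cnd, t) {
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  if (p$variant == "const_drift_const_bound")
    return(rep(p$drift_const, length(t)))
  tta <- pmax(tta_at(cnd, t), 0)
  d <- pmax(distance_at(cnd, t), 0)
  p$alpha * ((tta + p$beta * d) - p$theta_crit)
}

#' Logistic boundary gain
#'
#' `f(TTA) = 1 / (1 + exp(-k (TTA - tau)))`: close to 1 when the time gap
#' is comfortable (`TTA >> tau`), 1/2 at `TTA = tau`, and collapsing toward
#' 0 as the gap closes. Accepts TTA <= 0 (post-arrival), where the gain
#' tends to zero.
#'
#' @param p A [gap_params()].
#' @param tta Time-to-arrival, seconds (vectorized, any sign).
#' @return Gain in (0, 1), strictly increasing in `tta`.
#' @export
boundary_gain <- function(p, tta) {
  1 / (1 + exp(-p$k * (tta - p$tau)))
}

#' Decision boundary (upper; the lower bound is its negation)
#'
#' Full variant: `b0 * boundary_gain(p, TTA(t))`, collapsing as the
#' oncoming car approaches. Constant-bound variants: `b0` at all times.
#'
#' @inheritParams drift_rate
#' @return Boundary in evidence units, > 0.
#' @export
boundary_at <- function(p, cnd, t) {
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  if (p$variant != "full") return(rep(p$b0, length(t)))
  p$b0 * boundary_gain(p, tta_at(cnd, t))
}

#' Sample non-decision times
#'
#' Draws from `N(mu_nd, sigma_nd)` truncated below at 0 (rejection
#' sampling; the truncation is negligible for the fitted regime
#' `mu_nd >> sigma_nd`). With `sigma_nd = 0` returns `max(mu_nd, 0)`
#' deterministically.
#'
#' @param p A [gap_params()].
#' @param n Number of draws.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return Numeric vector of non-negative times, seconds.
#' @export
sample_nondecision_time <- function(p, n, seed = NULL) {
  with_seed(seed, {
    if (p$sigma_nd == 0) return(rep(max(p$mu_nd, 0), n))
    out <- rnorm(n, p$mu_nd, p$sigma_nd)
    bad <- which(out < 0)
    while (length(bad) > 0) {
      out[bad] <- rnorm(length(bad), p$mu_nd, p$sigma_nd)
      bad <- bad[out[bad] < 0]
    }
    out
  })
}
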