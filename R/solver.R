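#' Solve the first-passage problem for one condition
#'
#' Propagates the evidence density under the time-varying drift and
#' absorbing (possibly collapsing) boundaries with a Crank-Nicolson scheme
#' on a fixed evidence grid; the boundary is absorbed at the nearest grid
#' line. Integration stops at `t_max` (by default the arrival time
#' `tta0`); any undecided mass is censored into the stay outcome, since
#' the go option has physically expired once the car arrives.
#'
#' @param p A [gap_params()].
#' @param cnd A [condition()].
#' @param dt Time step, seconds.
#' @param dx Evidence grid spacing, evidence units.
#' @param t_max Integration horizon, seconds; defaults to `cnd$tta0`.
#' @return An object of class `fpt_solution` with fields:
#'   `time_grid` (seconds), `go_density` (first-passage density of go
#'   decisions, 1/s), `p_go`, `p_stay` (absorbed-at-lower plus censored
#'   mass), `p_censored`, `rt_grid` and `rt_density_observed` (go density
#'   convolved with the non-decision-time distribution), plus the grid
#'   settings used.
#' @examples
#' p <- gap_params(alpha = 0.5, beta = 0.05, theta_crit = 10, b0 = 2,
#'                 k = 0.8, tau = 5, mu_nd = 0.3, sigma_nd = 0.1)
#' sol <- solve_fpt(p, condition(5, 120))
#' sol$p_go
#' @export
solve_fpt <- function(p, cnd, dt = 0.005, dx = 0.01, t_max = NULL) {
  stopifnot(dt > 0, dx > 0)
  if (is.null(t_max)) t_max <- cnd$tta0
  nt <- ceiling(t_max / dt)
  tt <- dt * (0:nt)
  mu <- drift_rate(p, cnd, tt)
  bb <- boundary_at(p, cnd, tt)
  # cell Peclet condition for oscillation-free central differencing of the
  # advection term (diffusion coefficient 1/2): |mu| dx < 2
  if (max(abs(mu)) * dx >= 2)
    stop("grid resolution insufficient for this drift magnitude; ",
         "decrease dx or restrict the parameters", call. = FALSE)
  raw <- fpt_solve_cpp(mu, bb, dt, dx, p$b0)
  go_density <- pmax(raw$go_flux, 0)  # clear roundoff-scale negatives
  p_go <- raw$p_go
  rt <- convolve_nondecision(go_density, dt, p)
  structure(list(
    time_grid = dt * seq_len(nt),
    go_density = go_density,
    p_go = p_go,
    p_stay = raw$p_stay_absorbed + raw$p_undecided,
    p_censored = raw$p_undecided,
    rt_grid = rt$grid,
    rt_density_observed = rt$density,
    dt = dt, dx = dx, t_max = t_max,
    condition = cnd, params = p
  ), class = "fpt_solution")
}

#' @export
print.fpt_solution <- function(x, ...) {
  cat(sprintf("FPT solution (%s): p_go = %.4f, p_stay = %.4f (censored %.4f)\n",
              condition_key(x$condition), x$p_go, x$p_stay, x$p_censored))
  invisible(x)
}

#' Convolve a decision-time density with the non-decision time
#'
#' Discrete convolution of the go first-passage density with the
#' zero-truncated normal non-decision-time density, renormalized so the
#' total go mass is preserved. With `sigma_nd = 0` this is an exact shift
#' by `mu_nd` (rounded to the grid).
#'
#' @param go_density Density values on the step grid `dt * (1:nt)`.
#' @param dt Grid step, seconds.
#' @param p A [gap_params()] supplying `mu_nd`, `sigma_nd`.
#' @return List with `grid` (seconds) and `density` (1/s); the grid extends
#'   past the decision horizon to hold the convolution tail.
#' @export
convolve_nondecision <- function(go_density, dt, p) {
  n <- length(go_density)
  if (p$sigma_nd == 0) {
    shift <- round(max(p$mu_nd, 0) / dt)
    dens <- c(rep(0, shift), go_density)
  } else {
    K <- ceiling((max(p$mu_nd, 0) + 6 * p$sigma_nd) / dt)
    kt <- dt * (0:K)
    w <- dnorm(kt, p$mu_nd, p$sigma_nd)
    sw <- sum(w)
    if (sw == 0) { w <- rep(0, K + 1); w[1 + round(max(p$mu_nd, 0) / dt)] <- 1; sw <- 1 }
    w <- w / sw                      # discrete kernel weights, sum 1
    dens <- conv_open(go_density, w) # length n + K
    dens[dens < 0] <- 0
    tot <- sum(dens) * dt
    target <- sum(go_density) * dt
    if (tot > 0) dens <- dens * (target / tot)
  }
  list(grid = dt * seq_len(length(dens)), density = dens)
}

# Open (polynomial) convolution via FFT, out[m] = sum_i x[i] w[m - i + 1]
conv_open <- function(x, w) {
  n <- length(x) + length(w) - 1
  m <- stats::nextn(n, 2)
  xf <- stats::fft(c(x, rep(0, m - length(x))))
  wf <- stats::fft(c(w, rep(0, m - length(w))))
  out <- Re(stats::fft(xf * wf, inverse = TRUE)) / m
  out[seq_len(n)]
}

#' Simulate individual trials by Euler-Maruyama integration
#'
#' Each trial integrates the evidence with Gaussian increments of variance
#' `dt` and terminates at the first boundary crossing (post-step check) or
#' by censoring at `t_max` (a stay). Go trials receive an observed response
#' time `rt = decision_time + t_nd`.
#'
#' @inheritParams solve_fpt
#' @param n Number of trials.
#' @param seed Optional integer seed; the same seed reproduces the trials
#'   exactly.
#' @return A data frame with columns `decision` ("go"/"stay"),
#'   `decision_time` (NA for censored trials) and `rt` (NA for stays).
#' @export
simulate_trials <- function(p, cnd, n, dt = 0.005, seed = NULL, t_max = NULL) {
  stopifnot(n >= 1, dt > 0)
  if (is.null(t_max)) t_max <- cnd$tta0
  nt <- ceiling(t_max / dt)
  tt <- dt * (0:nt)
  mu <- drift_rate(p, cnd, tt)
  bb <- boundary_at(p, cnd, tt)
  with_seed(seed, {
    raw <- sim_trials_cpp(mu, bb, dt, as.integer(n))
    go <- raw$decision == 1L
    rt <- rep(NA_real_, n)
    if (any(go)) rt[go] <- raw$decision_time[go] + sample_nondecision_time(p, sum(go))
    data.frame(decision = ifelse(go, "go", "stay"),
               decision_time = raw$decision_time,
               rt = rt)
  })
}

#' Predicted condition summary from an FPT solution
#'
#' Go probability and go-RT quantiles read off the observed-RT CDF by
#' linear interpolation on the time grid.
#'
#' @param sol An [solve_fpt()] result.
#' @param levels Quantile probabilities in (0, 1).
#' @return List with `p_go`, `rt_quantiles` (NA when `p_go` is numerically
#'   zero) and `mean_rt` (predicted mean observed go-RT, NA when undefined).
#' @export
predicted_summary <- function(sol, levels = c(0.1, 0.3, 0.5, 0.7, 0.9)) {
  p_go <- sol$p_go
  if (p_go < 1e-9) {
    return(list(p_go = p_go,
                rt_quantiles = setNames(rep(NA_real_, length(levels)), levels),
                mean_rt = NA_real_))
  }
  dens <- sol$rt_density_observed
  grid <- sol$rt_grid
  cdf <- cumsum(dens) * sol$dt / p_go
  mean_rt <- sum(grid * dens) * sol$dt / p_go
  q <- quantiles_from_cdf(grid, cdf, levels)
  list(p_go = p_go, rt_quantiles = setNames(q, levels), mean_rt = mean_rt)
}

# Invert a discrete CDF by linear interpolation in time.
quantiles_from_cdf <- function(grid, cdf, levels) {
  keep <- c(TRUE, diff(cdf) > 1e-15)
  g <- grid[keep]; f <- pmin(cdf[keep], 1)
  if (length(g) < 2) return(rep(g[1] %||% NA_real_, length(levels)))
  approx(f, g, xout = levels, rule = 2, ties = "ordered")$y
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export an FPT solution as CSV
#'
#' Columns `t`, `go_density` (zero past the decision horizon) and
#' `rt_density_observed`, on the observed-RT time grid.
#'
#' @param sol An [solve_fpt()] result.
#' @param path Output file path.
#' @export
fpt_to_csv <- function(sol, path) {
  n <- length(sol$rt_grid)
  gd <- c(sol$go_density, rep(0, n - length(sol$go_density)))
  write.csv(data.frame(t = sol$rt_grid, go_density = gd,
                       rt_density_observed = sol$rt_density_observed),
            path, row.names = FALSE)
  invisible(path)
}
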