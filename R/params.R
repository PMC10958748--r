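#' Model variants
#'
#' * `"full"` — time-varying drift and TTA-collapsing boundary (8 free
#'   parameters: alpha, beta, theta_crit, b0, k, tau, mu_nd, sigma_nd).
#' * `"var_drift_const_bound"` — time-varying drift, constant boundary
#'   `+/- b0` (drops k and tau; 6 free parameters).
#' * `"const_drift_const_bound"` — a basic drift-diffusion model: one free
#'   constant drift rate replacing (alpha, beta, theta_crit) jointly, and a
#'   constant boundary (4 free parameters: drift_const, b0, mu_nd, sigma_nd).
#'
#' @name model_variants
NULL

MODEL_VARIANTS <- c("full", "var_drift_const_bound", "const_drift_const_bound")

#' Model parameters for the gap-acceptance drift-diffusion model
#'
#' Evidence `x` accumulates as `dx = alpha * ((TTA(t) + beta * d(t)) -
#' theta_crit) dt + dW` (unit-variance Wiener noise) and is absorbed at the
#' boundaries `+/- b0 / (1 + exp(-k * (TTA(t) - tau)))`. Observed response
#' time is decision time plus a normally distributed non-decision time
#' (truncated at zero).
#'
#' @param alpha Drift gain, >= 0. Evidence units per second per unit of
#'   combined gap (seconds). Decisions are random diffusion when `alpha = 0`.
#' @param beta Distance weight inside the drift, seconds per meter.
#' @param theta_crit Critical combined gap `TTA + beta * d` (seconds) at
#'   which the drift changes sign.
#' @param b0 Boundary scale, evidence units, > 0.
#' @param k Boundary sensitivity to TTA, 1/second, > 0.
#' @param tau TTA at which the boundary sits at its half-collapsed baseline
#'   `+/- b0/2`, seconds.
#' @param mu_nd Non-decision-time mean, seconds.
#' @param sigma_nd Non-decision-time standard deviation, seconds, >= 0.
#' @param variant One of `"full"`, `"var_drift_const_bound"`,
#'   `"const_drift_const_bound"` (see [model_variants]).
#' @param drift_const Constant drift rate, evidence units per second; used
#'   (and required) only by the `const_drift_const_bound` variant.
#' @return An object of class `gap_params`.
#' @examples
#' p <- gap_params(alpha = 1, beta = 0.05, theta_crit = 8, b0 = 2,
#'                 k = 2, tau = 4, mu_nd = 0.3, sigma_nd = 0.05)
#' @export
gap_params <- function(alpha = NA_real_, beta = NA_real_, theta_crit = NA_real_,
                       b0, k = NA_real_, tau = NA_real_,
                       mu_nd, sigma_nd, variant = "full",
                       drift_const = NA_real_) {
  variant <- match.arg(variant, MODEL_VARIANTS)
  if (!is.finite(b0) || b0 <= 0) stop("b0 must be > 0", call. = FALSE)
  if (!is.finite(sigma_nd) || sigma_nd < 0) stop("sigma_nd must be >= 0", call. = FALSE)
  if (variant == "const_drift_const_bound") {
    if (!is.finite(drift_const)) stop("const_drift_const_bound requires drift_const", call. = FALSE)
  } else {
    if (!is.finite(alpha) || alpha < 0) stop("alpha must be >= 0", call. = FALSE)
    if (!is.finite(beta) || !is.finite(theta_crit))
      stop("beta and theta_crit are required", call. = FALSE)
  }
  if (variant == "full") {
    if (!is.finite(k) || k <= 0) stop("k must be > 0", call. = FALSE)
    if (!is.finite(tau)) stop("tau is required for the full model", call. = FALSE)
  }
  structure(list(alpha = alpha, beta = beta, theta_crit = theta_crit,
                 b0 = b0, k = k, tau = tau, mu_nd = mu_nd,
                 sigma_nd = sigma_nd, variant = variant,
                 drift_const = drift_const),
            class = "gap_params")
}

#' @export
print.gap_params <- function(x, ...) {
  cat(sprintf("Gap-acceptance DDM parameters (variant: %s)\n", x$variant))
  nm <- free_param_names(x$variant)
  vals <- unlist(x[nm])
  cat(paste(sprintf("  %-10s %g", nm, vals), collapse = "\n"), "\n")
  invisible(x)
}

#' Free parameter names for a model variant
#'
#' @param variant A variant tag (see [model_variants]).
#' @return Character vector of free parameter names, in the fitting order.
#' @export
free_param_names <- function(variant) {
  variant <- match.arg(variant, MODEL_VARIANTS)
  switch(variant,
    full = c("alpha", "beta", "theta_crit", "b0", "k", "tau", "mu_nd", "sigma_nd"),
    var_drift_const_bound = c("alpha", "beta", "theta_crit", "b0", "mu_nd", "sigma_nd"),
    const_drift_const_bound = c("drift_const", "b0", "mu_nd", "sigma_nd")
  )
}

#' Convert between a free-parameter vector and `gap_params`
#'
#' The vector holds the variant's free parameters in the order of
#' [free_param_names()]; this is the representation the optimizer works in.
#'
#' @param v Numeric vector of free parameter values.
#' @param variant Variant tag.
#' @return [vec_to_params()]: a [gap_params()]; [params_to_vec()]: a named
#'   numeric vector.
#' @export
vec_to_params <- function(v, variant) {
  nm <- free_param_names(variant)
  stopifnot(length(v) == length(nm))
  a <- as.list(setNames(as.numeric(v), nm))
  a$variant <- variant
  do.call(gap_params, a)
}

#' @rdname vec_to_params
#' @param p A [gap_params()].
#' @export
params_to_vec <- function(p) {
  nm <- free_param_names(p$variant)
  setNames(unlist(p[nm]), nm)
}

#' Serialize / deserialize parameters as JSON
#'
#' The JSON object is flat, keyed by the parameter names plus `variant`.
#'
#' @param p A [gap_params()] object.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @export
params_to_json <- function(p, path = NULL) {
  x <- p[c(free_param_names(p$variant), "variant")]
  if (is.null(path)) return(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname params_to_json
#' @param json A JSON string or file path produced by [params_to_json()].
#' @export
params_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  do.call(gap_params, x)
}
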