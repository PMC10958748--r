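#' Experimental conditions and oncoming-vehicle kinematics
#'
#' A condition is one cell of the factorial design: an initial
#' time-to-arrival (TTA) and an initial distance of the oncoming vehicle.
#' The vehicle moves at the constant speed `v = d0 / tta0`, so both TTA and
#' distance decrease linearly until arrival.
#'
#' @param tta0 Initial time-to-arrival, seconds (> 0).
#' @param d0 Initial distance, meters (> 0).
#' @return An object of class `gap_condition`: a list with fields `tta0`,
#'   `d0` and the implied speed `v` (m/s).
#' @examples
#' cnd <- condition(tta0 = 4, d0 = 120)
#' cnd$v  # 30 m/s
#' @export
condition <- function(tta0, d0) {
  stopifnot(is.numeric(tta0), is.numeric(d0), length(tta0) == 1, length(d0) == 1)
  if (!is.finite(tta0) || !is.finite(d0) || tta0 <= 0 || d0 <= 0)
    stop("invalid design: tta0 and d0 must be positive and finite", call. = FALSE)
  structure(list(tta0 = tta0, d0 = d0, v = d0 / tta0), class = "gap_condition")
}

#' @export
print.gap_condition <- function(x, ...) {
  cat(sprintf("Condition: TTA0 = %g s, d0 = %g m (v = %g m/s)\n", x$tta0, x$d0, x$v))
  invisible(x)
}

#' Build the factorial condition grid
#'
#' Cartesian product of TTA levels and distance levels, in tta0-major order
#' (all distances for the first TTA, then the next TTA, ...). The ordering
#' is deterministic so that cross-validation fold indices are reproducible.
#'
#' @param ttas Numeric vector of initial TTA levels, seconds.
#' @param distances Numeric vector of initial distances, meters.
#' @return A list of [condition()] objects, length `length(ttas) * length(distances)`.
#' @examples
#' grid <- condition_grid(c(4, 5, 6), c(90, 120, 150))
#' length(grid)  # 9
#' @export
condition_grid <- function(ttas, distances) {
  if (length(ttas) == 0 || length(distances) == 0)
    stop("invalid design: empty condition lists", call. = FALSE)
  if (any(!is.finite(ttas)) || any(!is.finite(distances)) ||
      any(ttas <= 0) || any(distances <= 0))
    stop("invalid design: all TTA and distance levels must be positive", call. = FALSE)
  out <- vector("list", length(ttas) * length(distances))
  i <- 1L
  for (tta in ttas) for (d in distances) {
    out[[i]] <- condition(tta, d)
    i <- i + 1L
  }
  out
}

#' Time-to-arrival at time t
#'
#' TTA decreases linearly from `tta0` at 1 s/s; the value is not clamped at
#' zero, callers decide how to treat post-arrival times.
#'
#' @param cnd A [condition()].
#' @param t Time since vehicle appearance, seconds (vectorized, >= 0).
#' @return TTA in seconds (possibly <= 0 past arrival).
#' @export
tta_at <- function(cnd, t) {
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  cnd$tta0 - t
}

#' Distance to the oncoming vehicle at time t
#'
#' @inheritParams tta_at
#' @return Distance in meters (possibly <= 0 past arrival).
#' @export
distance_at <- function(cnd, t) {
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  cnd$d0 - cnd$v * t
}

#' Condition grid as a data frame
#'
#' @param grid A list of conditions from [condition_grid()].
#' @return A data frame with columns `tta0`, `d0`, `v`.
#' @export
conditions_df <- function(grid) {
  data.frame(
    tta0 = vapply(grid, function(c) c$tta0, numeric(1)),
    d0 = vapply(grid, function(c) c$d0, numeric(1)),
    v = vapply(grid, function(c) c$v, numeric(1))
  )
}

# Stable identifier for a condition: "tta4_d120"
condition_key <- function(cnd) sprintf("tta%g_d%g", cnd$tta0, cnd$d0)
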