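#' Per-participant empirical RT quantiles
#'
#' Empirical quantiles by linear interpolation between order statistics
#' (type 7). A single RT yields that value at every level.
#'
#' @param rts Response times, seconds (non-empty).
#' @param levels Strictly increasing probabilities in (0, 1).
#' @return Numeric vector of quantile values, one per level.
#' @export
participant_quantiles <- function(rts, levels = vincent_levels()) {
  if (length(rts) == 0)
    stop("no response times: participant excluded from vincentization",
         call. = FALSE)
  stopifnot(all(diff(levels) > 0), all(levels > 0), all(levels < 1))
  quantile(rts, levels, names = FALSE, type = 7)
}

#' Default vincentizing levels
#'
#' 19 equally spaced probabilities 0.05 ... 0.95: smooth group CDFs
#' without extrapolating into the distribution tails.
#' @export
vincent_levels <- function() seq(0.05, 0.95, by = 0.05)

#' Vincentize RT distributions across participants
#'
#' Averages per-participant quantile functions at fixed probability
#' levels; the group-averaged CDF is the inverse of the group-averaged
#' quantile function (obtained by swapping the axes of the
#' (level, quantile) pairs).
#'
#' @param qmat Numeric matrix, participants in rows, one column per level.
#' @param levels The probability levels of the columns.
#' @return Object of class `gap_vincentized`: `levels`, `group_quantiles`,
#'   and `cdf_grid` (data frame with columns `t`, `p`).
#' @export
vincentize <- function(qmat, levels = vincent_levels()) {
  qmat <- as.matrix(qmat)
  if (nrow(qmat) == 0) stop("no participants to vincentize", call. = FALSE)
  stopifnot(ncol(qmat) == length(levels))
  gq <- colMeans(qmat)
  structure(list(levels = levels, group_quantiles = unname(gq),
                 cdf_grid = data.frame(t = unname(gq), p = levels),
                 n_participants = nrow(qmat)),
            class = "gap_vincentized")
}

#' @export
print.gap_vincentized <- function(x, ...) {
  cat(sprintf("Vincentized RT distribution: %d participants, %d levels (%.2f..%.2f)\n",
              x$n_participants, length(x$levels), min(x$levels), max(x$levels)))
  invisible(x)
}

#' Export a vincentized distribution as CSV
#'
#' Writes the (level, group quantile) table; the same pairs read as
#' (t, cdf) give the group-averaged CDF.
#'
#' @param v A `gap_vincentized` object.
#' @param path Output path.
#' @export
vincentized_to_csv <- function(v, path) {
  write.csv(data.frame(level = v$levels, group_quantile = v$group_quantiles),
            path, row.names = FALSE)
  invisible(path)
}

#' Group means as averages of within-participant means
#'
#' Per condition, the group go probability and mean go-RT are unweighted
#' averages of each participant's own mean — a participant with few trials
#' counts as much as one with many. Participants without go responses in a
#' condition are omitted from that condition's RT mean.
#'
#' @param trials Data frame with `participant_id`, `tta_condition`,
#'   `d_condition`, `decision`, `rt`.
#' @return Data frame per condition: `tta0`, `d0`, `p_go`, `mean_rt`,
#'   `n_participants`, `n_participants_rt`.
#' @export
group_means <- function(trials) {
  key <- interaction(trials$tta_condition, trials$d_condition, drop = TRUE)
  rows <- lapply(split(trials, key), function(g) {
    by_pp <- split(g, g$participant_id, drop = TRUE)
    p_gos <- vapply(by_pp, function(h) mean(h$decision == "go"), numeric(1))
    rt_means <- vapply(by_pp, function(h) {
      rts <- h$rt[h$decision == "go" & !is.na(h$rt)]
      if (length(rts) == 0) NA_real_ else mean(rts)
    }, numeric(1))
    data.frame(tta0 = g$tta_condition[1], d0 = g$d_condition[1],
               p_go = mean(p_gos),
               mean_rt = if (all(is.na(rt_means))) NA_real_
                         else mean(rt_means, na.rm = TRUE),
               n_participants = length(by_pp),
               n_participants_rt = sum(!is.na(rt_means)))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$tta0, out$d0), ]
  rownames(out) <- NULL
  out
}

#' Binomial proportion standard error
#'
#' `sqrt(p (1 - p) / n)` with `p = n_go / n_trials`.
#'
#' @param n_go Number of go decisions.
#' @param n_trials Total number of trials (>= 1).
#' @return Standard error of the go proportion.
#' @export
binomial_sem <- function(n_go, n_trials) {
  stopifnot(all(n_trials >= 1), all(n_go >= 0), all(n_go <= n_trials))
  p <- n_go / n_trials
  sqrt(p * (1 - p) / n_trials)
}
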