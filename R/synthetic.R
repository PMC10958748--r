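#' Default group-mean model parameters for the synthetic population
#'
#' Chosen so that the simulated group reproduces the qualitative behavior
#' of the study population: an overall go rate near one half, go
#' probability increasing in both TTA and distance, and mean go-RTs well
#' under 2 s that increase with the TTA condition.
#'
#' @return A [gap_params()] (full variant).
#' @export
default_group_params <- function() {
  gap_params(alpha = 0.9, beta = 0.065, theta_crit = 11.45, b0 = 1.4,
             k = 1.3, tau = 3.4, mu_nd = 0.3, sigma_nd = 0.06,
             variant = "full")
}

#' Synthetic population specification
#'
#' Describes the participant pool the generator emulates: the group-mean
#' model parameters, independent between-participant normal variability
#' per parameter, and the task-artifact exclusion rates (failing to fully
#' stop before the turn; keeping the gas pedal pressed throughout).
#'
#' @param n_participants Number of participants.
#' @param means Group-mean [gap_params()] (full variant).
#' @param sds Named numeric vector of between-participant standard
#'   deviations (any subset of the full model's free parameters; missing
#'   entries default to 0).
#' @param exclusion_rates Named vector with `no_full_stop` (rate per left
#'   turn) and `pedal_held` (rate per go decision).
#' @return Object of class `gap_population_spec`.
#' @export
population_spec <- function(n_participants = 16,
                            means = default_group_params(),
                            sds = default_population_sds(),
                            exclusion_rates = c(no_full_stop = 0.014,
                                                pedal_held = 0.005)) {
  stopifnot(n_participants >= 1, inherits(means, "gap_params"),
            all(exclusion_rates >= 0), all(exclusion_rates <= 1))
  full_sds <- setNames(rep(0, 8), free_param_names("full"))
  if (length(sds)) {
    stopifnot(all(names(sds) %in% names(full_sds)), all(sds >= 0))
    full_sds[names(sds)] <- sds
  }
  structure(list(n_participants = n_participants, means = means,
                 sds = full_sds, exclusion_rates = exclusion_rates),
            class = "gap_population_spec")
}

#' Default between-participant standard deviations
#'
#' Moderate independent variability in drift weighting, critical gap,
#' urgency and non-decision time, producing the kind of individual
#' differences visible in per-participant go-probability and RT curves.
#'
#' @return Named numeric vector.
#' @export
default_population_sds <- function() {
  c(alpha = 0.15, beta = 0.012, theta_crit = 0.9, b0 = 0.2,
    k = 0.25, tau = 0.6, mu_nd = 0.05, sigma_nd = 0.015)
}

#' Generate a balanced trial schedule
#'
#' Per route, each TTA level appears exactly `left_turns_per_route /
#' length(tta_levels)` times in shuffled order; the distance condition is
#' drawn uniformly and independently per trial.
#'
#' @param n_routes Number of routes per participant.
#' @param left_turns_per_route Left turns per route (must be divisible by
#'   the number of TTA levels).
#' @param tta_levels TTA conditions, seconds.
#' @param distances Distance conditions, meters.
#' @param seed Integer seed.
#' @return Data frame with columns `route`, `trial`, `tta_condition`,
#'   `d_condition`.
#' @export
generate_schedule <- function(n_routes = 8, left_turns_per_route = 15,
                              tta_levels = c(4, 5, 6),
                              distances = c(90, 120, 150), seed = NULL) {
  per_level <- left_turns_per_route / length(tta_levels)
  if (per_level != round(per_level))
    stop("left_turns_per_route must be divisible by the number of TTA levels",
         call. = FALSE)
  with_seed(seed, {
    rows <- lapply(seq_len(n_routes), function(r) {
      ttas <- sample(rep(tta_levels, per_level))
      data.frame(route = r, trial = seq_len(left_turns_per_route),
                 tta_condition = ttas,
                 d_condition = sample(distances, left_turns_per_route,
                                      replace = TRUE))
    })
    do.call(rbind, rows)
  })
}

#' Sample a participant population
#'
#' Independent normal draws per parameter around the group means, clipped
#' to the model's parameter constraints (`alpha >= 0`, `b0 > 0`, `k > 0`,
#' `sigma_nd >= 0`).
#'
#' @param spec A [population_spec()].
#' @param seed Integer seed.
#' @return Named list of [gap_params()], `"p1"` ... `"p<n>"`.
#' @export
sample_population <- function(spec, seed = NULL) {
  m <- params_to_vec(spec$means)
  with_seed(seed, {
    out <- lapply(seq_len(spec$n_participants), function(i) {
      v <- setNames(rnorm(length(m), m, spec$sds[names(m)]), names(m))
      v["alpha"] <- max(v["alpha"], 0)
      v["b0"] <- max(v["b0"], 0.1)
      v["k"] <- max(v["k"], 0.01)
      v["sigma_nd"] <- max(v["sigma_nd"], 0)
      v["mu_nd"] <- max(v["mu_nd"], 0)
      vec_to_params(v, "full")
    })
    setNames(out, paste0("p", seq_len(spec$n_participants)))
  })
}

#' Generate a trial-level synthetic dataset
#'
#' For each participant, every scheduled left turn is simulated from that
#' participant's model parameters ([simulate_trials()]); task-artifact
#' exclusions are assigned at the specified rates (`no_full_stop` on any
#' left turn, `pedal_held` on go decisions) and go trials with RT > `rt_cut`
#' are flagged deterministically. Each excluded trial carries exactly one
#' reason (`no_full_stop` takes precedence, then `pedal_held`, then
#' `rt_gt_2s`).
#'
#' @param spec A [population_spec()].
#' @param schedule From [generate_schedule()]; by default the design's
#'   8 routes x 15 turns (itself seeded from `seed`).
#' @param seed Master integer seed; all stages derive from it.
#' @param dt Simulation time step, seconds. The default is finer than the
#'   density solver's grid because the simulator's post-step boundary check
#'   biases first passages late by O(sqrt(dt)); at 1 ms the generated trials
#'   follow the model's first-passage distribution to within sampling error.
#' @param rt_cut Extreme-RT exclusion threshold, seconds.
#' @return Data frame of trial records: `participant_id`, `route`, `trial`,
#'   `tta_condition`, `d_condition`, `decision`, `rt` (NA for stays),
#'   `excluded`, `exclusion_reason`.
#' @export
generate_dataset <- function(spec = population_spec(), schedule = NULL,
                             seed, dt = 0.001, rt_cut = 2) {
  if (is.null(schedule)) schedule <- generate_schedule(seed = seed)
  pop <- sample_population(spec, seed = seed + 1)
  datasets <- vector("list", spec$n_participants)
  for (i in seq_len(spec$n_participants)) {
    prm <- pop[[i]]
    df <- schedule
    df$participant_id <- names(pop)[i]
    df$decision <- NA_character_
    df$rt <- NA_real_
    key <- interaction(df$tta_condition, df$d_condition, drop = TRUE)
    for (kv in levels(key)) {
      idx <- which(key == kv)
      cnd <- condition(df$tta_condition[idx[1]], df$d_condition[idx[1]])
      sim <- simulate_trials(prm, cnd, n = length(idx), dt = dt,
                             seed = seed + 100 * i +
                               match(kv, levels(key)))
      df$decision[idx] <- sim$decision
      df$rt[idx] <- sim$rt
    }
    datasets[[i]] <- df
  }
  out <- do.call(rbind, datasets)
  out <- out[, c("participant_id", "route", "trial", "tta_condition",
                 "d_condition", "decision", "rt")]
  rownames(out) <- NULL
  out <- with_seed(seed + 2, {
    n <- nrow(out)
    reason <- rep("none", n)
    nfs <- runif(n) < spec$exclusion_rates[["no_full_stop"]]
    reason[nfs] <- "no_full_stop"
    ph <- runif(n) < spec$exclusion_rates[["pedal_held"]]
    reason[reason == "none" & ph & out$decision == "go"] <- "pedal_held"
    long <- out$decision == "go" & !is.na(out$rt) & out$rt > rt_cut
    reason[reason == "none" & long] <- "rt_gt_2s"
    out$excluded <- reason != "none"
    out$exclusion_reason <- reason
    out
  })
  out
}

#' Apply exclusion flags
#'
#' Removes flagged records and tabulates the exclusion reasons. Idempotent.
#'
#' @param records A dataset from [generate_dataset()] (or read back from
#'   CSV).
#' @return List with `retained` (records with `excluded == FALSE`) and
#'   `counts` (named exclusion counts, reasons only).
#' @export
apply_exclusions <- function(records) {
  excl <- records[records$excluded, , drop = FALSE]
  counts <- table(factor(excl$exclusion_reason,
                         levels = c("no_full_stop", "pedal_held", "rt_gt_2s")))
  list(retained = records[!records$excluded, , drop = FALSE],
       counts = c(counts))
}

#' Write / read a trial dataset as CSV
#'
#' Missing RTs (stay decisions) are written as empty fields; a header row
#' is always present.
#'
#' @param records Trial data frame.
#' @param path File path.
#' @export
write_dataset <- function(records, path) {
  write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(rt = "numeric"))
  df$excluded <- as.logical(df$excluded)
  df
}
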