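#' Default run configuration
#'
#' A single plain-text (YAML) configuration governs every pipeline
#' command; all stage seeds derive from the one master seed.
#'
#' @param seed Master integer seed.
#' @return Nested list with `design`, `population`, `solver`, `fit`,
#'   `seed`.
#' @export
default_config <- function(seed = 1) {
  list(
    design = list(tta_conditions = c(4, 5, 6),
                  distance_conditions = c(90, 120, 150),
                  n_routes = 8, left_turns_per_route = 15),
    population = list(n_participants = 16,
                      means = as.list(params_to_vec(default_group_params())),
                      sds = as.list(default_population_sds()),
                      exclusion_rates = list(no_full_stop = 0.014,
                                             pedal_held = 0.005)),
    solver = list(dt = 0.005, dx = 0.01),
    fit = list(variant = "full",
               weights = list(p = 2, q = 1),
               quantile_levels = c(0.1, 0.3, 0.5, 0.7, 0.9),
               de = list(pop_size = NULL, max_gen = 200, tol = 1e-6)),
    seed = seed
  )
}

#' Read a run configuration from YAML
#'
#' Fields missing from the file fall back to [default_config()] values.
#'
#' @param path YAML file path.
#' @return Configuration list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  if (is.null(user$seed)) stop("config error: field 'seed' is required", call. = FALSE)
  modifyList(default_config(seed = user$seed), user)
}

config_population_spec <- function(config) {
  p <- config$population
  population_spec(n_participants = p$n_participants,
                  means = vec_to_params(unlist(p$means), "full"),
                  sds = unlist(p$sds),
                  exclusion_rates = unlist(p$exclusion_rates))
}

# Polynomial rolling hash (mod the Mersenne prime 2^31 - 1) of the
# canonical text form of the config, for provenance stamps.
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config), collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

stage_log <- function(out_dir, stage, config, extra = list()) {
  log <- c(list(stage = stage, config_hash = config_hash(config),
                seed = config$seed, time = format(Sys.time(), usetz = TRUE)),
           extra)
  jsonlite::write_json(log, file.path(out_dir, paste0(stage, "_log.json")),
                       auto_unbox = TRUE, digits = NA)
}

#' Simulate a synthetic dataset to disk
#'
#' Runs the synthetic-data generator end to end and writes `dataset.csv`
#' plus a provenance log (config hash, seed).
#'
#' @param config From [default_config()] / [read_run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Path of the dataset CSV, invisibly.
#' @export
cmd_simulate <- function(config = default_config(), out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  d <- config$design
  schedule <- generate_schedule(d$n_routes, d$left_turns_per_route,
                                d$tta_conditions, d$distance_conditions,
                                seed = config$seed)
  records <- generate_dataset(config_population_spec(config),
                              schedule = schedule, seed = config$seed,
                              dt = config$solver$dt)
  path <- file.path(out_dir, "dataset.csv")
  write_dataset(records, path)
  stage_log(out_dir, "simulate", config,
            list(n_records = nrow(records), n_excluded = sum(records$excluded)))
  invisible(path)
}

load_trials <- function(dataset, config) {
  records <- if (is.character(dataset)) read_dataset(dataset) else dataset
  need <- c("participant_id", "tta_condition", "d_condition", "decision", "rt",
            "excluded")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("dataset schema mismatch: missing columns ",
         paste(miss, collapse = ", "), call. = FALSE)
  apply_exclusions(records)$retained
}

#' Fit the model to a dataset
#'
#' Group mode fits the group-averaged targets (vincentized quantiles,
#' within-participant-mean averages); per-participant mode fits each
#' participant individually. Fit JSONs and a per-condition prediction
#' table are written to `out_dir`.
#'
#' @param dataset Path to a dataset CSV, or a trial data frame.
#' @param config Run configuration.
#' @param mode `"group"` or `"per-participant"`.
#' @param variant Model variant tag (default from config).
#' @param out_dir Output directory.
#' @return The fit (group mode) or list of fits, invisibly.
#' @export
cmd_fit <- function(dataset, config = default_config(), mode = "group",
                    variant = config$fit$variant, out_dir = ".") {
  mode <- match.arg(mode, c("group", "per-participant"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  trials <- load_trials(dataset, config)
  des <- de_settings(pop_size = config$fit$de$pop_size,
                     max_gen = config$fit$de$max_gen,
                     tol = config$fit$de$tol)
  weights <- unlist(config$fit$weights)
  levels <- config$fit$quantile_levels
  dt <- config$solver$dt; dx <- config$solver$dx
  if (mode == "group") {
    summ <- group_summaries(trials, levels = levels)
    fit <- fit_model(summ, variant = variant, settings = des,
                     weights = weights, seed = config$seed, dt = dt, dx = dx)
    fit_to_json(fit, file.path(out_dir, paste0("fit_group_", variant, ".json")))
    grid <- condition_grid(config$design$tta_conditions,
                           config$design$distance_conditions)
    write.csv(predict_conditions(fit$params, grid, levels, dt, dx),
              file.path(out_dir, paste0("predictions_group_", variant, ".csv")),
              row.names = FALSE)
    stage_log(out_dir, "fit", config, list(mode = mode, variant = variant,
                                           loss = fit$loss))
    return(invisible(fit))
  }
  fits <- fit_per_participant(trials, variant = variant, seed = config$seed,
                              levels = levels, settings = des,
                              weights = weights, dt = dt, dx = dx)
  for (id in names(fits))
    fit_to_json(fits[[id]],
                file.path(out_dir, sprintf("fit_%s_%s.json", id, variant)))
  stage_log(out_dir, "fit", config, list(mode = mode, variant = variant,
                                         n_fits = length(fits)))
  invisible(fits)
}

#' Hold-one-condition-out cross-validation of a dataset
#'
#' Runs [run_cv()] on the group-averaged summaries and writes the 9-row
#' fold summary CSV.
#'
#' @inheritParams cmd_fit
#' @return The CV result, invisibly.
#' @export
cmd_crossval <- function(dataset, config = default_config(),
                         variant = config$fit$variant, out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  trials <- load_trials(dataset, config)
  summ <- group_summaries(trials, levels = config$fit$quantile_levels)
  folds <- make_folds(summ, config$design$tta_conditions,
                      config$design$distance_conditions)
  des <- de_settings(pop_size = config$fit$de$pop_size,
                     max_gen = config$fit$de$max_gen, tol = config$fit$de$tol)
  cv <- run_cv(folds, variant = variant, settings = des, seed = config$seed,
               weights = unlist(config$fit$weights),
               dt = config$solver$dt, dx = config$solver$dx)
  write.csv(cv$summary, file.path(out_dir, paste0("crossval_", variant, ".csv")),
            row.names = FALSE)
  stage_log(out_dir, "crossval", config, list(variant = variant))
  invisible(cv)
}

#' Compare the full model against its restricted variants
#'
#' Fits the full model and both simpler alternatives to the same group
#' summaries (shared seed), and writes per-variant losses and per-
#' condition predicted go probabilities and mean RTs.
#'
#' @inheritParams cmd_fit
#' @return List with `fits` and the comparison `table`, invisibly.
#' @export
cmd_compare <- function(dataset, config = default_config(), out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  trials <- load_trials(dataset, config)
  summ <- group_summaries(trials, levels = config$fit$quantile_levels)
  des <- de_settings(pop_size = config$fit$de$pop_size,
                     max_gen = config$fit$de$max_gen, tol = config$fit$de$tol)
  grid <- condition_grid(config$design$tta_conditions,
                         config$design$distance_conditions)
  fits <- list()
  tabs <- list()
  for (variant in MODEL_VARIANTS) {
    fit <- fit_model(summ, variant = variant, settings = des,
                     weights = unlist(config$fit$weights), seed = config$seed,
                     dt = config$solver$dt, dx = config$solver$dx)
    fits[[variant]] <- fit
    tab <- predict_conditions(fit$params, grid, config$fit$quantile_levels,
                              config$solver$dt, config$solver$dx)
    tab <- data.frame(variant = variant, loss = fit$loss,
                      tab[, c("tta0", "d0", "p_go", "mean_rt")])
    tabs[[variant]] <- tab
  }
  table <- do.call(rbind, tabs)
  rownames(table) <- NULL
  write.csv(table, file.path(out_dir, "model_comparison.csv"),
            row.names = FALSE)
  stage_log(out_dir, "compare", config, list(
    losses = lapply(fits, function(f) f$loss)))
  invisible(list(fits = fits, table = table))
}

#' Vincentized group RT distributions per condition
#'
#' @inheritParams cmd_fit
#' @param levels Vincentizing levels.
#' @return Data frame of (condition, level, group quantile), invisibly;
#'   also written as CSV.
#' @export
cmd_vincentize <- function(dataset, config = default_config(),
                           levels = vincent_levels(), out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  trials <- load_trials(dataset, config)
  key <- interaction(trials$tta_condition, trials$d_condition, drop = TRUE)
  rows <- lapply(split(trials, key), function(g) {
    qs <- lapply(split(g, g$participant_id, drop = TRUE), function(h) {
      rts <- h$rt[h$decision == "go" & !is.na(h$rt)]
      if (length(rts) == 0) NULL else participant_quantiles(rts, levels)
    })
    qs <- qs[!vapply(qs, is.null, logical(1))]
    if (length(qs) == 0) return(NULL)
    v <- vincentize(do.call(rbind, qs), levels)
    data.frame(tta0 = g$tta_condition[1], d0 = g$d_condition[1],
               level = v$levels, group_quantile = v$group_quantiles)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  write.csv(out, file.path(out_dir, "vincentized.csv"), row.names = FALSE)
  stage_log(out_dir, "vincentize", config, list())
  invisible(out)
}
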