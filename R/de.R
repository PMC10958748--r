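#' Differential-evolution settings
#'
#' @param pop_size Population size; default `15 * length(lower)` when `NULL`.
#' @param max_gen Maximum number of generations.
#' @param tol Relative convergence tolerance on the population loss spread.
#' @param F Differential weight; a length-2 vector dithers F uniformly in
#'   that range each generation (dithering preserves population diversity
#'   on plateaus of the objective).
#' @param CR Crossover probability.
#' @param strategy `"best1bin"` (greedy, fast convergence) or `"rand1bin"`
#'   (explorative; better on deceptive multimodal objectives).
#' @return A list of settings for [de_optimize()].
#' @export
de_settings <- function(pop_size = NULL, max_gen = 200, tol = 1e-6,
                        F = c(0.5, 1), CR = 0.7, strategy = "best1bin") {
  strategy <- match.arg(strategy, c("best1bin", "rand1bin"))
  list(pop_size = pop_size, max_gen = max_gen, tol = tol, F = F, CR = CR,
       strategy = strategy)
}

#' Bound-constrained differential evolution (best/1/bin)
#'
#' Minimizes `fn` over a box. Deterministic given `seed`. Trial points that
#' leave the box are reflected back inside. Convergence is declared when
#' the relative spread of the population's losses falls below `tol`.
#'
#' @param fn Objective taking a numeric vector, returning a scalar loss
#'   (non-finite values are treated as a large penalty).
#' @param lower,upper Numeric bound vectors of equal length.
#' @param settings See [de_settings()].
#' @param seed Integer seed (required, for reproducibility).
#' @return List with `par`, `value`, `n_evaluations`, `generations`,
#'   `converged`.
#' @export
de_optimize <- function(fn, lower, upper, settings = de_settings(), seed) {
  stopifnot(length(lower) == length(upper), all(upper > lower))
  d <- length(lower)
  np <- settings$pop_size %||% (15L * d)
  np <- max(np, 5L)
  penal <- 1e12
  evalf <- function(x) {
    v <- tryCatch(fn(x), error = function(e) penal)
    if (!is.finite(v)) penal else v
  }
  with_seed(seed, {
    pop <- matrix(runif(np * d, rep(lower, each = np), rep(upper, each = np)),
                  nrow = np)
    fit <- apply(pop, 1, evalf)
    nev <- np
    converged <- FALSE
    gen <- 0L
    for (gen in seq_len(settings$max_gen)) {
      best <- pop[which.min(fit), ]
      Fg <- if (length(settings$F) == 2)
        runif(1, settings$F[1], settings$F[2]) else settings$F
      rand1 <- identical(settings$strategy, "rand1bin")
      for (i in seq_len(np)) {
        rs <- sample(setdiff(seq_len(np), i), if (rand1) 3 else 2)
        base <- if (rand1) pop[rs[3], ] else best
        mut <- base + Fg * (pop[rs[1], ] - pop[rs[2], ])
        # reflect into the box
        mut <- ifelse(mut < lower, pmin(2 * lower - mut, upper), mut)
        mut <- ifelse(mut > upper, pmax(2 * upper - mut, lower), mut)
        cross <- runif(d) < settings$CR
        cross[sample.int(d, 1)] <- TRUE
        trial <- ifelse(cross, mut, pop[i, ])
        fv <- evalf(trial)
        nev <- nev + 1L
        if (fv <= fit[i]) { pop[i, ] <- trial; fit[i] <- fv }
      }
      spread <- max(fit) - min(fit)
      if (spread <= settings$tol * (abs(min(fit)) + 1e-12)) { converged <- TRUE; break }
    }
    if (all(fit >= penal))
      stop("fit failure: no feasible parameter vector found ",
           "(all objective evaluations failed)", call. = FALSE)
    i <- which.min(fit)
    list(par = pop[i, ], value = fit[i], n_evaluations = nev,
         generations = gen, converged = converged)
  })
}
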