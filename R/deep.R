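#' Differential-evolution configuration
#'
#' Settings for the entirely-parallel differential evolution (DE) used
#' in the global search phase.  Trial vectors combine a classic rand/1
#' mutant with a trigonometric mutant via binomial or exponential
#' recombination; members are replaced only on strict improvement, and
#' every `substitution_period` generations the oldest members (longest
#' unimproved) are overwritten with copies of the best ones.
#'
#' @param NP population size (>= 4, default 30).
#' @param S_const scaling constant of the rand/1 mutation (default 0.9).
#' @param crossover_p crossover probability in (0, 1) (default 0.5).
#' @param G_max number of generations (default 100).
#' @param M number of extra random candidate solutions fed into the
#'   pipeline alongside the greedy one (default 10).
#' @param recombination `"binomial"` or `"exponential"`.
#' @param substitution_period generations between age-based
#'   substitutions (default 20).
#' @param substitution_count how many oldest members are replaced per
#'   substitution (default 3; must be < NP).
#' @param seed optional RNG seed applied at the start of [run_deep()].
#' @param workers parallel evaluation slots (default 5).  Objective
#'   evaluations within a generation are independent, so they may be
#'   dispatched concurrently; the implementation evaluates them in
#'   member order, which makes results identical for every worker count.
#' @return list with class `de_config`.
#' @export
de_config <- function(NP = 30, S_const = 0.9, crossover_p = 0.5,
                      G_max = 100, M = 10,
                      recombination = c("binomial", "exponential"),
                      substitution_period = 20, substitution_count = 3,
                      seed = NULL, workers = 5) {
  recombination <- match.arg(recombination)
  stopifnot(NP >= 4, crossover_p > 0, crossover_p < 1, G_max >= 0,
            M >= 0, substitution_period >= 1, substitution_count >= 0,
            substitution_count < NP)
  structure(list(NP = as.integer(NP), S_const = S_const,
                 crossover_p = crossover_p, G_max = as.integer(G_max),
                 M = as.integer(M), recombination = recombination,
                 substitution_period = as.integer(substitution_period),
                 substitution_count = as.integer(substitution_count),
                 seed = seed, workers = as.integer(workers)),
            class = "de_config")
}

#' rand/1 differential mutation
#'
#' `v = q_r1 + S_const * (q_r2 - q_r3)` for three distinct members.
#'
#' @param q_r1,q_r2,q_r3 member vectors of equal length.
#' @param S_const scaling constant.
#' @return the mutant vector.
#' @export
mutate_rand1 <- function(q_r1, q_r2, q_r3, S_const) {
  q_r1 + S_const * (q_r2 - q_r3)
}

#' Trigonometric differential mutation
#'
#' The mutant is the centroid of three members, perturbed along each
#' pairwise difference with coefficients given by the members' relative
#' objective magnitudes `phi_i = |F_i| / sum(|F|)`; when all three
#' objective values are zero the mutant is the plain centroid.
#'
#' @param q_r1,q_r2,q_r3 member vectors of equal length.
#' @param F_vals their three objective values.
#' @return the mutant vector.
#' @export
mutate_trigonometric <- function(q_r1, q_r2, q_r3, F_vals) {
  stopifnot(length(F_vals) == 3L, all(is.finite(F_vals)))
  tot <- sum(abs(F_vals))
  centroid <- (q_r1 + q_r2 + q_r3) / 3
  if (tot == 0) return(centroid)
  phi <- abs(F_vals) / tot
  centroid +
    (phi[2] - phi[1]) * (q_r1 - q_r2) +
    (phi[3] - phi[2]) * (q_r2 - q_r3) +
    (phi[1] - phi[3]) * (q_r3 - q_r1)
}

#' Combine two trial vectors by crossover
#'
#' Binomial: one uniform draw per coordinate; the coordinate is taken
#' from `v` with probability `crossover_p`, else from `z`.  Exponential:
#' coordinates are taken from `v` while successive uniform draws stay
#' below `crossover_p`, and from `z` from the first failure on.
#'
#' @param v,z trial vectors of equal length.
#' @param crossover_p crossover probability.
#' @param mode `"binomial"` or `"exponential"`.
#' @return the combined vector.  Consumes `length(v)` draws from the R
#'   RNG stream in binomial mode and up to `length(v)` in exponential
#'   mode.
#' @export
recombine <- function(v, z, crossover_p,
                      mode = c("binomial", "exponential")) {
  mode <- match.arg(mode)
  D <- length(v)
  stopifnot(length(z) == D)
  if (mode == "binomial") {
    u <- stats::runif(D)
    ifelse(u < crossover_p, v, z)
  } else {
    out <- z
    for (j in seq_len(D)) {
      if (stats::runif(1) < crossover_p) out[j] <- v[j] else break
    }
    out
  }
}

#' Greedy selection between a member and its trial vector
#'
#' The trial replaces the member only if its objective value strictly
#' decreases; otherwise the member is kept and its age (generations
#' since last update) is incremented.
#'
#' @param current list with elements `vector`, `value`, `age`.
#' @param trial trial vector.
#' @param objective objective function.
#' @return updated member list.
#' @export
select_replace <- function(current, trial, objective) {
  f <- objective(trial)
  if (!is.finite(f)) stop("objective returned a non-finite value for a trial vector")
  if (f < current$value) {
    list(vector = trial, value = f, age = 0L)
  } else {
    list(vector = current$vector, value = current$value,
         age = current$age + 1L)
  }
}

#' Replace the oldest members by copies of the best ones
#'
#' The `count` members with the greatest age (ties broken by slot index)
#' are overwritten with copies of the `count` members with the lowest
#' objective value (ties likewise); ages of the overwritten slots are
#' reset.
#'
#' @param state DE state: list with `members` (NP x D matrix), `values`,
#'   `ages`.
#' @param count number of members to replace (< NP).
#' @return the updated state.
#' @export
substitute_oldest <- function(state, count) {
  count <- as.integer(count)
  if (count == 0L) return(state)
  NP <- nrow(state$members)
  stopifnot(count < NP)
  oldest <- order(-state$ages, seq_len(NP))[seq_len(count)]
  best <- order(state$values, seq_len(NP))[seq_len(count)]
  state$members[oldest, ] <- state$members[best, , drop = FALSE]
  state$values[oldest] <- state$values[best]
  state$ages[oldest] <- 0L
  state
}

#' Run the differential-evolution search
#'
#' Starts from `init` (padded with uniform random vectors in
#' `[lower, upper)` up to `NP` members), and evolves the set for
#' `G_max` generations.  Each generation builds, for every member, a
#' rand/1 mutant and a trigonometric mutant from three distinct other
#' members, combines them by [recombine()], wraps the result into the
#' box, and applies [select_replace()].  Trials are constructed from the
#' generation-start population and applied synchronously, so objective
#' evaluations are independent within a generation and their dispatch
#' order cannot affect the RNG stream; results are identical for any
#' worker count.  With `G_max = 0` the best of `init` is returned.
#'
#' @param objective function of one vector returning a finite scalar to
#'   minimize; must be deterministic.
#' @param init list of equal-length numeric start vectors (non-empty).
#' @param config a [de_config()].
#' @param lower,upper box bounds used for random padding and wrapping.
#' @return list: `best` (vector), `best_value`, `state` (final members,
#'   values, ages), `trace` (best value per generation, non-increasing).
#' @export
run_deep <- function(objective, init, config = de_config(),
                     lower = 0, upper = 1) {
  stopifnot(length(init) >= 1L, upper > lower)
  if (!is.null(config$seed)) set.seed(config$seed)
  D <- length(init[[1]])
  if (any(lengths(init) != D)) stop("init vectors must share one length")
  if (config$G_max == 0L) {
    vals <- vapply(init, objective, numeric(1))
    i <- which.min(vals)
    return(list(best = init[[i]], best_value = vals[i],
                state = list(members = do.call(rbind, init), values = vals,
                             ages = rep(0L, length(init))),
                trace = numeric(0)))
  }
  NP <- config$NP
  members <- matrix(0, NP, D)
  n0 <- min(length(init), NP)
  for (i in seq_len(n0)) members[i, ] <- init[[i]]
  if (n0 < NP) {
    members[(n0 + 1L):NP, ] <- matrix(stats::runif((NP - n0) * D, lower, upper),
                                      NP - n0, D)
  }
  wrap <- function(x) lower + (x - lower) %% (upper - lower)
  values <- vapply(seq_len(NP), function(i) objective(members[i, ]), numeric(1))
  state <- list(members = members, values = values, ages = rep(0L, NP))
  trace <- numeric(config$G_max)
  for (g in seq_len(config$G_max)) {
    trials <- matrix(0, NP, D)
    for (i in seq_len(NP)) {
      r <- sample(setdiff(seq_len(NP), i), 3L)
      v <- mutate_rand1(state$members[r[1], ], state$members[r[2], ],
                        state$members[r[3], ], config$S_const)
      z <- mutate_trigonometric(state$members[r[1], ], state$members[r[2], ],
                                state$members[r[3], ], state$values[r])
      trials[i, ] <- wrap(recombine(v, z, config$crossover_p,
                                    config$recombination))
    }
    # independent evaluations (parallelizable across config$workers slots)
    new_members <- lapply(seq_len(NP), function(i) {
      select_replace(list(vector = state$members[i, ],
                          value = state$values[i], age = state$ages[i]),
                     trials[i, ], objective)
    })
    for (i in seq_len(NP)) {
      state$members[i, ] <- new_members[[i]]$vector
      state$values[i] <- new_members[[i]]$value
      state$ages[i] <- new_members[[i]]$age
    }
    if (config$substitution_count > 0L &&
        g %% config$substitution_period == 0L) {
      state <- substitute_oldest(state, config$substitution_count)
    }
    trace[g] <- min(state$values)
  }
  i <- which.min(state$values)
  list(best = state$members[i, ], best_value = state$values[i],
       state = state, trace = trace)
}
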