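#' Parameters of the greedy constructive phase
#'
#' @param beta scaling factor applied to the maximal admissible weight of
#'   a newly added population (default 0.95; slightly below 1 leaves
#'   headroom so the subtraction does not overshoot a component).
#' @param epsilon overshoot tolerance, as in [fit_params()].
#' @param max_pops maximum number of ancestral populations in a solution
#'   (default 4 — e.g. tracing ancestry to the four grandparents).
#' @param stop_tol minimax error below which the greedy construction
#'   stops adding populations (default 1e-6): once the current subset
#'   already reproduces the query to solver precision, a sparser
#'   solution is preferred over filling up to `max_pops`.
#' @return list with class `greedy_params`.
#' @export
greedy_params <- function(beta = 0.95, epsilon = 0.01, max_pops = 4,
                          stop_tol = 1e-6) {
  stopifnot(beta > 0, beta <= 1, epsilon >= 0, max_pops >= 1, stop_tol >= 0)
  structure(list(beta = beta, epsilon = epsilon,
                 max_pops = as.integer(max_pops), stop_tol = stop_tol),
            class = "greedy_params")
}

#' Select the population with the highest affinity to a residual
#'
#' Evaluates [affinity_score()] of every non-excluded panel population
#' against the current residual and returns the index of the best one;
#' ties are broken toward the lowest panel index.
#'
#' @param panel a [readmix_panel()].
#' @param residual current residual vector (query minus already-weighted
#'   populations; may lie off the simplex).
#' @param exclude integer indices never to pick (already in the solution).
#' @param params a [fit_params()].
#' @return a single panel row index.
#' @export
pick_next_population <- function(panel, residual, exclude = integer(),
                                 params = fit_params()) {
  cand <- setdiff(seq_len(panel$N), exclude)
  if (length(cand) == 0L) stop("all populations are excluded")
  losses <- vapply(cand, function(j) {
    affinity_score(panel$Q[j, ], residual, params)$loss
  }, numeric(1))
  cand[which.min(losses)]
}

#' Maximal admissible weight of a population against a residual
#'
#' The largest `w` such that `w * r_k` stays below `residual_k + epsilon`
#' in every component where `r_k > 0`, capped at 1, floored at 0, and
#' scaled by `beta`.
#'
#' @param r population admixture vector.
#' @param residual current residual vector.
#' @param params a [greedy_params()].
#' @return scalar weight in \[0, beta\].
#' @export
population_weight <- function(r, residual, params = greedy_params()) {
  pos <- r > 1e-12
  if (!any(pos)) stop("invalid reference row: all components are zero")
  w <- min(1, min((residual[pos] + params$epsilon) / r[pos]))
  max(w, 0) * params$beta
}

#' Greedy construction of the first candidate solution
#'
#' Starting from the user-fixed populations (conditional mode; weights
#' for the fixed members are computed and subtracted first, in the given
#' order), repeatedly adds the population with the highest affinity to
#' the current residual, computes its admissible weight, and subtracts
#' the weighted population vector — until `max_pops` populations are in
#' the solution or the subset already fits the query to `stop_tol`.
#' The final weights are re-fit on the full subset with
#' [chebyshev_weights()].
#'
#' @param panel a [readmix_panel()].
#' @param target query admixture vector.
#' @param fixed integer indices of prior populations (may be empty).
#' @param params a [greedy_params()].
#' @param fit a [fit_params()].
#' @param equal_weights fit and stop using the equally weighted
#'   objective; the solution is always built up to `max_pops` members in
#'   this mode (the number of contributors is assumed known).
#' @return a solution object: list of `indices`, `weights`,
#'   `minimax_error`.
#' @export
build_initial_solution <- function(panel, target, fixed = integer(),
                                   params = greedy_params(),
                                   fit = fit_params(),
                                   equal_weights = FALSE) {
  if (panel$N < 1L) stop("empty panel")
  fixed <- as.integer(fixed)
  if (length(fixed) > params$max_pops) {
    stop("more fixed prior populations than max_pops")
  }
  S <- integer()
  residual <- target
  add <- function(j) {
    w <- population_weight(panel$Q[j, ], residual, params)
    residual <<- residual - w * panel$Q[j, ]
    S <<- c(S, j)
  }
  for (j in fixed) add(j)
  while (length(S) < params$max_pops && length(S) < panel$N) {
    if (!equal_weights && length(S) > 0L) {
      err <- chebyshev_weights(S, panel, target)$minimax_error
      if (err <= params$stop_tol) break
    }
    add(pick_next_population(panel, residual, exclude = S, params = fit))
  }
  fit_solution(S, panel, target, equal_weights = equal_weights)
}

#' Improve a solution by pairwise population swaps
#'
#' Scans all pairs (x in the solution, y outside it), re-fitting the
#' weights for each candidate swap, and applies the swap with the
#' largest reduction in minimax error; repeats until no swap reduces the
#' error by more than 1e-9.  Fixed (prior) populations are never swapped
#' out.  Best-improvement order makes the result deterministic.
#'
#' @param solution a solution object (from [build_initial_solution()]).
#' @param panel a [readmix_panel()].
#' @param target query admixture vector.
#' @param fixed integer indices that must stay in the solution.
#' @param equal_weights use the equally weighted objective.
#' @return the improved solution.
#' @export
swap_improve <- function(solution, panel, target, fixed = integer(),
                         equal_weights = FALSE) {
  S <- solution$indices
  best <- solution
  repeat {
    movable <- setdiff(S, fixed)
    outside <- setdiff(seq_len(panel$N), S)
    if (length(movable) == 0L || length(outside) == 0L) break
    improved <- FALSE
    cur <- best
    for (x in movable) {
      for (y in outside) {
        S2 <- S
        S2[S2 == x] <- y
        cand <- fit_solution(S2, panel, target, equal_weights = equal_weights)
        if (cand$minimax_error < cur$minimax_error - 1e-9) {
          cur <- cand
          improved <- TRUE
        }
      }
    }
    if (!improved) break
    best <- cur
    S <- best$indices
  }
  best
}
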