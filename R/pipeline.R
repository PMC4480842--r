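#' Full pipeline configuration
#'
#' @param greedy a [greedy_params()].
#' @param fit a [fit_params()].
#' @param de a [de_config()].
#' @param stable_membership_frac fraction of candidate solutions a
#'   population must appear in to be reported as stable (default 0.75).
#' @param unmixed_tol minimax error of the best single-population fit
#'   below which the individual is reported as unmixed (default 0.02,
#'   conservative relative to within-population variability of panel
#'   admixture means).
#' @param prior_discard_margin allowed excess of the conditional fit's
#'   minimax error over the unconditional one before the user prior is
#'   judged to contradict the genotype and discarded (default 0.05).
#' @param equal_weights assume the mixture weights are equal a priori
#'   and optimize only the population subset (of size
#'   `greedy$max_pops`).
#' @param local_radius_km geographic radius of the local-refinement
#'   neighborhood (default 500 km, spanning neighboring-country panels).
#' @param local_knn number of nearest populations in admixture space
#'   (L-infinity) added to the neighborhood per solution member
#'   (default 10).
#' @return list with class `readmix_config`.
#' @export
readmix_config <- function(greedy = greedy_params(), fit = fit_params(),
                           de = de_config(),
                           stable_membership_frac = 0.75,
                           unmixed_tol = 0.02,
                           prior_discard_margin = 0.05,
                           equal_weights = FALSE,
                           local_radius_km = 500, local_knn = 10) {
  stopifnot(stable_membership_frac >= 0.5, stable_membership_frac <= 1,
            unmixed_tol >= 0, prior_discard_margin >= 0,
            local_radius_km >= 0, local_knn >= 0)
  structure(list(greedy = greedy, fit = fit, de = de,
                 stable_membership_frac = stable_membership_frac,
                 unmixed_tol = unmixed_tol,
                 prior_discard_margin = prior_discard_margin,
                 equal_weights = isTRUE(equal_weights),
                 local_radius_km = local_radius_km,
                 local_knn = as.integer(local_knn)),
            class = "readmix_config")
}

# Decode a continuous DE vector into distinct panel indices.
# Each coordinate lives in [0, N); decoding floors to an index with
# wrap-around, and duplicates (including collisions with `used`) are
# repaired by advancing to the next unused index.
decode_indices <- function(x, N, used = integer()) {
  out <- integer(length(x))
  taken <- logical(N)
  taken[used] <- TRUE
  for (j in seq_along(x)) {
    i <- (floor(x[j]) %% N) + 1L
    while (taken[i]) i <- (i %% N) + 1L
    taken[i] <- TRUE
    out[j] <- i
  }
  out
}

# Objective over encoded index vectors, with memoisation on the decoded
# subset (DE revisits the same subsets constantly).
make_subset_objective <- function(panel, target, fixed, equal_weights) {
  cache <- new.env(parent = emptyenv())
  function(x) {
    S <- c(fixed, decode_indices(x, panel$N, used = fixed))
    key <- paste(sort(S), collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- chebyshev_weights(S, panel, target,
                             equal_weights = equal_weights)$minimax_error
    cache[[key]] <- val
    val
  }
}

#' Classify a query vector as unmixed
#'
#' Fits every single panel population at weight 1 and reports whether
#' the best minimax error falls below the unmixed tolerance.
#'
#' @param target query admixture vector.
#' @param panel a [readmix_panel()].
#' @param config a [readmix_config()].
#' @return list: `is_unmixed`, `index` (best single population), `error`.
#' @export
classify_unmixed <- function(target, panel, config = readmix_config()) {
  errs <- unname(apply(panel$Q, 1L, function(r) max(abs(r - target))))
  i <- which.min(errs)
  list(is_unmixed = errs[i] <= config$unmixed_tol,
       index = unname(i), error = unname(errs[i]))
}

#' Local refinement over close populations
#'
#' Builds a neighborhood of the current solution — all panel populations
#' within `local_radius_km` of any solution member, plus each member's
#' `local_knn` nearest populations in L-infinity admixture distance —
#' and exhaustively tries single-population replacements from it,
#' keeping the best strictly improving one; repeats to a fixed point.
#' While the fit is still worse than the tolerance margin
#' `config$fit$epsilon`, replacement of population pairs is also tried,
#' escaping single-swap local minima.  This step distinguishes closely
#' related neighbors (e.g. Belorussian / Russian / Ukrainian) that the
#' global search may have confused.
#'
#' @param solution a solution object.
#' @param panel a [readmix_panel()].
#' @param target query admixture vector.
#' @param config a [readmix_config()].
#' @param fixed integer indices never replaced.
#' @return the refined solution (error never worse than the input's).
#' @export
local_refine <- function(solution, panel, target, config = readmix_config(),
                         fixed = integer()) {
  eqw <- config$equal_weights
  best <- solution
  repeat {
    S <- best$indices
    # geographic neighborhood
    pts <- cbind(panel$lon, panel$lat)
    geo <- rep(FALSE, panel$N)
    for (i in S) {
      d <- geosphere::distHaversine(pts[i, , drop = FALSE], pts,
                                    r = 6371000) / 1000
      geo <- geo | (d <= config$local_radius_km)
    }
    # admixture-space k nearest neighbors of each member
    knn <- rep(FALSE, panel$N)
    if (config$local_knn > 0L) {
      for (i in S) {
        d <- apply(panel$Q, 1L, function(r) max(abs(r - panel$Q[i, ])))
        d[i] <- Inf
        knn[order(d)[seq_len(min(config$local_knn, panel$N - 1L))]] <- TRUE
      }
    }
    cand <- setdiff(which(geo | knn), S)
    movable <- setdiff(S, fixed)
    if (length(cand) == 0L || length(movable) == 0L) break
    cur <- best
    for (x in movable) {
      for (y in cand) {
        S2 <- S
        S2[S2 == x] <- y
        trial <- fit_solution(S2, panel, target, equal_weights = eqw)
        if (trial$minimax_error < cur$minimax_error - 1e-9) cur <- trial
      }
    }
    # pair replacements while the fit misses the tolerance margin
    if (cur$minimax_error >= best$minimax_error - 1e-9 &&
        best$minimax_error > config$fit$epsilon &&
        length(movable) >= 2L && length(cand) >= 2L) {
      xs <- utils::combn(movable, 2L, simplify = FALSE)
      ys <- utils::combn(cand, 2L, simplify = FALSE)
      for (x2 in xs) {
        for (y2 in ys) {
          S2 <- c(setdiff(S, x2), y2)
          trial <- fit_solution(S2, panel, target, equal_weights = eqw)
          if (trial$minimax_error < cur$minimax_error - 1e-9) cur <- trial
        }
      }
    }
    if (cur$minimax_error >= best$minimax_error - 1e-9) break
    best <- cur
  }
  best
}

#' Average an ensemble of candidate solutions
#'
#' A population is stable if it appears in at least
#' `stable_membership_frac` of the solutions (inclusive); stable
#' populations are reported with their mean weight over the solutions
#' containing them, renormalized to sum to 1.  Remaining populations are
#' listed as regional candidates with their membership fractions.
#'
#' @param solutions non-empty list of solution objects.
#' @param panel a [readmix_panel()].
#' @param config a [readmix_config()].
#' @return list with `stable` and `regional` data frames (population,
#'   weight / mean_weight, membership, lat, lon) and `minimax_error`
#'   (the best across the solutions).
#' @export
ensemble_average <- function(solutions, panel, config = readmix_config()) {
  if (length(solutions) == 0L) stop("no solutions to average")
  n <- length(solutions)
  count <- numeric(panel$N)
  wsum <- numeric(panel$N)
  for (sol in solutions) {
    count[sol$indices] <- count[sol$indices] + 1
    wsum[sol$indices] <- wsum[sol$indices] + sol$weights
  }
  frac <- count / n
  meanw <- ifelse(count > 0, wsum / pmax(count, 1), 0)
  stable_idx <- which(frac >= config$stable_membership_frac)
  regional_idx <- setdiff(which(count > 0), stable_idx)
  sw <- meanw[stable_idx]
  if (length(stable_idx) > 0L && sum(sw) > 0) sw <- sw / sum(sw)
  mk <- function(idx, w) {
    data.frame(population = panel$population[idx],
               weight = w, membership = frac[idx],
               lat = panel$lat[idx], lon = panel$lon[idx],
               stringsAsFactors = FALSE, row.names = NULL)
  }
  stable <- mk(stable_idx, sw)
  stable <- stable[order(-stable$weight), , drop = FALSE]
  rownames(stable) <- NULL
  regional <- mk(regional_idx, meanw[regional_idx])
  names(regional)[2] <- "mean_weight"
  regional <- regional[order(-regional$membership), , drop = FALSE]
  rownames(regional) <- NULL
  list(stable = stable, regional = regional,
       minimax_error = min(vapply(solutions, `[[`, numeric(1),
                                  "minimax_error")))
}

# One full phase-1 + phase-2 + phase-3 pass for a given set of fixed
# (prior) indices.  Returns the refined candidate solutions and the
# ensemble summary.
core_run <- function(target, panel, fixed, config) {
  gp <- config$greedy
  eqw <- config$equal_weights
  # Phase 1: greedy construction + swap improvement
  sol0 <- build_initial_solution(panel, target, fixed = fixed,
                                 params = gp, fit = config$fit,
                                 equal_weights = eqw)
  sol0 <- swap_improve(sol0, panel, target, fixed = fixed,
                       equal_weights = eqw)
  p_free <- length(sol0$indices) - length(fixed)
  de <- config$de
  if (p_free == 0L || de$M == 0L) {
    sols <- list(sol0)
  } else {
    # Phase 2a: DE over index vectors, seeded with the greedy solution
    # and M random candidates (padded to NP inside run_deep)
    objective <- make_subset_objective(panel, target, fixed, eqw)
    enc0 <- setdiff(sol0$indices, fixed) - 1 + 0.5
    init <- c(list(enc0),
              lapply(seq_len(de$M),
                     function(i) stats::runif(p_free, 0, panel$N)))
    res <- run_deep(objective, init, de, lower = 0, upper = panel$N)
    ord <- order(res$state$values, seq_along(res$state$values))
    take <- ord[seq_len(min(de$M + 1L, length(ord)))]
    sols <- lapply(take, function(i) {
      S <- c(fixed, decode_indices(res$state$members[i, ], panel$N,
                                   used = fixed))
      fit_solution(S, panel, target, equal_weights = eqw)
    })
  }
  # Phase 2b: local refinement of each candidate, then drop numerically
  # zero-weight members (the LP vertex optimum zeroes out populations
  # that do not contribute)
  sols <- lapply(sols, function(s) {
    s <- local_refine(s, panel, target, config, fixed = fixed)
    if (!eqw) {
      keep <- s$weights > 1e-6 | s$indices %in% fixed
      if (any(!keep) && any(keep)) {
        s <- fit_solution(s$indices[keep], panel, target)
      }
    }
    s
  })
  # Phase 3: ensemble averaging
  ens <- ensemble_average(sols, panel, config)
  c(ens, list(solutions = sols))
}

#' Conditional-mode prior handling
#'
#' Runs the decomposition constrained to include the prior populations
#' and compares its best minimax error with the unconditional one; if
#' the conditional error exceeds the unconditional error by more than
#' `prior_discard_margin`, the prior contradicts the genotype and is
#' discarded.
#'
#' @param target query admixture vector.
#' @param panel a [readmix_panel()].
#' @param priors character vector of prior population names.
#' @param config a [readmix_config()].
#' @param unconditional_error best minimax error of the unconditional
#'   run.
#' @return list: `fixed` (resolved indices), `discarded` (flag), and
#'   `result` (the conditional core run, or `NULL` when discarded).
#' @export
apply_prior <- function(target, panel, priors, config, unconditional_error) {
  fixed <- panel_index(panel, priors)
  res <- core_run(target, panel, fixed, config)
  if (res$minimax_error > unconditional_error + config$prior_discard_margin) {
    list(fixed = fixed, discarded = TRUE, result = NULL)
  } else {
    list(fixed = fixed, discarded = FALSE, result = res)
  }
}

#' Decompose an admixture vector into reference populations
#'
#' The full three-phase pipeline: greedy construction with swap
#' improvement, differential-evolution global search over population
#' subsets followed by local refinement of the best M + 1 candidates,
#' and ensemble averaging of the populations with stable membership.
#' In unconditional mode a query matching a single panel population
#' (best single-population minimax error below `unmixed_tol`) is
#' reported as unmixed.  With `priors`, the decomposition is constrained
#' to include the named populations unless that degrades the fit by more
#' than `prior_discard_margin` (the prior is then discarded and the
#' unconditional result reported).  With `config$equal_weights` the
#' weights are frozen at `1/p` and only the subset is optimized.
#'
#' @param target query admixture vector (K proportions summing to 1).
#' @param panel a [readmix_panel()].
#' @param priors character vector of prior population names (conditional
#'   mode); must exist in the panel.
#' @param config a [readmix_config()].
#' @param seed optional integer seed; fixing it makes the whole report
#'   reproducible.
#' @return an object of class `readmix_report`: list with `stable` and
#'   `regional` data frames, `mode`, `prior_discarded`, `unmixed`,
#'   `minimax_error`, and the underlying `solutions`.
#' @export
run_readmix <- function(target, panel, priors = character(),
                        config = readmix_config(), seed = NULL) {
  fixed <- if (length(priors) > 0L) panel_index(panel, priors) else integer()
  target <- validate_simplex(target)
  if (length(target) != panel$K) {
    stop("query vector length does not match the panel's K")
  }
  if (!is.null(seed)) set.seed(seed)
  mode <- if (config$equal_weights) "equal_weights"
          else if (length(fixed) > 0L) "conditional" else "unconditional"

  um <- classify_unmixed(target, panel, config)
  if (um$is_unmixed && !config$equal_weights) {
    single <- fit_solution(um$index, panel, target)
    uncond <- c(ensemble_average(list(single), panel, config),
                list(solutions = list(single)))
  } else {
    uncond <- core_run(target, panel, integer(), config)
  }

  prior_discarded <- FALSE
  used <- uncond
  if (length(fixed) > 0L) {
    ap <- apply_prior(target, panel, priors, config, uncond$minimax_error)
    if (ap$discarded) {
      prior_discarded <- TRUE
    } else {
      used <- ap$result
    }
  }

  structure(list(stable = used$stable, regional = used$regional,
                 mode = mode, prior_discarded = prior_discarded,
                 unmixed = um$is_unmixed && !config$equal_weights,
                 minimax_error = used$minimax_error,
                 solutions = used$solutions, K = panel$K),
            class = "readmix_report")
}

#' @export
print.readmix_report <- function(x, ...) {
  cat(sprintf("reAdmix decomposition (%s mode)%s%s\n", x$mode,
              if (x$unmixed) " — unmixed" else "",
              if (x$prior_discarded) " — prior discarded" else ""))
  cat(sprintf("  minimax error: %.6g over %d candidate solution(s)\n",
              x$minimax_error, length(x$solutions)))
  if (nrow(x$stable) > 0L) {
    cat("  stable populations:\n")
    for (i in seq_len(nrow(x$stable))) {
      cat(sprintf("    %-20s weight %.4f (membership %.0f%%)\n",
                  x$stable$population[i], x$stable$weight[i],
                  100 * x$stable$membership[i]))
    }
  } else {
    cat("  no stable populations (see regional candidates)\n")
  }
  if (nrow(x$regional) > 0L) {
    cat("  regional candidates:",
        paste(x$regional$population, collapse = ", "), "\n")
  }
  invisible(x)
}
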