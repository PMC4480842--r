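#' Fit parameters for the affinity search
#'
#' @param epsilon tolerance of the negative-residual penalty: residual
#'   components below `-epsilon` incur the overshoot penalty (default
#'   0.01, the scale of rounding in published admixture tables).
#' @param alpha_grid step of the 1-D grid over which the mixing
#'   proportion alpha is scanned (default 1e-4); must lie in (0, 0.1].
#' @return list with class `fit_params`.
#' @export
fit_params <- function(epsilon = 0.01, alpha_grid = 1e-4) {
  stopifnot(epsilon >= 0, alpha_grid > 0, alpha_grid <= 0.1)
  structure(list(epsilon = epsilon, alpha_grid = alpha_grid),
            class = "fit_params")
}

#' Penalized squared-error loss on a residual vector
#'
#' `sum(d^2)` plus, for every component below `-epsilon`, a penalty of
#' `1 + 2|d|`.  The penalty discourages overshooting the query vector,
#' i.e. including too many (or too strongly weighted) reference
#' populations.
#'
#' @param d numeric residual vector (difference of two admixture
#'   vectors; need not lie on the simplex).
#' @param epsilon penalty activation tolerance (>= 0).
#' @return nonnegative scalar; zero iff `d` is all zero.
#' @examples
#' loss_fn(c(0.1, -0.2), 0.01)  # 0.01 + 0.04 + (1 + 0.4) = 1.45
#' @export
loss_fn <- function(d, epsilon = 0.01) {
  if (any(!is.finite(d))) stop("residual vector contains non-finite values")
  pen <- d < -epsilon
  sum(d^2) + sum(pen * (1 - 2 * d))
}

# loss_fn evaluated for a vector of alpha values at once: column a of
# D = target - alpha_a * p.  Returns one loss per alpha.
loss_over_alphas <- function(p, target, alphas, epsilon) {
  D <- outer(target, rep(1, length(alphas))) - outer(p, alphas)
  pen <- D < -epsilon
  colSums(D^2) + colSums(pen * (1 - 2 * D))
}

#' Affinity of a candidate population to a query vector
#'
#' Finds the mixing proportion `alpha` in \[0, 1\] minimizing
#' `loss_fn(target - alpha * p, epsilon)`.  The search is a deterministic
#' grid scan at step `alpha_grid`, followed by a fine scan at step 1e-6
#' in the bracket around the coarse minimum (the loss is piecewise
#' quadratic with upward jumps where the penalty activates, so a local
#' fine grid is used rather than a smooth-function line search).
#'
#' @param p candidate population admixture vector.
#' @param target query admixture vector (or a greedy residual, which may
#'   lie off the simplex).
#' @param params a [fit_params()].
#' @return list with elements `alpha` (the minimizing proportion) and
#'   `loss` (its loss value).
#' @export
affinity_score <- function(p, target, params = fit_params()) {
  stopifnot(length(p) == length(target))
  step <- params$alpha_grid
  alphas <- seq(0, 1, by = step)
  if (alphas[length(alphas)] < 1) alphas <- c(alphas, 1)
  losses <- loss_over_alphas(p, target, alphas, params$epsilon)
  i <- which.min(losses)
  lo <- max(0, alphas[i] - step)
  hi <- min(1, alphas[i] + step)
  fine <- seq(lo, hi, by = 1e-6)
  fl <- loss_over_alphas(p, target, fine, params$epsilon)
  j <- which.min(fl)
  list(alpha = fine[j], loss = fl[j])
}

#' Chebyshev minimax weights for a fixed population subset
#'
#' Given a subset S of panel populations and a query vector, finds the
#' convex-combination weights A (nonnegative, summing to 1) minimizing
#' the maximum absolute componentwise error between the combination and
#' the query.  This Chebyshev approximation problem is solved exactly as
#' a linear program: minimize t subject to
#' `-t <= (R_S' A - target)_k <= t`, `sum(A) = 1`, `A >= 0`.
#'
#' The optimal minimax value is unique; the weight vector attaining it
#' need not be (when `|S| > K + 1` or the reference vectors are affinely
#' dependent), in which case the solver's vertex optimum is reported.
#'
#' @param S integer vector of distinct panel row indices (non-empty).
#' @param panel a [readmix_panel()].
#' @param target query admixture vector of length `panel$K`.
#' @param equal_weights if `TRUE`, skip the optimization and evaluate the
#'   equally weighted combination `A = (1/p, ..., 1/p)`.
#' @return list with class `fit_result`: `weights` (named by
#'   population), `minimax_error`, and `approximation` (the fitted
#'   K-vector).
#' @export
chebyshev_weights <- function(S, panel, target, equal_weights = FALSE) {
  S <- as.integer(S)
  if (length(S) == 0L) stop("population subset S must be non-empty")
  if (anyDuplicated(S)) stop("population subset S contains duplicate indices")
  if (any(S < 1L | S > panel$N)) stop("population index out of range")
  stopifnot(length(target) == panel$K)
  R <- panel$Q[S, , drop = FALSE]
  p <- length(S)
  if (equal_weights) {
    a <- rep(1 / p, p)
  } else if (p == 1L) {
    a <- 1
  } else {
    K <- panel$K
    obj <- c(rep(0, p), 1)
    A1 <- cbind(t(R), rep(-1, K))   # R'a - t <= target
    A2 <- cbind(t(R), rep(1, K))    # R'a + t >= target
    A3 <- matrix(c(rep(1, p), 0), nrow = 1)
    sol <- boot::simplex(a = obj, A1 = A1, b1 = target,
                         A2 = A2, b2 = target, A3 = A3, b3 = 1,
                         maxi = FALSE, eps = 1e-10)
    if (sol$solved != 1) {
      stop(sprintf(paste0("Chebyshev LP solver failed (status %d) for subset {%s};",
                          " target sum %.6g"),
                   sol$solved, paste(S, collapse = ","), sum(target)))
    }
    a <- sol$soln[seq_len(p)]
    # clean solver dust and restore the exact convex-combination
    # invariants before recomputing the error
    a[a < 0] <- 0
    a <- a / sum(a)
  }
  approx <- as.numeric(crossprod(R, a))
  structure(list(weights = stats::setNames(a, panel$population[S]),
                 minimax_error = max(abs(approx - target)),
                 approximation = approx),
            class = "fit_result")
}

# Internal: fit a subset and package it as a solution object
fit_solution <- function(S, panel, target, equal_weights = FALSE) {
  fr <- chebyshev_weights(S, panel, target, equal_weights = equal_weights)
  structure(list(indices = as.integer(S),
                 weights = unname(fr$weights),
                 minimax_error = fr$minimax_error),
            class = "readmix_solution")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Chebyshev fit: minimax error", format(x$minimax_error, digits = 6), "\n")
  print(round(x$weights, 6))
  invisible(x)
}
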