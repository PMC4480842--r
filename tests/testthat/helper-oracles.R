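# Independent brute-force oracles used to cross-check the analytic /
# LP implementations.  These evaluate the objectives directly on dense
# grids and share no code with the functions they check.

# Dense scan for the loss-minimizing alpha in [0, 1] at a fixed step.
affinity_oracle <- function(p, target, epsilon, step = 1e-6) {
  best_a <- 0
  best_l <- Inf
  # chunked to bound memory
  breaks <- seq(0, 1, length.out = 21)
  for (i in seq_len(20)) {
    alphas <- seq(breaks[i], breaks[i + 1], by = step)
    D <- outer(target, rep(1, length(alphas))) - outer(p, alphas)
    pen <- D < -epsilon
    l <- colSums(D^2) + colSums(pen * (1 - 2 * D))
    j <- which.min(l)
    if (l[j] < best_l) {
      best_l <- l[j]
      best_a <- alphas[j]
    }
  }
  list(alpha = best_a, loss = best_l)
}

# Minimax error of the best convex combination of up to 3 reference
# rows, by two-stage grid search over the weight simplex.
chebyshev_oracle <- function(R, target) {
  p <- nrow(R)
  eval_minimax <- function(W) {
    # W: matrix of weight rows; minimax error of each row's combination
    E <- abs(W %*% R - matrix(target, nrow(W), length(target), byrow = TRUE))
    Reduce(pmax, asplit(E, 2))
  }
  if (p == 1) {
    return(max(abs(R[1, ] - target)))
  }
  if (p == 2) {
    a1 <- seq(0, 1, by = 1e-5)
    return(min(eval_minimax(cbind(a1, 1 - a1))))
  }
  grid2 <- function(lo1, hi1, lo2, hi2, step) {
    a1 <- seq(lo1, hi1, by = step)
    a2 <- seq(lo2, hi2, by = step)
    g <- expand.grid(a1 = a1, a2 = a2)
    g <- g[g$a1 + g$a2 <= 1 + 1e-12, ]
    W <- cbind(g$a1, g$a2, pmax(0, 1 - g$a1 - g$a2))
    e <- eval_minimax(W)
    list(a = W[which.min(e), 1:2], err = min(e))
  }
  coarse <- grid2(0, 1, 0, 1, 0.002)
  fine <- grid2(max(0, coarse$a[1] - 0.002), min(1, coarse$a[1] + 0.002),
                max(0, coarse$a[2] - 0.002), min(1, coarse$a[2] + 0.002),
                1e-5)
  min(coarse$err, fine$err)
}

# Largest admissible greedy weight by direct scan on a 1e-5 grid.
population_weight_oracle <- function(r, residual, epsilon, beta) {
  w <- seq(0, 1, by = 1e-5)
  pos <- r > 1e-12
  ok <- vapply(w, function(wi) all(wi * r[pos] <= residual[pos] + epsilon),
               logical(1))
  max(w[ok], 0) * beta
}
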