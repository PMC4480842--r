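test_that("the best-affinity population is found, with low-index ties", {
  panel <- tiny_panel()
  tv <- panel$Q["Delta", ]
  expect_equal(pick_next_population(panel, tv), 4L)
  # duplicate of Delta earlier in the panel wins the tie
  dup <- readmix_panel(c("Dup", panel$population),
                       c(0, panel$lat), c(0, panel$lon),
                       rbind(panel$Q["Delta", ], panel$Q))
  expect_equal(pick_next_population(dup, tv), 1L)
  expect_error(pick_next_population(panel, tv, exclude = 1:4), "excluded")
})

test_that("greedy pick matches exhaustive affinity evaluation", {
  set.seed(11)
  panel <- generate_panel(20, K = 5, seed = 11)
  pars <- fit_params()
  for (i in 1:5) {
    tv <- validate_simplex(runif(5) + 0.01, tol = Inf)
    losses <- vapply(1:20, function(j) {
      affinity_score(panel$Q[j, ], tv, pars)$loss
    }, numeric(1))
    expect_equal(pick_next_population(panel, tv, params = pars),
                 which.min(losses))
  }
})

test_that("the admissible weight rule matches its definition", {
  gp0 <- greedy_params(beta = 1, epsilon = 0)
  expect_equal(population_weight(c(1, 0), c(0.5, 0.5), gp0), 0.5)
  # candidate equal to the residual: full weight, scaled by beta
  gp <- greedy_params(beta = 0.95, epsilon = 0)
  r <- c(0.3, 0.5, 0.2)
  expect_equal(population_weight(r, r, gp), 0.95)
  expect_error(population_weight(c(0, 0), c(0.5, 0.5), gp), "all components")
})

test_that("the admissible weight matches a 1e-5 grid oracle", {
  set.seed(12)
  gp <- greedy_params(beta = 0.95, epsilon = 0.01)
  for (i in 1:10) {
    r <- validate_simplex(runif(4) + 0.01, tol = Inf)
    residual <- runif(4, -0.05, 0.6)
    got <- population_weight(r, residual, gp)
    ora <- population_weight_oracle(r, residual, gp$epsilon, gp$beta)
    expect_lt(abs(got - ora), 1e-5 * gp$beta + 1e-12)
  }
})

test_that("greedy subtraction keeps residuals above -epsilon", {
  set.seed(13)
  gp <- greedy_params(beta = 0.95, epsilon = 0.01)
  for (i in 1:20) {
    r <- validate_simplex(runif(5) + 0.01, tol = Inf)
    residual <- runif(5, 0, 0.5)
    w <- population_weight(r, residual, gp)
    expect_true(all(residual - w * r >= -gp$epsilon - 1e-12))
  }
})

test_that("greedy construction recovers simple solutions", {
  panel <- tiny_panel()
  sol <- build_initial_solution(panel, panel$Q["Delta", ],
                                params = greedy_params(max_pops = 1))
  expect_equal(sol$indices, 4L)
  expect_equal(sol$weights, 1)
  expect_equal(sol$minimax_error, 0, tolerance = 1e-10)

  # two-source noiseless mixture; distractors far (L-infinity) from the
  # sources and from the mixture
  panel2 <- readmix_panel(
    c("SrcA", "SrcB", "FarC", "FarD"),
    lat = c(50, 0, 40, 35), lon = c(15, 25, -100, 105),
    Q = rbind(c(0.90, 0.05, 0.05, 0.00),
              c(0.05, 0.85, 0.05, 0.05),
              c(0.00, 0.00, 0.90, 0.10),
              c(0.05, 0.00, 0.10, 0.85)))
  tv <- 0.5 * panel2$Q[1, ] + 0.5 * panel2$Q[2, ]
  sol <- build_initial_solution(panel2, tv,
                                params = greedy_params(max_pops = 2))
  expect_setequal(sol$indices, c(1L, 2L))
  expect_lt(sol$minimax_error, 1e-8)

  # a fixed prior equal to the query dominates the solution
  sol <- build_initial_solution(panel, panel$Q["Delta", ], fixed = 4L)
  expect_true(4L %in% sol$indices)
  expect_equal(sol$weights[sol$indices == 4L], 1, tolerance = 1e-8)
})

test_that("sparsity stop: an exact subset is not padded to max_pops", {
  panel <- readmix_panel(
    c("SrcA", "SrcB", "FarC", "FarD"),
    lat = c(50, 0, 40, 35), lon = c(15, 25, -100, 105),
    Q = rbind(c(0.90, 0.05, 0.05, 0.00),
              c(0.05, 0.85, 0.05, 0.05),
              c(0.00, 0.00, 0.90, 0.10),
              c(0.05, 0.00, 0.10, 0.85)))
  tv <- 0.5 * panel$Q[1, ] + 0.5 * panel$Q[2, ]
  sol <- build_initial_solution(panel, tv, params = greedy_params(max_pops = 4))
  expect_equal(length(sol$indices), 2L)
  expect_setequal(sol$indices, c(1L, 2L))
})

test_that("swap improvement is monotone and finds exact twins", {
  panel <- tiny_panel()
  # already optimal: unchanged
  sol <- build_initial_solution(panel, panel$Q["Delta", ],
                                params = greedy_params(max_pops = 1))
  expect_identical(swap_improve(sol, panel, panel$Q["Delta", ])$indices,
                   sol$indices)

  # a wrong near-twin swaps to the exact duplicate of the true source
  twin <- readmix_panel(
    c("True", "Twin", "Other"), c(0, 1, 50), c(0, 1, 50),
    rbind(c(0.6, 0.3, 0.1),
          c(0.58, 0.31, 0.11),
          c(0.1, 0.1, 0.8)))
  tv <- twin$Q["True", ]
  bad <- structure(list(indices = 2L, weights = 1,
                        minimax_error = max(abs(twin$Q[2, ] - tv))),
                   class = "readmix_solution")
  fixed_up <- swap_improve(bad, twin, tv)
  expect_equal(fixed_up$indices, 1L)
  expect_equal(fixed_up$minimax_error, 0, tolerance = 1e-12)
})

test_that("swap improvement beats the exhaustive single-swap oracle", {
  set.seed(14)
  panel <- generate_panel(15, K = 4, seed = 14)
  for (i in 1:5) {
    tv <- validate_simplex(runif(4) + 0.01, tol = Inf)
    S <- sample(15, 2)
    sol <- structure(
      c(list(indices = as.integer(S)),
        chebyshev_weights(S, panel, tv)[c("weights", "minimax_error")]),
      class = "readmix_solution")
    sol$weights <- unname(sol$weights)
    improved <- swap_improve(sol, panel, tv)
    expect_lte(improved$minimax_error, sol$minimax_error + 1e-12)
    # one round of best single swaps can do no better
    best_single <- min(vapply(S, function(x) {
      min(vapply(setdiff(1:15, S), function(y) {
        chebyshev_weights(c(setdiff(S, x), y), panel, tv)$minimax_error
      }, numeric(1)))
    }, numeric(1)))
    expect_lte(improved$minimax_error, best_single + 1e-9)
  }
})
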