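test_that("random panels are valid, reproducible and shaped by concentration", {
  p1 <- generate_panel(10, K = 6, concentration = 1, seed = 61)
  expect_equal(unname(rowSums(p1$Q)), rep(1, 10))
  expect_true(all(p1$Q >= 0))
  expect_true(all(p1$V >= 1e-5 & p1$V <= 1e-3))
  p2 <- generate_panel(10, K = 6, concentration = 1, seed = 61)
  expect_identical(p1$Q, p2$Q)
  expect_identical(p1$lat, p2$lat)
  # tiny concentration: predominantly near-vertex vectors
  pv <- generate_panel(6, K = 2, concentration = 0.05, seed = 62)
  expect_gte(mean(apply(pv$Q, 1, max) > 0.7), 5 / 6)
})

test_that("benchmark panels have pure sources and balanced groups", {
  panel <- generate_benchmark_panel(n_pops = 12, K = 4, seed = 63)
  expect_equal(as.integer(table(panel$group)), rep(3L, 4))
  expect_equal(unname(panel$Q["European1", ]), c(1, 0, 0, 0))
  expect_equal(unname(panel$Q["African1", ]), c(0, 1, 0, 0))
  # non-source members keep most mass on their own component
  own <- vapply(seq_len(panel$N), function(i) {
    panel$Q[i, match(panel$group[i], c("European", "African",
                                       "NativeAmerican", "EastAsian"))]
  }, numeric(1))
  expect_true(all(own >= 0.7))
  expect_equal(unname(rowSums(panel$Q)), rep(1, 12))
})

test_that("noiseless simulated mixtures are exact weighted means", {
  panel <- tiny_panel()
  sc <- mixture_scenario(c("Alpha", "Beta"), c(0.5, 0.5))
  expect_equal(simulate_mixture(panel, sc),
               unname(0.5 * panel$Q[1, ] + 0.5 * panel$Q[2, ]))
  # the three-way 50 x 25 x 25 scenario
  sc3 <- mixture_scenario(c("Alpha", "Beta", "Gamma"), c(0.5, 0.25, 0.25))
  expect_equal(simulate_mixture(panel, sc3),
               unname(0.5 * panel$Q[1, ] + 0.25 * panel$Q[2, ] +
                        0.25 * panel$Q[3, ]))
  expect_error(mixture_scenario("Alpha", 1), ">= 2")
})

test_that("noise variance follows the scenario model", {
  # interior vectors so clipping/renormalization is negligible
  panel <- readmix_panel(c("P1", "P2"), c(0, 10), c(0, 10),
                         Q = rbind(c(0.4, 0.35, 0.25), c(0.2, 0.3, 0.5)),
                         V = rbind(c(8e-4, 5e-4, 6e-4),
                                   c(4e-4, 9e-4, 7e-4)))
  w <- c(0.5, 0.5)
  eps <- 0.05
  sc <- mixture_scenario(c("P1", "P2"), w, eps = eps)
  set.seed(64)
  sims <- t(replicate(1000, simulate_mixture(panel, sc)))
  expected_var <- eps^2 * as.numeric(crossprod(panel$V, w^2))
  # renormalization to the simplex couples the components: by the delta
  # method, var(t_k') = (1 - t_k)^2 v_k + t_k^2 sum_{j != k} v_j
  tv0 <- as.numeric(crossprod(panel$Q, w))
  delta_var <- vapply(1:3, function(k) {
    (1 - tv0[k])^2 * expected_var[k] + tv0[k]^2 * sum(expected_var[-k])
  }, numeric(1))
  expect_lt(max(abs(apply(sims, 2, var) / delta_var - 1)), 0.2)
  # and stays on the scale of the unconstrained noise model
  expect_lt(max(abs(apply(sims, 2, var) / expected_var - 1)), 0.5)

  # variance grows as eps^2: ratio across eps values
  v_by_eps <- vapply(c(0.01, 0.03, 0.05), function(e) {
    sce <- mixture_scenario(c("P1", "P2"), w, eps = e)
    set.seed(65)
    var(replicate(800, simulate_mixture(panel, sce)[1]))
  }, numeric(1))
  expect_equal(v_by_eps[2] / v_by_eps[1], 9, tolerance = 0.25)
  expect_equal(v_by_eps[3] / v_by_eps[1], 25, tolerance = 0.25)

  # a panel without variances cannot be used with eps > 0
  nov <- readmix_panel(c("P1", "P2"), c(0, 1), c(0, 1),
                       Q = rbind(c(0.5, 0.5), c(0.2, 0.8)))
  expect_error(simulate_mixture(nov, mixture_scenario(c("P1", "P2"),
                                                      eps = 0.01)),
               "variance")
})

test_that("zombie genotypes follow binomial sampling from frequencies", {
  L <- 200
  P <- cbind(rep(0, L), rep(1, L), rep(0.3, L))
  expect_true(all(zombie_genotypes(P, 1, m = 5, seed = 1) == 0))
  expect_true(all(zombie_genotypes(P, 2, m = 5, seed = 1) == 2))
  G <- zombie_genotypes(cbind(rep(0.3, 10000)), 1, m = 15, seed = 66)
  expect_equal(dim(G), c(15, 10000))
  expect_true(all(G %in% 0:2))
  se <- sqrt(2 * 0.3 * 0.7 / (15 * 10000))
  expect_lt(abs(mean(G) - 0.6), 3 * se)
  expect_identical(zombie_genotypes(P, 3, m = 4, seed = 2),
                   zombie_genotypes(P, 3, m = 4, seed = 2))
  expect_error(zombie_genotypes(P, 9, m = 2), "out of range")
  expect_error(zombie_genotypes(P - 2, 1), "frequencies")
})

test_that("great-circle distances match closed forms", {
  expect_equal(haversine_km(c(12, 34), c(12, 34)), 0)
  expect_equal(haversine_km(c(0, 0), c(0, 180)), pi * 6371,
               tolerance = 1e-6)
  expect_equal(haversine_km(c(0, 0), c(0, 90)), pi * 6371 / 2,
               tolerance = 1e-6)
  expect_equal(haversine_km(c(90, 0), c(-90, 0)), pi * 6371,
               tolerance = 1e-6)
})

test_that("prediction scoring distinguishes name and position accuracy", {
  panel <- tiny_panel()
  mk_report <- function(pops, w) {
    idx <- match(pops, panel$population)
    structure(list(stable = data.frame(population = pops, weight = w,
                                       membership = rep(1, length(pops)),
                                       lat = panel$lat[idx],
                                       lon = panel$lon[idx]),
                   regional = data.frame(), mode = "unconditional",
                   prior_discarded = FALSE, unmixed = FALSE,
                   minimax_error = 0, solutions = list(), K = panel$K),
              class = "readmix_report")
  }
  truth <- mixture_scenario(c("Alpha", "Beta"), c(0.5, 0.5))
  exact <- evaluate_prediction(mk_report(c("Alpha", "Beta"), c(0.5, 0.5)),
                               truth, panel)
  expect_true(exact$correct_position)
  expect_true(exact$at_least_one_correct_origin)
  expect_true(exact$correct_populations)
  expect_equal(exact$avg_distance_km, 0)

  # wrong names but geographically close: position correct, names not
  near <- readmix_panel(c("TrueSrc", "NearMiss"), c(50, 50.9), c(15, 15),
                        Q = rbind(c(0.9, 0.1), c(0.1, 0.9)))
  rep_near <- structure(list(
    stable = data.frame(population = "NearMiss", weight = 1, membership = 1,
                        lat = 50.9, lon = 15),
    regional = data.frame(), mode = "unconditional",
    prior_discarded = FALSE, unmixed = TRUE, minimax_error = 0,
    solutions = list(), K = 2), class = "readmix_report")
  tr <- list(sources = c("TrueSrc", "NearMiss"), weights = c(0.5, 0.5))
  one <- evaluate_prediction(rep_near,
                             mixture_scenario(c("TrueSrc", "NearMiss"),
                                              c(0.5, 0.5)), near)
  expect_true(one$correct_position)       # ~100 km < 320 km
  expect_false(one$correct_populations)
  expect_true(one$at_least_one_correct_origin)
  expect_lt(one$avg_distance_km, 110)
  expect_gt(one$avg_distance_km, 40)

  # order of predicted and true populations is irrelevant
  sw <- evaluate_prediction(mk_report(c("Beta", "Alpha"), c(0.5, 0.5)),
                            mixture_scenario(c("Beta", "Alpha")), panel)
  expect_true(sw$correct_populations)

  # empty stable set scores zero everywhere
  none <- mk_report(character(0), numeric(0))
  z <- evaluate_prediction(none, truth, panel)
  expect_false(z$correct_position)
  expect_false(z$at_least_one_correct_origin)
  expect_gt(z$avg_distance_km, 0)
})

test_that("batch metrics aggregate to hand-counted percentages", {
  cases <- data.frame(
    correct_position = c(TRUE, TRUE, FALSE),
    at_least_one_correct_origin = c(TRUE, FALSE, FALSE),
    correct_populations = c(TRUE, FALSE, FALSE),
    avg_distance_km = c(0, 100, 900))
  m <- summarize_metrics(cases)
  expect_equal(m$correct_position_pct, 200 / 3)
  expect_equal(m$at_least_one_correct_origin_pct, 100 / 3)
  expect_equal(m$correct_populations_pct, 100 / 3)
  expect_equal(m$avg_distance_to_correct_population_km, 1000 / 3)
})

test_that("ancestry composition maps solutions into component space", {
  panel <- generate_benchmark_panel(n_pops = 12, K = 4, seed = 67)
  tv <- 0.2 * panel$Q["European1", ] + 0.8 * panel$Q["African1", ]
  rep <- run_readmix(tv, panel, config = fast_config(), seed = 6)
  comp <- ancestry_composition(rep, panel, by = "component")
  expect_equal(unname(comp), unname(tv), tolerance = 1e-6)
  grp <- ancestry_composition(rep, panel, by = "group")
  expect_equal(unname(grp[c("European", "African")]), c(0.2, 0.8),
               tolerance = 1e-6)
})
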