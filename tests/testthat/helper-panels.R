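# Shared fixture builders (all generated in code; no data files).

# Tiny hand-built panel: K = 3, four populations at known points.
tiny_panel <- function() {
  readmix_panel(
    population = c("Alpha", "Beta", "Gamma", "Delta"),
    lat = c(50, 0, 40, 35), lon = c(15, 25, -100, 105),
    Q = rbind(c(1, 0, 0),
              c(0, 1, 0),
              c(0, 0, 1),
              c(0.5, 0.3, 0.2)),
    V = matrix(1e-4, 4, 3))
}

# Panel with three near-identical, co-located populations (related
# neighbors, e.g. Belorussian/Russian/Ukrainian) plus two outgroups.
related_trio_panel <- function() {
  base <- c(0.55, 0.35, 0.05, 0.05)
  readmix_panel(
    population = c("NeighborA", "NeighborB", "NeighborC", "Far1", "Far2"),
    lat = c(53.9, 55.7, 50.4, 0, 35),
    lon = c(27.6, 37.6, 30.5, 25, 105),
    Q = rbind(base,
              validate_simplex(base + c(0.015, -0.015, 0, 0)),
              validate_simplex(base + c(-0.015, 0.01, 0.005, 0)),
              c(0.05, 0.05, 0.85, 0.05),
              c(0.05, 0.05, 0.05, 0.85)))
}

# A random mixture instance with well-separated sources: a K = 8 panel
# of 12 populations drawn near the simplex vertices, sources chosen by
# max-min L-infinity separation (>= 0.4 between sources, every
# distractor >= 0.1 away from every source).  Panels are redrawn from
# the running RNG stream until the separation conditions hold, so the
# instance is deterministic given the seed.
recovery_instance <- function(seed, n_sources, eps = 0) {
  set.seed(seed)
  scen_w <- list(NULL, c(0.5, 0.5), c(0.5, 0.25, 0.25), rep(0.25, 4))
  repeat {
    panel <- generate_panel(12, K = 8, concentration = 0.3)
    D <- as.matrix(stats::dist(panel$Q, method = "maximum"))
    # greedy max-min separated subset
    src <- as.integer(which(D == max(D), arr.ind = TRUE)[1, ])
    while (length(src) < n_sources) {
      d <- apply(D[, src, drop = FALSE], 1, min)
      d[src] <- -1
      src <- c(src, which.max(d))
    }
    ok_src <- min(D[src, src][upper.tri(diag(length(src)))]) >= 0.4
    ok_dist <- all(apply(D[-src, src, drop = FALSE], 1, min) >= 0.1)
    if (ok_src && ok_dist) break
  }
  scen <- mixture_scenario(panel$population[src], scen_w[[n_sources]],
                           eps = eps)
  list(panel = panel, scenario = scen,
       target = simulate_mixture(panel, scen))
}

# Fast pipeline configuration for unit tests (smaller DE budget).
fast_config <- function(...) {
  readmix_config(de = de_config(NP = 16, G_max = 40, M = 5), ...)
}
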