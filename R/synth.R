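#' Generate a random synthetic reference panel
#'
#' Populations receive admixture vectors drawn from a symmetric
#' Dirichlet distribution (small `concentration` pushes vectors toward
#' the simplex vertices, i.e. well-differentiated populations; large
#' values produce heavily admixed ones), uniform random world
#' coordinates, per-component variances uniform in \[1e-5, 1e-3\]
#' (the scale of sampling noise in population-mean admixture
#' proportions), and sample sizes between 2 and 15 as observed in
#' real reference databases.
#'
#' @param n_pops number of populations (>= 2).
#' @param K number of admixture components (>= 2).
#' @param concentration symmetric Dirichlet concentration (default 1 =
#'   uniform on the simplex).
#' @param seed optional RNG seed.
#' @return a [readmix_panel()] with variances and sample sizes.
#' @export
generate_panel <- function(n_pops, K, concentration = 1, seed = NULL) {
  stopifnot(n_pops >= 2, K >= 2, concentration > 0)
  if (!is.null(seed)) set.seed(seed)
  G <- matrix(stats::rgamma(n_pops * K, shape = concentration), n_pops, K)
  # guard exact zeros from gamma underflow at small concentrations
  # without distorting the draw
  G[G < 1e-300] <- 1e-300
  Q <- G / rowSums(G)
  readmix_panel(population = sprintf("Pop%02d", seq_len(n_pops)),
                lat = stats::runif(n_pops, -55, 70),
                lon = stats::runif(n_pops, -180, 180),
                Q = Q,
                V = matrix(stats::runif(n_pops * K, 1e-5, 1e-3), n_pops, K),
                sample_n = sample(2:15, n_pops, replace = TRUE))
}

# region centers (lat, lon) used to place ancestry groups on the map
.group_centers <- list(European = c(50, 15), African = c(0, 25),
                       NativeAmerican = c(40, -100), EastAsian = c(35, 105))

#' Generate an ancestry-group-structured benchmark panel
#'
#' Builds a panel whose populations fall into K ancestry groups (for
#' K = 4: European, African, Native American, East Asian), assigned
#' round-robin so groups are balanced.  The first population of each
#' group named in `source_groups` is a designated source; pure sources
#' sit exactly on their group's simplex vertex.  All other populations
#' carry most of their mass on their own component, with an admixed
#' fraction drawn uniformly from `admix_frac_range` and spread over two
#' other components — mirroring real continental panels, where
#' populations share 70-95% of their own ancestral component and have
#' exact zeros elsewhere.  Group members are placed around a common
#' regional center so geographic distances are meaningful.
#'
#' @param n_pops total number of populations.
#' @param K number of components / ancestry groups (2-4 named groups).
#' @param source_groups character names of groups that receive a
#'   designated source population.
#' @param pure_sources logical, recycled over `source_groups`: whether
#'   each source is pure (exactly the group vertex).
#' @param admix_frac_range range of the admixed mass of non-pure
#'   populations (default 0.05-0.3).
#' @param seed optional RNG seed.
#' @return a [readmix_panel()] with `group` labels; designated sources
#'   are the first population of each source group (named e.g.
#'   `"European1"`).
#' @export
generate_benchmark_panel <- function(n_pops = 12, K = 4,
                                     source_groups = c("European", "African"),
                                     pure_sources = TRUE,
                                     admix_frac_range = c(0.05, 0.3),
                                     seed = NULL) {
  stopifnot(K >= 2, K <= 4, n_pops >= K)
  if (!is.null(seed)) set.seed(seed)
  groups <- names(.group_centers)[seq_len(K)]
  stopifnot(all(source_groups %in% groups))
  pure_sources <- rep_len(pure_sources, length(source_groups))
  gidx <- ((seq_len(n_pops) - 1L) %% K) + 1L   # round-robin group labels
  member <- stats::ave(seq_len(n_pops), gidx, FUN = seq_along)
  gname <- groups[gidx]
  Q <- matrix(0, n_pops, K)
  for (i in seq_len(n_pops)) {
    g <- gidx[i]
    is_source <- member[i] == 1L && gname[i] %in% source_groups
    pure <- is_source && pure_sources[match(gname[i], source_groups)]
    if (pure) {
      Q[i, g] <- 1
    } else {
      m <- stats::runif(1, admix_frac_range[1], admix_frac_range[2])
      # spread over two other components: a population admixed toward a
      # single neighbor could, together with that neighbor's source,
      # reproduce a two-way source mixture exactly, which real
      # continental panels do not do
      others <- sample(setdiff(seq_len(K), g), size = min(2L, K - 1L))
      share <- stats::runif(length(others))
      Q[i, others] <- m * share / sum(share)
      Q[i, g] <- 1 - m
    }
  }
  centers <- do.call(rbind, .group_centers[gname])
  readmix_panel(population = paste0(gname, member),
                lat = pmin(89, pmax(-89, centers[, 1] +
                                      stats::runif(n_pops, -8, 8))),
                lon = centers[, 2] + stats::runif(n_pops, -8, 8),
                Q = Q,
                V = matrix(stats::runif(n_pops * K, 1e-5, 1e-3), n_pops, K),
                sample_n = sample(2:15, n_pops, replace = TRUE),
                group = gname)
}

#' Define a mixture scenario
#'
#' A scenario names 2-4 source populations with positive weights
#' summing to 1 and a noise scale, e.g. the "50 x 50",
#' "50 x 25 x 25" and "25 x 25 x 25 x 25" marriage scenarios.
#'
#' @param sources character vector of 2-4 source population names.
#' @param weights positive weights summing to 1 (default equal).
#' @param eps noise scale (0 = noiseless; typical values 0.01, 0.03,
#'   0.05 emulate within-population variability of admixture
#'   proportions).
#' @return list with class `mixture_scenario`.
#' @export
mixture_scenario <- function(sources, weights = NULL, eps = 0) {
  n <- length(sources)
  stopifnot(n >= 2, n <= 4, eps >= 0)
  if (is.null(weights)) weights <- rep(1 / n, n)
  stopifnot(length(weights) == n, all(weights > 0),
            abs(sum(weights) - 1) < 1e-8)
  structure(list(sources = as.character(sources),
                 weights = as.numeric(weights) / sum(weights), eps = eps),
            class = "mixture_scenario")
}

#' Simulate an admixed individual from a mixture scenario
#'
#' The simulated vector is the weighted mean of the source population
#' vectors plus componentwise Gaussian noise with variance
#' `eps^2 * sum(w_i^2 * sigma^2_k(r_i))` (the weighted sum of the
#' per-component population variances), clipped at zero and
#' renormalized to the simplex.
#'
#' @param panel a [readmix_panel()]; must carry variances when
#'   `eps > 0`.
#' @param scenario a [mixture_scenario()].
#' @return a K-component admixture vector.
#' @export
simulate_mixture <- function(panel, scenario) {
  idx <- panel_index(panel, scenario$sources)
  w <- scenario$weights
  tv <- as.numeric(crossprod(panel$Q[idx, , drop = FALSE], w))
  if (scenario$eps > 0) {
    if (is.null(panel$V)) {
      stop("panel has no per-component variances; generate the panel with ",
           "variances (see generate_panel) or add v1..vK columns")
    }
    vark <- as.numeric(crossprod(panel$V[idx, , drop = FALSE], w^2))
    tv <- tv + scenario$eps * stats::rnorm(panel$K, 0, sqrt(vark))
    tv[tv < 0] <- 0
  }
  tv / sum(tv)
}

#' Sample synthetic ("zombie") genotypes from ancestral allele
#' frequencies
#'
#' For ancestral population `k`, each of `m` synthetic individuals gets
#' an independent Binomial(n = 2, p = P\[j, k\]) genotype (0, 1 or 2
#' copies of the allele) at every locus `j` — a likely genotype of an
#' individual drawn from that ancestral population.
#'
#' @param P L x K matrix of ancestral allele frequencies in \[0, 1\].
#' @param k ancestral population column index.
#' @param m number of individuals to sample (default 15).
#' @param seed optional RNG seed.
#' @return m x L integer matrix of genotypes in `{0, 1, 2}`.
#' @export
zombie_genotypes <- function(P, k, m = 15, seed = NULL) {
  P <- as.matrix(P)
  if (any(P < 0 | P > 1)) stop("allele frequencies must lie in [0, 1]")
  k <- as.integer(k)
  if (k < 1L || k > ncol(P)) stop("ancestral index k out of range")
  if (!is.null(seed)) set.seed(seed)
  L <- nrow(P)
  matrix(stats::rbinom(m * L, size = 2L, prob = rep(P[, k], each = m)),
         nrow = m, ncol = L)
}
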