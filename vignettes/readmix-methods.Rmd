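---
title: "Decomposing admixture vectors into reference populations: model and methods"
author: "readmixr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing admixture vectors into reference populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(readmixr)
```

## The problem

Global ancestry tools such as ADMIXTURE summarize an individual's genome
as a vector of $K$ proportions over putative ancestral populations.  For
an unmixed individual this vector sits close to the mean vector of one
modern reference population, and nearest-population assignment works
well.  For a recently admixed individual — say, one Russian and one
Kenyan grandparent line — the vector sits *between* reference
populations, and nearest-population assignment lands on a population in
the geographic or genetic middle that has nothing to do with the
individual's actual ancestry.

`readmixr` instead models the query vector $T = (t_1, \dots, t_K)$ as a
convex combination of reference-population vectors.  Both $T$ and the
$N$ reference rows $r_i$ of the panel matrix $R$ have nonnegative
entries summing to one, i.e. they are points on the standard
$(K-1)$-simplex.  The task is to find a *small* index set
$S = (s_1, \dots, s_p)$ and weights $A = (a_1, \dots, a_p)$,
$a_i \ge 0$, $\sum a_i = 1$, such that

$$P = \sum_{i=1}^{p} a_i\, r_{s(i)} \approx T .$$

Sparsity matters: when $N > K + 1$ many convex combinations reproduce
the same point, so the smallest adequate subset (at most `max_pops`
populations, default 4 — the grandparent time frame) is what is sought,
optionally anchored by user-supplied prior populations.

## Fit criteria

**Chebyshev objective.**  For a fixed subset $S$, the weights minimize
the worst componentwise error
$f(S, T) = \min_A \max_k |P_k - t_k|$.
This is a classic Chebyshev approximation problem, solved exactly as a
linear program (minimize $t$ subject to $-t \le (R_S^\top A - T)_k \le
t$, $A \ge 0$, $\sum a_i = 1$) via the two-phase simplex method
(`boot::simplex`, tolerance $10^{-10}$).  The minimal error is unique;
the weights attaining it need not be when the subset is affinely
dependent or larger than $K + 1$, in which case the solver's vertex
optimum is reported (vertex solutions also zero out non-contributing
populations, which serves the sparsity goal).  `chebyshev_weights()`
cleans solver dust (clips weights at 0, renormalizes their sum to 1)
before recomputing the reported error, so the returned error is always
exactly `max(abs(approximation - target))`.

**Affinity score.**  The greedy phase ranks candidate populations by
how much of the current residual they can absorb.  For candidate $P$
and residual $T$, the affinity is the mixing proportion
$\alpha \in [0, 1]$ minimizing the penalized loss

$$L(d) = \sum_k d_k^2 + \sum_{k:\, d_k < -\varepsilon} (1 + 2 |d_k|),
\qquad d = T - \alpha P .$$

The second term activates when a component is overshot by more than
$\varepsilon$ and penalizes over-inclusion of populations.  The default
$\varepsilon = 0.01$ matches the rounding scale of published admixture
tables.  As a function of $\alpha$, $L$ is piecewise quadratic with
*upward jumps* at each activation threshold, so smooth line searches
(golden section, Brent) can bracket the wrong piece.  The implementation
therefore scans a grid of step `alpha_grid` ($10^{-4}$) and then
rescans the bracket around the coarse minimum at step $10^{-6}$; this
is deterministic and agrees with a dense $10^{-6}$ scan to one step.

## The three phases

**Phase 1 — greedy construction and swap improvement.**  Starting from
the prior populations (conditional mode) or the empty set, repeatedly:
pick the population with the best affinity to the residual; give it the
largest weight that keeps every component of the residual above
$-\varepsilon$, scaled by $\beta$ (default 0.95 — slightly below 1 so a
component is never exhausted by an early, possibly suboptimal pick);
subtract; repeat until `max_pops` populations are chosen *or* the
subset already reproduces $T$ to `stop_tol` ($10^{-6}$) minimax error —
the early stop keeps solutions as sparse as the data allows.  Weights
are then re-fit on the full subset by the LP, and all (solution,
outside) population swaps are tried repeatedly, applying the best
strictly improving swap until none remains (best-improvement order, for
determinism).

**Phase 2 — global and local search.**  The greedy solution is combined
with $M$ (default 10) random index sets of the same size and handed to
a differential-evolution search over index vectors.  Each coordinate is
a continuous value in $[0, N)$; decoding floors it to a population
index with wrap-around, and duplicates within a vector are repaired by
advancing to the next unused index.  Every generation, each of the `NP`
(default 30) members is challenged by a trial vector built from a
rand/1 mutant $v = q_{r1} + S (q_{r2} - q_{r3})$ and a trigonometric
mutant (the centroid of three members perturbed along their pairwise
differences with coefficients from the members' relative objective
magnitudes), combined by binomial or exponential crossover; the trial
replaces the member only if its objective strictly decreases.  Every
`substitution_period` (20) generations, the `substitution_count` (3)
longest-unimproved members are overwritten by copies of the current
best — an age-based restart that concentrates the set.  Objective
evaluations within a generation are independent: trials are built from
the generation-start population and applied synchronously, so any
degree of evaluation parallelism yields bit-identical results (the
`workers` setting is accepted for interface compatibility; evaluations
run serially here).  Objective values per decoded subset are memoised,
which makes the many revisits of converged sets nearly free.

The best $M + 1$ members of the final set are then refined locally:
the candidate neighborhood of a solution is every population within
`local_radius_km` (500 km) of a member plus each member's `local_knn`
(10) nearest populations in $L_\infty$ admixture distance, and all
single-population replacements from the neighborhood are tried to a
fixed point.  While a solution's error still exceeds $\varepsilon$,
replacements of population *pairs* are also tried: single swaps alone
can stall in local minima two substitutions away from the optimum,
which is exactly the failure mode the local step exists to remove
(distinguishing closely related neighbors such as Belorussian, Russian
and Ukrainian panels).  Finally, numerically zero-weight members
($< 10^{-6}$) are dropped and the subset re-fit.

**Phase 3 — ensemble averaging.**  A population is *stable* if it
appears in at least `stable_membership_frac` (75%, inclusive) of the
$M + 1$ refined solutions; stable populations are reported with their
mean weights (over the solutions containing them) renormalized to sum
to 1.  The remaining populations are listed as *regional* candidates
with their membership fractions — at small $K$ many subsets can
represent the same point exactly, and the regional list is where that
ambiguity surfaces.  `ancestry_composition()` maps the ensemble back
into ancestry space (the mean fitted $P$ over solutions, or the
group-label sums of the weights), which is the representation that
remains well defined even when population identity is ambiguous.

## Modes

**Unmixed classification** runs first: if the best single-population
fit has minimax error at most `unmixed_tol` (0.02, conservative
relative to the few-percent within-population variability of panel
admixture means), the individual is reported unmixed with that single
population at weight 1.

**Conditional mode** seeds the solution with user-named prior
populations, which are never swapped out, and compares the best
conditional error with the unconditional one.  If the conditional fit
is worse by more than `prior_discard_margin` (0.05), the prior is
declared to contradict the genotype, the flag is set, and the
unconditional result is reported.  Because weights may legitimately be
zero, a wrong prior usually costs nothing — the LP parks it at ~0
weight — and is then *kept* (at negligible weight) rather than
discarded; the discard fires when the prior displaces needed capacity,
i.e. when all `max_pops` slots are required by the true sources, or in
equal-weights mode where every member must carry weight $1/p$.

**Equal-weights mode** freezes $A = (1/p, \dots, 1/p)$ (the case of a
marriage between known-many lines) and optimizes only the subset, which
is then always built to exactly `max_pops` members; `max_pops` is the
assumed number of contributors in this mode.

## The synthetic data generator

`generate_panel()` draws admixture rows from a symmetric Dirichlet
(concentration < 1 gives well-differentiated, near-vertex populations),
uniform world coordinates, per-component variances uniform in
$[10^{-5}, 10^{-3}]$ (the scale of sampling noise in population means
estimated from a handful of genotyped individuals) and sample sizes of
2–15, as in real reference databases.  `generate_benchmark_panel()`
builds ancestry-group-structured panels (European, African, Native
American, East Asian for $K = 4$): designated source populations can be
exactly pure (simplex vertices), and every other population keeps
70–95% of its own component with the admixed remainder spread over
exactly two other components.  The two-component spread is deliberate:
a distractor admixed toward a single neighboring group could combine
with that group's source to reproduce a two-way mixture exactly,
destroying the identifiability that the two-way benchmark presumes;
with two-component spread every distractor touches an ancestry group
absent from the mixture, so the true pair is the unique zero-error
solution.

`simulate_mixture()` implements
$T = \sum_i w_i r_i + \epsilon\, N\!\big(0, \textstyle\sum_i w_i^2
\sigma^2(r_i)\big)$, clipping negatives and renormalizing to the
simplex.  Renormalization couples the components: by the delta method
the realized per-component variance is
$(1 - t_k)^2 v_k + t_k^2 \sum_{j \ne k} v_j$ rather than the raw
$v_k = \epsilon^2 \sum_i w_i^2 \sigma_k^2(r_i)$ — about 30% lower for
central components.  The $\epsilon^2$ scaling across noise levels is
unaffected.  `zombie_genotypes()` samples synthetic individuals from an
ancestral allele-frequency matrix, Binomial$(2, P_{jk})$ per locus —
likely genotypes of individuals drawn from an ancestral population.

What the generator does *not* emulate: linkage between markers (the
admixture vectors carry no positional information by construction),
correlated estimation noise across components of a real ADMIXTURE fit,
unbalanced world coverage of real panels, and reference populations
that are themselves recently admixed.  Passing tests on these synthetic
panels therefore demonstrate correctness of the decomposition machinery
under the stated noise model, not field accuracy on any real database.

## Evaluation metrics

`evaluate_prediction()` scores a decomposition against the simulated
truth: *correct populations* (predicted stable set equals the true
source set exactly), *at least one correct origin* (any name matches),
and *correct position*, defined as the mean over true sources of the
great-circle distance to the nearest predicted population being at most
320 km.  With several true origins, the per-true-source
nearest-prediction mean is one defensible aggregation of the single
320-km rule; others (e.g. per-origin counting) are possible.  An empty
stable set scores zero on all flags with the distance set to the worst
observed.  Distances use the haversine formula with Earth radius
6371 km.

## Numerical choices and problem sizes

* Renormalization of near-1 row sums (tolerance 0.01 on input) is a
  floating-point fixed point: vectors already summing to 1 within
  $10^{-12}$ are returned unchanged, so read–write–read cycles are
  byte-stable; panels are written with 17 significant digits.
* Ties in the greedy pick and in DE member ordering break toward the
  lowest index; selection requires a strict decrease; swap and local
  refinement apply the best improvement and stop below $10^{-9}$ gains
  — all choices made for determinism.  A fixed seed reproduces the
  entire report.
* The LP cannot be infeasible under the convex-combination constraints;
  solver failures (never observed) raise an error with the offending
  subset.
* Test and benchmark runs use panels of 12–14 populations with
  $K = 4$ (ancestry-group surrogates) and 12 populations with $K = 8$
  (recovery studies), DE at its defaults (NP 30, 100 generations,
  $M = 10$), sized so the full pipeline completes in about a second
  per query on one core.

## Known limitations

* At small $K$ the population-level decomposition is fundamentally
  non-unique for mixtures with all components positive; the stable set
  honestly reflects that ambiguity (few populations reach 75%
  membership) and `ancestry_composition()` is the stable summary.
* The prior-discard rule compares only minimax errors; a prior that is
  merely redundant (zero weight) is kept, not flagged.
* Greedy construction with $\beta < 1$ can take detours through
  admixed near-twins of the true sources; later phases repair this,
  but the phase-1 solution alone is not a reliable decomposition.
* The DE search is exhaustive in effect only on small panels; on
  panels of thousands of populations the defaults explore a vanishing
  fraction of subsets and `G_max`/`NP` should be raised.
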