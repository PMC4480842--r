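#' Great-circle distance between two points, in kilometers
#'
#' Haversine distance with Earth radius 6371 km.
#'
#' @param a,b numeric vectors `c(lat, lon)` in decimal degrees.
#' @return distance in kilometers.
#' @export
haversine_km <- function(a, b) {
  geosphere::distHaversine(c(a[2], a[1]), c(b[2], b[1]), r = 6371000) / 1000
}

#' Score one prediction against the simulated truth
#'
#' For every true source the distance to the nearest predicted stable
#' population is computed (0 km when the population itself is
#' predicted).  A prediction has the correct position when the mean of
#' these distances is at most `threshold_km` (default 320 km), the
#' correct populations when the predicted stable name set equals the
#' true source set exactly, and at least one correct origin when any
#' predicted name matches a true source.  An empty stable set scores 0
#' on all flags, with the distance set to the largest true-source /
#' panel distance observed.
#'
#' @param report a `readmix_report`.
#' @param truth a [mixture_scenario()].
#' @param panel the [readmix_panel()] both refer to.
#' @param threshold_km correct-position radius (default 320).
#' @return one-row data frame: `correct_position`,
#'   `at_least_one_correct_origin`, `correct_populations` (logicals) and
#'   `avg_distance_km`.
#' @export
evaluate_prediction <- function(report, truth, panel, threshold_km = 320) {
  true_idx <- panel_index(panel, truth$sources)
  pred <- report$stable$population
  if (length(pred) == 0L) {
    worst <- max(vapply(true_idx, function(i) {
      max(vapply(seq_len(panel$N), function(j) {
        haversine_km(c(panel$lat[i], panel$lon[i]),
                     c(panel$lat[j], panel$lon[j]))
      }, numeric(1)))
    }, numeric(1)))
    return(data.frame(correct_position = FALSE,
                      at_least_one_correct_origin = FALSE,
                      correct_populations = FALSE,
                      avg_distance_km = worst))
  }
  pred_idx <- panel_index(panel, pred)
  d <- vapply(true_idx, function(i) {
    min(vapply(pred_idx, function(j) {
      haversine_km(c(panel$lat[i], panel$lon[i]),
                   c(panel$lat[j], panel$lon[j]))
    }, numeric(1)))
  }, numeric(1))
  data.frame(correct_position = mean(d) <= threshold_km,
             at_least_one_correct_origin =
               length(intersect(pred, truth$sources)) > 0L,
             correct_populations = setequal(pred, truth$sources),
             avg_distance_km = mean(d))
}

#' Aggregate per-case scores into accuracy percentages
#'
#' @param cases data frame of rows from [evaluate_prediction()].
#' @return list: `correct_position_pct`,
#'   `at_least_one_correct_origin_pct`, `correct_populations_pct` (in
#'   \[0, 100\]) and `avg_distance_to_correct_population_km` (mean over
#'   cases).
#' @export
summarize_metrics <- function(cases) {
  stopifnot(nrow(cases) >= 1)
  list(correct_position_pct = 100 * mean(cases$correct_position),
       at_least_one_correct_origin_pct =
         100 * mean(cases$at_least_one_correct_origin),
       correct_populations_pct = 100 * mean(cases$correct_populations),
       avg_distance_to_correct_population_km = mean(cases$avg_distance_km))
}

#' Ancestry composition recovered by a decomposition
#'
#' Maps the ensemble of candidate solutions into ancestry space.  With
#' `by = "component"`, returns the mean (over solutions) of each
#' solution's fitted approximation `P = sum(a_i r_i)` — the recovered
#' admixture composition in the K ancestral components, the quantity
#' that stays well defined even when several population subsets
#' reproduce the query equally well (which is common at small K).  With
#' `by = "group"`, sums each solution's weights over the panel's
#' ancestry-group labels and averages across solutions.
#'
#' @param report a `readmix_report` with its `solutions`.
#' @param panel the [readmix_panel()] used for the decomposition.
#' @param by `"component"` or `"group"` (the latter requires panel
#'   group labels).
#' @return named numeric vector summing to 1.
#' @export
ancestry_composition <- function(report, panel,
                                 by = c("component", "group")) {
  by <- match.arg(by)
  sols <- report$solutions
  if (is.null(sols) || length(sols) == 0L) {
    stop("report carries no solutions (was it read back from disk?)")
  }
  if (by == "component") {
    P <- vapply(sols, function(s) {
      as.numeric(crossprod(panel$Q[s$indices, , drop = FALSE], s$weights))
    }, numeric(panel$K))
    out <- rowMeans(P)
    names(out) <- sprintf("c%d", seq_len(panel$K))
  } else {
    if (is.null(panel$group)) stop("panel has no ancestry-group labels")
    grp <- sort(unique(panel$group))
    W <- vapply(sols, function(s) {
      vapply(grp, function(g) {
        sum(s$weights[panel$group[s$indices] == g])
      }, numeric(1))
    }, numeric(length(grp)))
    out <- rowMeans(matrix(W, nrow = length(grp)))
    names(out) <- grp
  }
  out / sum(out)
}
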