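# Coverage, capacity, scenario-projection and sensitivity reporting.

#' Coverage of demand within a service radius
#'
#' For every node and intervention: the percentage of demand served by open
#' centers at most `radius_km` away (inclusive threshold). The denominator
#' is the node's demand, not the patients served, so unmet demand lowers
#' coverage. Per-intervention averages are unweighted means over nodes and
#' the overall figure is the mean of the per-intervention averages.
#'
#' @param instance a [problem_instance()].
#' @param solution a feasible [solution_allocation()].
#' @param radius_km service radius (default 40 km).
#' @return object of class `coverage_report`: list with `per_node`
#'   (data.frame `node_id` plus one percentage column per intervention),
#'   `averages` (named per-intervention), and `overall`.
#' @export
coverage_report <- function(instance, solution, radius_km = 40) {
  inst <- instance
  mask <- inst$dm$d[inst$nodes, inst$sites, drop = FALSE] <= radius_km
  n_i <- length(inst$nodes); n_k <- length(inst$interventions)
  pct <- matrix(0, n_i, n_k,
                dimnames = list(inst$nodes, inst$interventions))
  for (k in seq_len(n_k)) {
    Yk <- matrix(solution$Y[, , k], n_i)
    served_near <- rowSums(Yk * mask)
    pct[, k] <- ifelse(inst$D[, k] > 0, 100 * served_near / inst$D[, k], 0)
  }
  averages <- colMeans(pct)
  structure(
    list(
      per_node = data.frame(node_id = inst$nodes, pct,
                            stringsAsFactors = FALSE, check.names = FALSE),
      averages = averages,
      overall = mean(averages),
      radius_km = radius_km
    ),
    class = "coverage_report"
  )
}

#' @export
print.coverage_report <- function(x, ...) {
  cat("<coverage_report> radius ", x$radius_km, " km\n", sep = "")
  cat("  per-intervention averages:",
      paste(sprintf("%s %.2f%%", names(x$averages), x$averages),
            collapse = ", "), "\n")
  cat("  overall:", sprintf("%.2f%%", x$overall), "\n")
  invisible(x)
}

#' Capacity and utilisation of the opened centers
#'
#' @param instance a [problem_instance()].
#' @param solution a feasible [solution_allocation()].
#' @return data.frame with one row per open site and intervention:
#'   `site`, `intervention`, `capacity_hours`, `patients`,
#'   `professional_hours` (hours actually used, `L^k` per patient), and
#'   `utilization` in `[0, 1]`. Closed sites are omitted.
#' @export
capacity_report <- function(instance, solution) {
  inst <- instance
  open <- which(solution$X > 0.5)
  n_i <- length(inst$nodes)
  rows <- list()
  for (j in open) for (k in seq_along(inst$interventions)) {
    patients <- sum(matrix(solution$Y[, , k], n_i)[, j])
    used <- inst$hours_per_patient[k] * patients
    cap <- solution$C[j, k]
    rows[[length(rows) + 1L]] <- data.frame(
      site = inst$sites[j], intervention = inst$interventions[k],
      capacity_hours = cap, patients = patients,
      professional_hours = used,
      utilization = if (cap > 0) used / cap else 0,
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0L) {
    return(data.frame(site = character(0), intervention = character(0),
                      capacity_hours = numeric(0), patients = numeric(0),
                      professional_hours = numeric(0),
                      utilization = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Back-of-envelope coverage projection for expansion scenarios
#'
#' Starting from an overall average coverage achieved by two centers, each
#' additional center is assumed to replicate the average per-center share
#' (half the overall figure, rounded to 2 decimals), and scaling existing
#' capacity scales coverage proportionally. The headline figure is rounded
#' to the nearest integer percent; the unrounded value is also returned.
#'
#' @param overall_coverage_pct baseline overall coverage (percent).
#' @param n_extra_centers number of additional centers (>= 0).
#' @param capacity_multiplier multiplier on existing capacity (>= 0;
#'   1 = unchanged).
#' @return list with `projected_pct` (unrounded) and `headline_pct`
#'   (nearest integer percent).
#' @export
scenario_projection <- function(overall_coverage_pct, n_extra_centers = 0,
                                capacity_multiplier = 1) {
  stopifnot(overall_coverage_pct >= 0, n_extra_centers >= 0,
            capacity_multiplier >= 0)
  per_center <- round(overall_coverage_pct / 2, 2)
  projected <- overall_coverage_pct + n_extra_centers * per_center +
    (capacity_multiplier - 1) * overall_coverage_pct
  list(projected_pct = projected, headline_pct = round(projected))
}

#' Sensitivity of the model to the objective weights
#'
#' Re-solves the model over a grid of values for the risk weight `delta`
#' and/or the equity weight `pi`, for three model variants: the OF1-only
#' optimum, the OF2-only optimum, and the bi-objective knee solution of an
#' epsilon sweep. Each row records the weight, the objective values, the
#' open sites, and the overall coverage within the radius.
#'
#' @param instance a [problem_instance()].
#' @param values weight grid (default `seq(0.1, 0.9, by = 0.1)`).
#' @param which one of `"delta"`, `"pi"`, `"both"`: which weight(s) the grid
#'   varies; `"both"` moves them in lock-step.
#' @param variants subset of `c("of1", "of2", "knee")`.
#' @param n_points epsilon grid size for the knee variant.
#' @param radius_km coverage radius.
#' @param gap relative MIP gap.
#' @return data.frame with one row per (weight value, variant); infeasible
#'   rows are flagged in `status` and carry `NA` metrics.
#' @export
weight_sweep <- function(instance, values = seq(0.1, 0.9, by = 0.1),
                         which = c("both", "delta", "pi"),
                         variants = c("of1", "of2", "knee"),
                         n_points = 10, radius_km = 40, gap = 1e-4) {
  which <- match.arg(which)
  variants <- match.arg(variants, several.ok = TRUE)
  rows <- list()
  for (w in values) {
    inst_w <- instance
    if (which %in% c("delta", "both")) inst_w$delta <- w
    if (which %in% c("pi", "both")) inst_w$pi_weight <- w
    for (v in variants) {
      sol <- tryCatch({
        if (v == "knee") {
          fr <- epsilon_sweep(inst_w, n_points = n_points, gap = gap)
          fr$solutions[[fr$knee]]
        } else {
          build_and_solve(inst_w, objective = v, gap = gap)
        }
      }, error = function(e) {
        structure(list(status = "infeasible", message = conditionMessage(e)),
                  class = "equiloc_infeasible")
      })
      if (is_infeasible(sol)) {
        rows[[length(rows) + 1L]] <- data.frame(
          weight = w, variant = v, status = "infeasible",
          of1 = NA_real_, of2 = NA_real_, coverage_pct = NA_real_,
          n_open = NA_real_, open_sites = NA_character_,
          stringsAsFactors = FALSE
        )
      } else {
        cov <- coverage_report(inst_w, sol, radius_km = radius_km)
        rows[[length(rows) + 1L]] <- data.frame(
          weight = w, variant = v, status = sol$status,
          of1 = sol$of1, of2 = sol$of2, coverage_pct = cov$overall,
          n_open = sum(sol$X > 0.5),
          open_sites = paste(names(sol$X)[sol$X > 0.5], collapse = ";"),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}

#' Maximum relative variation of OF1 along a frontier
#'
#' The largest percentage change in objective 1 between consecutive frontier
#' points (sorted by epsilon), with the earlier point as denominator.
#' Pairs whose denominator is zero are skipped. A diagnostic of how sensitive
#' the epsilon-constraint method is to the grid resolution.
#'
#' @param frontier a [epsilon_sweep()] result, or a data.frame with columns
#'   `epsilon` and `of1`.
#' @return maximum relative variation, in percent.
#' @export
epsilon_variation <- function(frontier) {
  pts <- if (inherits(frontier, "pareto_frontier")) frontier$points
         else as.data.frame(frontier)
  if (nrow(pts) < 2L) {
    stop("epsilon_variation needs at least two frontier points", call. = FALSE)
  }
  pts <- pts[order(pts$epsilon), ]
  prev <- pts$of1[-nrow(pts)]
  nxt <- pts$of1[-1]
  ok <- prev != 0
  if (!any(ok)) return(0)
  max(100 * abs(nxt[ok] - prev[ok]) / abs(prev[ok]))
}

#' Annual service hours of one full-time professional
#'
#' @param hours_per_day working hours per day.
#' @param days_per_year working days per year.
#' @return total annual hours.
#' @export
annual_hours <- function(hours_per_day = 8, days_per_year = 260) {
  stopifnot(hours_per_day > 0, days_per_year > 0)
  hours_per_day * days_per_year
}

#' Hourly operating cost from a monthly salary
#'
#' @param monthly_salary professional's monthly salary (currency units).
#' @param hours_per_day working hours per day (default 8).
#' @param days_per_month working days per month (default 20).
#' @return cost per service hour.
#' @export
hourly_cost <- function(monthly_salary, hours_per_day = 8,
                        days_per_month = 20) {
  stopifnot(monthly_salary > 0, hours_per_day > 0, days_per_month > 0)
  monthly_salary / (hours_per_day * days_per_month)
}
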