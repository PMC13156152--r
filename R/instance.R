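#' Fully parameterised location-allocation problem instance
#'
#' Bundles the sets (demand nodes `I`, candidate sites `J`, intervention
#' types `K`), the per-node risk and equity index tables, the demand table,
#' the distance matrix, and every scalar of the capacitated bi-objective
#' integer program.
#'
#' @param nodes character vector of demand-node ids (set `I`).
#' @param sites character vector of candidate-site ids (set `J`); must be
#'   contained in the distance matrix node set. Defaults to `nodes`.
#' @param R `|I| x |K|` matrix of risk indices (columns are interventions).
#' @param sigma `|I| x |K|` matrix of equity indices.
#' @param D `|I| x |K|` matrix of integer patient demand.
#' @param dm a [distance_matrix()] covering all of `nodes` and `sites`.
#' @param budget length-`|K|` vector: funds available per intervention.
#' @param hourly_cost length-`|K|` vector `F`: operating cost per capacity
#'   hour, per intervention.
#' @param hours_per_patient length-`|K|` vector `L`: service hours one
#'   patient requires (e.g. 0.05 h for 20-person group prevention sessions,
#'   1 h for individual mitigation sessions).
#' @param r_min minimum annual working hours to open a center (hours).
#' @param phi minimum number of patients that must be served at every demand
#'   node, summed over interventions and centers.
#' @param delta weight in `[0, 1]` on risk (vs. normalised distance) in
#'   objective 1.
#' @param pi_weight weight in `[0, 1]` on equity (vs. normalised distance)
#'   in objective 2.
#' @param big_m linking constant forcing zero flow to closed sites; defaults
#'   to the total demand (see [default_big_m()]).
#' @param phi_k optional length-`|K|` vector of per-intervention minimum
#'   patients per node; when supplied it replaces the combined `phi` floor.
#' @return object of class `problem_instance`.
#' @export
problem_instance <- function(nodes, sites = nodes, R, sigma, D, dm,
                             budget, hourly_cost, hours_per_patient,
                             r_min = 2080, phi = 0,
                             delta = 0.7, pi_weight = 0.7,
                             big_m = NULL, phi_k = NULL) {
  nodes <- as.character(nodes)
  sites <- as.character(sites)
  stopifnot(inherits(dm, "distance_matrix"))
  if (!all(nodes %in% dm$node_ids) || !all(sites %in% dm$node_ids)) {
    stop("distance matrix does not cover all nodes/sites", call. = FALSE)
  }
  R <- as.matrix(R); sigma <- as.matrix(sigma); D <- as.matrix(D)
  n_i <- length(nodes); n_k <- ncol(D)
  for (nm in c("R", "sigma", "D")) {
    m <- get(nm)
    if (nrow(m) != n_i || ncol(m) != n_k) {
      stop(nm, " must be an |I| x |K| matrix", call. = FALSE)
    }
    if (any(!is.finite(m)) || any(m < 0)) {
      stop(nm, " must be nonnegative and finite", call. = FALSE)
    }
  }
  if (any(D != round(D))) stop("demand must be integer", call. = FALSE)
  if (length(budget) != n_k || length(hourly_cost) != n_k ||
      length(hours_per_patient) != n_k) {
    stop("budget, hourly_cost, hours_per_patient must have one entry per intervention",
         call. = FALSE)
  }
  if (any(budget < 0)) stop("budget must be nonnegative", call. = FALSE)
  if (any(hourly_cost <= 0)) stop("hourly_cost must be positive", call. = FALSE)
  if (any(hours_per_patient <= 0)) {
    stop("hours_per_patient must be positive", call. = FALSE)
  }
  if (delta < 0 || delta > 1 || pi_weight < 0 || pi_weight > 1) {
    stop("delta and pi_weight must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(phi_k) && length(phi_k) != n_k) {
    stop("phi_k must have one entry per intervention", call. = FALSE)
  }
  k_names <- if (n_k == length(INTERVENTIONS)) INTERVENTIONS else paste0("k", seq_len(n_k))
  dimnames(R) <- dimnames(sigma) <- dimnames(D) <- list(nodes, k_names)
  inst <- structure(
    list(
      nodes = nodes, sites = sites, interventions = k_names,
      R = R, sigma = sigma, D = D, dm = dm,
      d = dm$d[nodes, sites, drop = FALSE], d_max = dm$d_max,
      budget = setNames(as.numeric(budget), k_names),
      hourly_cost = setNames(as.numeric(hourly_cost), k_names),
      hours_per_patient = setNames(as.numeric(hours_per_patient), k_names),
      r_min = r_min, phi = phi, phi_k = phi_k,
      delta = delta, pi_weight = pi_weight,
      big_m = NA_real_
    ),
    class = "problem_instance"
  )
  inst$big_m <- if (is.null(big_m)) default_big_m(inst) else big_m
  inst
}

#' Default big-M linking constant
#'
#' The sum of the total demand over all nodes and interventions: no arc can
#' ever carry more flow than the whole system demands, so this is the
#' tightest generic choice and avoids the numerical trouble of an oversized
#' constant.
#'
#' @param instance a [problem_instance()].
#' @return total demand (patients).
#' @export
default_big_m <- function(instance) {
  sum(instance$D)
}

#' Decision-variable counts of the integer program
#'
#' The model has one integer flow variable per (demand node, site,
#' intervention) triple, one integer capacity variable per (site,
#' intervention) pair, and one binary open indicator per site. Binary
#' variables are counted inside the total.
#'
#' @param n_demand,n_sites,n_interventions positive set sizes.
#' @return named integer vector `c(total = ..., binary = ...)`.
#' @export
count_variables <- function(n_demand, n_sites, n_interventions) {
  stopifnot(n_demand >= 1, n_sites >= 1, n_interventions >= 1)
  total <- n_demand * n_sites * n_interventions +
    n_sites * n_interventions + n_sites
  c(total = as.integer(total), binary = as.integer(n_sites))
}

#' @export
print.problem_instance <- function(x, ...) {
  cat("<problem_instance> ", length(x$nodes), " demand nodes, ",
      length(x$sites), " candidate sites, ", length(x$interventions),
      " interventions\n", sep = "")
  cat("  total demand:", sum(x$D), "patients; phi =", x$phi,
      "; delta =", x$delta, "; pi =", x$pi_weight, "\n")
  cat("  budgets:", paste(format(x$budget, big.mark = ","), collapse = " / "),
      "\n")
  invisible(x)
}
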