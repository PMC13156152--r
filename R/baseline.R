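# Population-ranked siting heuristic: the comparison point for the exact
# bi-objective model. Centers are placed in the most populated cities until
# the budgets run out; every node still receives its policy minimum.

#' Population-ranked baseline heuristic
#'
#' Opens centers greedily in descending population order (ties break to the
#' earlier `node_id` in instance order). Budget hours are first reserved to
#' serve the `phi` minimum-service floor at every demand node (assigned to
#' interventions in order of increasing hours-per-patient, routed to the
#' nearest open center); each opened city then absorbs the maximum
#' budget-fundable capacity for its own remaining demand. A candidate city is
#' opened only while the budgets can still fund the minimum operating hours
#' `R_min`; capacity at an opened site is topped up to `R_min` where its own
#' demand does not reach it. The result satisfies every model constraint and
#' is evaluated on both objectives as the "base point".
#'
#' @param instance a [problem_instance()].
#' @param profiles the matching [municipality_profiles()] table (for
#'   population ranks); row order must match `instance$nodes`.
#' @return a [solution_allocation()], or an infeasibility report when the
#'   minimum service floor cannot be funded.
#' @export
population_heuristic <- function(instance, profiles) {
  inst <- instance
  if (!identical(as.character(profiles$node_id), inst$nodes)) {
    stop("profiles must match instance nodes (same ids, same order)",
         call. = FALSE)
  }
  if (!all(inst$sites %in% inst$nodes)) {
    stop("population_heuristic requires candidate sites to be demand nodes",
         call. = FALSE)
  }
  n_i <- length(inst$nodes); n_j <- length(inst$sites)
  n_k <- length(inst$interventions)
  Lk <- inst$hours_per_patient
  fundable <- floor(inst$budget / inst$hourly_cost)

  # phi minimum per node and intervention, and the hours it reserves
  f <- .phi_assignment(inst)
  reserve <- ceiling(colSums(f) * Lk)
  if (any(reserve > fundable)) {
    k <- which(reserve > fundable)[1]
    return(structure(
      list(status = "infeasible", solver_status = "heuristic",
           message = sprintf(
             "minimum service needs %g %s hours but the budget funds only %g",
             reserve[k], inst$interventions[k], fundable[k])),
      class = "equiloc_infeasible"
    ))
  }
  avail <- fundable - reserve

  # open sites by population, largest first; node_id order breaks ties
  pop <- profiles$population[match(inst$sites, inst$nodes)]
  site_order <- order(-pop, seq_len(n_j))
  phi_any <- sum(f) > 0
  X <- integer(n_j)
  own <- matrix(0, n_j, n_k)  # own-demand patients served at each open site
  for (j in site_order) {
    i <- match(inst$sites[j], inst$nodes)
    grant <- pmin(inst$D[i, ] - f[i, ], floor(avail / Lk))
    grant_hours <- ceiling(grant * Lk)
    shortfall <- max(0, inst$r_min - sum(grant_hours) -
                       if (sum(X) == 0 && phi_any) sum(reserve) else 0)
    # top-up hours to reach R_min, drawn where budget room remains
    room <- avail - grant_hours
    topup <- pmin(room, shortfall)
    if (n_k >= 2) {
      topup[1] <- min(room[1], shortfall)
      for (k in seq_len(n_k)[-1]) {
        topup[k] <- min(room[k], shortfall - sum(topup[seq_len(k - 1)]))
      }
    }
    if (sum(grant_hours) + sum(topup) +
        (if (sum(X) == 0 && phi_any) sum(reserve) else 0) < inst$r_min) {
      break  # budgets exhausted: cannot open this or any later site
    }
    X[j] <- 1L
    own[j, ] <- grant
    avail <- avail - grant_hours - topup
  }
  if (sum(X) == 0 && phi_any) {
    return(structure(
      list(status = "infeasible", solver_status = "heuristic",
           message = "budgets cannot fund the minimum operating hours of any center"),
      class = "equiloc_infeasible"
    ))
  }

  # flows: phi minimum routed to the nearest open site, then own demand;
  # capacities follow the flows and are topped up to R_min. Integer hour
  # round-ups can overrun a budget by a few hours, so a reconciliation loop
  # sheds own-demand patients (or closes an unsustainable site) until every
  # constraint verifies.
  build_flows <- function(X, own) {
    Y <- array(0, c(n_i, n_j, n_k))
    open <- which(X == 1)
    if (length(open) > 0L) {
      for (i in seq_len(n_i)) {
        jj <- open[which.min(inst$d[i, open])]
        Y[i, jj, ] <- Y[i, jj, ] + f[i, ]
      }
      for (j in open) {
        i <- match(inst$sites[j], inst$nodes)
        Y[i, j, ] <- Y[i, j, ] + own[j, ]
      }
    }
    Y
  }
  capacities <- function(Y, X) {
    C <- matrix(0, n_j, n_k)
    for (k in seq_len(n_k)) {
      C[, k] <- ceiling(Lk[k] * colSums(matrix(Y[, , k], n_i, n_j)))
    }
    room <- fundable - colSums(C)
    for (j in which(X == 1)) {
      need <- inst$r_min - sum(C[j, ])
      for (k in seq_len(n_k)) {
        if (need <= 0) break
        take <- max(0, min(need, room[k]))
        C[j, k] <- C[j, k] + take
        room[k] <- room[k] - take
        need <- need - take
      }
    }
    C
  }
  shed_order <- rev(site_order[site_order %in% which(X == 1)])
  repeat {
    Y <- build_flows(X, own)
    C <- capacities(Y, X)
    viol <- verify_solution(inst, list(Y = Y, C = C, X = X))
    viol <- viol[viol$constraint %in% c("budget", "min_hours"), , drop = FALSE]
    if (nrow(viol) == 0L) break
    if (any(viol$constraint == "budget")) {
      shed <- FALSE
      for (j in shed_order) {
        kk <- which(own[j, ] > 0)
        if (length(kk) > 0L) {
          k <- kk[length(kk)]
          own[j, k] <- own[j, k] - max(1, ceiling(1 / Lk[k]))
          own[j, k] <- max(0, own[j, k])
          shed <- TRUE
          break
        }
      }
      if (shed) next
    }
    # min-hours shortfall (or nothing left to shed): close the last site
    drop <- shed_order[1]
    if (length(shed_order) <= 1L && phi_any) {
      return(structure(
        list(status = "infeasible", solver_status = "heuristic",
             message = "could not reconcile heuristic capacities with the budgets"),
        class = "equiloc_infeasible"
      ))
    }
    X[drop] <- 0L
    own[drop, ] <- 0
    shed_order <- shed_order[-1]
  }
  if (sum(X) == 0 && phi_any) {
    return(structure(
      list(status = "infeasible", solver_status = "heuristic",
           message = "budgets cannot fund the minimum operating hours of any center"),
      class = "equiloc_infeasible"
    ))
  }
  solution_allocation(inst, Y, C, X, status = "optimal", gap = NA_real_)
}
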