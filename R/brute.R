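# Exhaustive enumeration oracle for tiny instances. Independent of the MILP
# backend: enumerates every open-site pattern and every integer flow
# assignment, and checks capacity/budget feasibility in closed form. Used to
# certify the exact solver on randomized tiny instances.

.compositions_upto <- function(total_max, m) {
  # all nonnegative integer vectors of length m with sum <= total_max
  g <- do.call(expand.grid, rep(list(0:total_max), m))
  g <- as.matrix(g[rowSums(g) <= total_max, , drop = FALSE])
  dimnames(g) <- NULL
  g
}

#' Exact optimum of a tiny instance by exhaustive enumeration
#'
#' Enumerates all site-opening patterns and all integer flow assignments
#' within the demand bounds, checking the capacity, budget, minimum-hours and
#' minimum-service constraints for each. Intended purely as a testing oracle;
#' a guard refuses instances beyond `|J| <= 3`, `|K| <= 2`, total demand
#' `<= 12`.
#'
#' @param instance a [problem_instance()] within the guard.
#' @param objective `"of1"` or `"of2"`.
#' @param of2_floor optional epsilon floor on objective 2.
#' @return a [solution_allocation()] at the exact optimum, or an
#'   infeasibility report ([is_infeasible()]).
#' @export
brute_force_solve <- function(instance, objective = c("of1", "of2"),
                              of2_floor = NULL) {
  objective <- match.arg(objective)
  inst <- instance
  n_i <- length(inst$nodes); n_j <- length(inst$sites)
  n_k <- length(inst$interventions)
  if (n_j > 3 || n_k > 2 || sum(inst$D) > 12) {
    stop("brute_force_solve guard: requires |J| <= 3, |K| <= 2, total demand <= 12",
         call. = FALSE)
  }
  Lk <- inst$hours_per_patient
  fundable <- floor(inst$budget / inst$hourly_cost)
  dn <- if (inst$d_max > 0) inst$d / inst$d_max else inst$d * 0
  co1 <- lapply(seq_len(n_k), function(k) {
    inst$delta * matrix(inst$R[, k], n_i, n_j) - (1 - inst$delta) * dn
  })
  co2 <- lapply(seq_len(n_k), function(k) {
    inst$pi_weight * matrix(inst$sigma[, k], n_i, n_j) -
      (1 - inst$pi_weight) * dn
  })

  best <- NULL
  best_obj <- -Inf

  for (pattern in 0:(2^n_j - 1)) {
    X <- as.integer(intToBits(pattern))[seq_len(n_j)]
    open <- which(X == 1)
    # candidate flow vectors per (i, k) cell over the open sites
    cells <- list()
    for (k in seq_len(n_k)) for (i in seq_len(n_i)) {
      if (length(open) == 0L || inst$D[i, k] == 0) {
        mat <- matrix(0, 1, n_j)
      } else {
        comp <- .compositions_upto(inst$D[i, k], length(open))
        mat <- matrix(0, nrow(comp), n_j)
        mat[, open] <- comp
      }
      cells[[length(cells) + 1L]] <- list(
        i = i, k = k, mat = mat,
        t = rowSums(mat),
        o1 = as.vector(mat %*% co1[[k]][i, ]),
        o2 = as.vector(mat %*% co2[[k]][i, ])
      )
    }
    n_comb <- prod(vapply(cells, function(cl) nrow(cl$mat), numeric(1)))
    if (n_comb > 3e6) {
      stop("brute_force_solve: enumeration too large (", n_comb, " combinations)",
           call. = FALSE)
    }
    idx <- as.matrix(do.call(expand.grid, lapply(cells, function(cl) {
      seq_len(nrow(cl$mat))
    })))
    pick <- function(field) {
      m <- vapply(seq_along(cells), function(cc) {
        cells[[cc]][[field]][idx[, cc]]
      }, numeric(nrow(idx)))
      matrix(m, nrow = nrow(idx))
    }
    obj1 <- rowSums(pick("o1"))
    obj2 <- rowSums(pick("o2"))
    tmat <- pick("t")

    feas <- rep(TRUE, nrow(idx))
    # minimum service
    if (!is.null(inst$phi_k)) {
      for (cc in seq_along(cells)) {
        feas <- feas & (tmat[, cc] >= inst$phi_k[cells[[cc]]$k])
      }
    } else if (inst$phi > 0) {
      for (i in seq_len(n_i)) {
        ci <- which(vapply(cells, function(cl) cl$i == i, logical(1)))
        feas <- feas & (rowSums(tmat[, ci, drop = FALSE]) >= inst$phi)
      }
    }
    # capacity hours: base = ceil(L_k * patients at (j, k)); top-ups to meet
    # R_min at open sites must fit the per-intervention budgets
    base_sum_k <- matrix(0, nrow(idx), n_k)        # total base hours per k
    site_base <- array(0, c(nrow(idx), n_j, n_k))  # base hours per (j, k)
    for (k in seq_len(n_k)) {
      kcells <- which(vapply(cells, function(cl) cl$k == k, logical(1)))
      for (j in open) {
        S <- rowSums(matrix(vapply(kcells, function(cc) {
          cells[[cc]]$mat[idx[, cc], j]
        }, numeric(nrow(idx))), nrow = nrow(idx)))
        site_base[, j, k] <- ceiling(Lk[k] * S)
      }
      base_sum_k[, k] <- rowSums(site_base[, , k, drop = FALSE][, , 1, drop = FALSE])
    }
    extra <- matrix(0, nrow(idx), n_j)
    for (j in open) {
      have <- rowSums(matrix(site_base[, j, ], nrow(idx), n_k))
      extra[, j] <- pmax(0, inst$r_min - have)
    }
    e_tot <- rowSums(extra)
    slack <- matrix(rep(fundable, each = nrow(idx)), nrow(idx), n_k) - base_sum_k
    feas <- feas & apply(slack >= 0, 1, all)
    if (n_k == 2) {
      lo <- pmax(0, e_tot - slack[, 2])
      hi <- pmin(e_tot, slack[, 1])
      feas <- feas & (lo <= hi)
    } else {
      feas <- feas & (e_tot <= slack[, 1])
    }
    if (!is.null(of2_floor)) feas <- feas & (obj2 >= of2_floor - 1e-9)

    objective_vals <- if (objective == "of1") obj1 else obj2
    objective_vals[!feas] <- -Inf
    if (any(feas)) {
      w <- which.max(objective_vals)
      if (objective_vals[w] > best_obj + 1e-12) {
        best_obj <- objective_vals[w]
        Y <- array(0, c(n_i, n_j, n_k))
        for (cc in seq_along(cells)) {
          cl <- cells[[cc]]
          Y[cl$i, , cl$k] <- cl$mat[idx[w, cc], ]
        }
        # distribute top-up hours: as much on k = 1 as the budget allows
        C <- matrix(site_base[w, , ], n_j, n_k)
        ex <- extra[w, ]
        if (n_k == 2) {
          e1 <- min(e_tot[w], slack[w, 1])
          e1 <- max(e1, max(0, e_tot[w] - slack[w, 2]))
          for (j in open) {
            take <- min(ex[j], e1)
            C[j, 1] <- C[j, 1] + take
            C[j, 2] <- C[j, 2] + ex[j] - take
            e1 <- e1 - take
          }
        } else {
          C[, 1] <- C[, 1] + ex
        }
        best <- list(Y = Y, C = C, X = X)
      }
    }
  }
  if (is.null(best)) {
    return(structure(
      list(status = "infeasible", solver_status = "enumeration",
           message = .diagnose_infeasibility(inst)),
      class = "equiloc_infeasible"
    ))
  }
  solution_allocation(inst, best$Y, best$C, best$X,
                      status = "optimal", gap = 0)
}
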