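# Integer-program construction and solution handling for the capacitated
# bi-objective location-allocation model.
#
# Decision variables (all integer):
#   Y[i,j,k]  patients flowing from demand node i to center j, intervention k
#   C[j,k]    annual capacity hours of center j for intervention k
#   X[j]      binary: 1 if a center is opened at site j
#
# Constraints:
#   demand       sum_j Y[i,j,k]            <= D[i,k]            (i,k)
#   budget       F[k] * sum_j C[j,k]       <= Budget[k]         (k)
#   min_hours    sum_k C[j,k]              >= R_min * X[j]      (j)
#   capacity     L[k] * sum_i Y[i,j,k]     <= C[j,k]            (j,k)
#   open_link    sum_{i,k} Y[i,j,k]        <= M * X[j]          (j)
#   min_service  sum_{j,k} Y[i,j,k]        >= phi               (i)
#   cap_link     C[j,k] <= floor(Budget[k]/F[k]) * X[j]         (j,k)
#
# cap_link is not part of the printed formulation: min_hours only
# lower-bounds open sites, so without it a closed site could carry phantom
# capacity that consumes budget. It tightens the model without cutting any
# integer solution in which capacity at closed sites is zero.

.var_layout <- function(inst) {
  n_i <- length(inst$nodes)
  n_j <- length(inst$sites)
  n_k <- length(inst$interventions)
  nY <- n_i * n_j * n_k
  nC <- n_j * n_k
  list(
    n_i = n_i, n_j = n_j, n_k = n_k, nY = nY, nC = nC,
    n_var = nY + nC + n_j,
    idx_Y = function(i, j, k) (k - 1L) * n_i * n_j + (j - 1L) * n_i + i,
    idx_C = function(j, k) nY + (k - 1L) * n_j + j,
    idx_X = function(j) nY + nC + j
  )
}

# Objective coefficient vector over the full variable layout.
.objective_coef <- function(inst, which = c("of1", "of2")) {
  which <- match.arg(which)
  lay <- .var_layout(inst)
  w <- if (which == "of1") inst$delta else inst$pi_weight
  idx <- if (which == "of1") inst$R else inst$sigma
  dn <- if (inst$d_max > 0) inst$d / inst$d_max else inst$d * 0
  cY <- unlist(lapply(seq_len(lay$n_k), function(k) {
    as.vector(w * matrix(idx[, k], lay$n_i, lay$n_j) - (1 - w) * dn)
  }), use.names = FALSE)
  c(cY, rep(0, lay$nC + lay$n_j))
}

#' Build the integer program in sparse matrix form
#'
#' Assembles the objective vectors, constraint triplets, bounds and
#' integrality flags of the capacitated bi-objective integer program. All
#' decision variables are integer; the site-opening indicators are the binary
#' subset.
#'
#' @param instance a [problem_instance()].
#' @return list with elements `n_var`, `a_row`/`a_col`/`a_val` (triplets of
#'   the `<=` constraint matrix), `b_ub`, `row_labels`, `lb`, `ub`,
#'   `integrality`, `vartype` (`"Y"`, `"C"`, `"X"` per variable), `c_of1`,
#'   `c_of2`, and the internal `layout`.
#' @export
build_model <- function(instance) {
  inst <- instance
  lay <- .var_layout(inst)
  n_i <- lay$n_i; n_j <- lay$n_j; n_k <- lay$n_k
  Fk <- inst$hourly_cost; Lk <- inst$hours_per_patient
  cap_k <- floor(inst$budget / Fk)

  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  b <- numeric(0); labels <- character(0)
  r <- 0L
  add_row <- function(cidx, cval, rhs, label) {
    r <<- r + 1L
    rows <<- c(rows, rep(r, length(cidx)))
    cols <<- c(cols, cidx)
    vals <<- c(vals, cval)
    b <<- c(b, rhs)
    labels <<- c(labels, label)
  }

  for (k in seq_len(n_k)) for (i in seq_len(n_i)) {
    add_row(lay$idx_Y(i, seq_len(n_j), k), rep(1, n_j), inst$D[i, k],
            sprintf("demand[%s,%s]", inst$nodes[i], inst$interventions[k]))
  }
  # budget in hours: F^k sum_j C <= Budget^k with integer C is equivalent to
  # sum_j C <= floor(Budget^k / F^k); unit coefficients keep the matrix well
  # scaled when budgets are in currency units of 1e9
  for (k in seq_len(n_k)) {
    add_row(lay$idx_C(seq_len(n_j), k), rep(1, n_j), cap_k[k],
            sprintf("budget[%s]", inst$interventions[k]))
  }
  for (j in seq_len(n_j)) {
    add_row(c(lay$idx_C(j, seq_len(n_k)), lay$idx_X(j)),
            c(rep(-1, n_k), inst$r_min), 0,
            sprintf("min_hours[%s]", inst$sites[j]))
  }
  for (k in seq_len(n_k)) for (j in seq_len(n_j)) {
    add_row(c(lay$idx_Y(seq_len(n_i), j, k), lay$idx_C(j, k)),
            c(rep(Lk[k], n_i), -1), 0,
            sprintf("capacity[%s,%s]", inst$sites[j], inst$interventions[k]))
  }
  for (j in seq_len(n_j)) {
    yidx <- unlist(lapply(seq_len(n_k), function(k) lay$idx_Y(seq_len(n_i), j, k)))
    add_row(c(yidx, lay$idx_X(j)), c(rep(1, length(yidx)), -inst$big_m), 0,
            sprintf("open_link[%s]", inst$sites[j]))
  }
  if (!is.null(inst$phi_k)) {
    for (k in seq_len(n_k)) for (i in seq_len(n_i)) {
      add_row(lay$idx_Y(i, seq_len(n_j), k), rep(-1, n_j), -inst$phi_k[k],
              sprintf("min_service[%s,%s]", inst$nodes[i], inst$interventions[k]))
    }
  } else if (inst$phi > 0) {
    for (i in seq_len(n_i)) {
      yidx <- unlist(lapply(seq_len(n_k), function(k) lay$idx_Y(i, seq_len(n_j), k)))
      add_row(yidx, rep(-1, length(yidx)), -inst$phi,
              sprintf("min_service[%s]", inst$nodes[i]))
    }
  }
  for (k in seq_len(n_k)) for (j in seq_len(n_j)) {
    add_row(c(lay$idx_C(j, k), lay$idx_X(j)), c(1, -cap_k[k]), 0,
            sprintf("cap_link[%s,%s]", inst$sites[j], inst$interventions[k]))
  }

  ubY <- unlist(lapply(seq_len(n_k), function(k) {
    rep(inst$D[, k], times = n_j)
  }), use.names = FALSE)
  ubC <- rep(cap_k, each = n_j)
  list(
    n_var = lay$n_var,
    a_row = rows, a_col = cols, a_val = vals,
    b_ub = b, row_labels = labels,
    lb = rep(0, lay$n_var),
    ub = c(ubY, ubC, rep(1, n_j)),
    integrality = rep(1L, lay$n_var),
    vartype = c(rep("Y", lay$nY), rep("C", lay$nC), rep("X", n_j)),
    c_of1 = .objective_coef(inst, "of1"),
    c_of2 = .objective_coef(inst, "of2"),
    layout = lay
  )
}

.as_flow_array <- function(inst, Y) {
  lay <- .var_layout(inst)
  if (is.null(dim(Y))) {
    stopifnot(length(Y) == lay$nY)
    Y <- array(Y, dim = c(lay$n_i, lay$n_j, lay$n_k))
  }
  stopifnot(all(dim(Y) == c(lay$n_i, lay$n_j, lay$n_k)))
  dimnames(Y) <- list(inst$nodes, inst$sites, inst$interventions)
  Y
}

.weighted_flow_value <- function(inst, Y, index_table, weight) {
  Y <- .as_flow_array(inst, Y)
  if (any(Y < 0)) stop("flows must be nonnegative", call. = FALSE)
  dn <- if (inst$d_max > 0) inst$d / inst$d_max else {
    if (any(inst$d > 0)) stop("d_max is zero but distances are nonzero", call. = FALSE)
    inst$d * 0
  }
  n_i <- dim(Y)[1]
  val <- 0
  for (k in seq_len(dim(Y)[3])) {
    Yk <- matrix(Y[, , k], nrow = n_i)
    val <- val + weight * sum(index_table[, k] * rowSums(Yk)) -
      (1 - weight) * sum(dn * Yk)
  }
  val
}

#' Evaluate objective 1 (risk-weighted coverage) for a flow assignment
#'
#' `OF1 = delta * sum R[i,k] Y[i,j,k] - (1 - delta) * sum (d[i,j]/d_max) Y[i,j,k]`.
#' Computed directly from the instance tables, independently of any solver
#' output.
#'
#' @param instance a [problem_instance()].
#' @param Y flow array `|I| x |J| x |K|` (or flat vector in variable order).
#' @return scalar objective value.
#' @export
evaluate_of1 <- function(instance, Y) {
  .weighted_flow_value(instance, Y, instance$R, instance$delta)
}

#' Evaluate objective 2 (equity-weighted coverage) for a flow assignment
#'
#' As [evaluate_of1()] with the equity index in place of risk and the
#' `pi_weight` in place of `delta`.
#'
#' @inheritParams evaluate_of1
#' @return scalar objective value.
#' @export
evaluate_of2 <- function(instance, Y) {
  .weighted_flow_value(instance, Y, instance$sigma, instance$pi_weight)
}

#' Assemble a solution-allocation object
#'
#' Both objective values are recomputed from the flows via [evaluate_of1()]
#' and [evaluate_of2()]; solver-reported objectives are never trusted.
#'
#' @param instance a [problem_instance()].
#' @param Y flow array (patients), `C` capacity matrix `|J| x |K|` (hours),
#'   `X` binary open vector.
#' @param C,X see above.
#' @param status one of `"optimal"`, `"infeasible"`, `"gap-limited"`.
#' @param gap relative optimality gap reported by the solver.
#' @param message optional diagnostic text.
#' @return object of class `solution_allocation`.
#' @export
solution_allocation <- function(instance, Y, C, X,
                                status = "optimal", gap = 0, message = NULL) {
  Y <- .as_flow_array(instance, Y)
  C <- matrix(C, length(instance$sites), length(instance$interventions),
              dimnames = list(instance$sites, instance$interventions))
  X <- setNames(as.numeric(X), instance$sites)
  structure(
    list(
      Y = Y, C = C, X = X,
      of1 = evaluate_of1(instance, Y),
      of2 = evaluate_of2(instance, Y),
      status = status, gap = gap, message = message
    ),
    class = "solution_allocation"
  )
}

#' @export
print.solution_allocation <- function(x, ...) {
  open <- names(x$X)[x$X > 0.5]
  cat("<solution_allocation> status:", x$status, "\n")
  cat("  OF1 =", format(x$of1), " OF2 =", format(x$of2), "\n")
  cat("  open sites (", length(open), "): ",
      paste(head(open, 8), collapse = ", "),
      if (length(open) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Check a solution against every model constraint
#'
#' Re-validates integrality, nonnegativity and each constraint family of the
#' integer program for an arbitrary (not necessarily solver-produced)
#' solution. An empty report means the solution is feasible.
#'
#' @param instance a [problem_instance()].
#' @param solution a [solution_allocation()] or a list with `Y`, `C`, `X`.
#' @param tol numeric feasibility tolerance.
#' @return data.frame with columns `constraint`, `where`, `lhs`, `rhs`; zero
#'   rows when all constraints hold.
#' @export
verify_solution <- function(instance, solution, tol = 1e-6) {
  inst <- instance
  Y <- .as_flow_array(inst, solution$Y)
  C <- solution$C; X <- solution$X
  n_i <- dim(Y)[1]; n_j <- dim(Y)[2]; n_k <- dim(Y)[3]
  Fk <- inst$hourly_cost; Lk <- inst$hours_per_patient
  cap_k <- floor(inst$budget / Fk)
  out <- list()
  bad <- function(constraint, where, lhs, rhs) {
    out[[length(out) + 1L]] <<- data.frame(
      constraint = constraint, where = where, lhs = lhs, rhs = rhs,
      stringsAsFactors = FALSE
    )
  }
  if (any(abs(Y - round(Y)) > tol)) bad("integrality", "Y", NA, NA)
  if (any(abs(C - round(C)) > tol)) bad("integrality", "C", NA, NA)
  if (any(abs(X - round(X)) > tol) || any(X < -tol | X > 1 + tol)) {
    bad("binary", "X", NA, NA)
  }
  if (any(Y < -tol)) bad("nonnegativity", "Y", min(Y), 0)
  if (any(C < -tol)) bad("nonnegativity", "C", min(C), 0)
  for (k in seq_len(n_k)) {
    Yk <- matrix(Y[, , k], nrow = n_i)
    served <- rowSums(Yk)
    over <- which(served > inst$D[, k] + tol)
    for (i in over) {
      bad("demand", sprintf("[%s,%s]", inst$nodes[i], inst$interventions[k]),
          served[i], inst$D[i, k])
    }
    spend <- Fk[k] * sum(C[, k])
    if (spend > inst$budget[k] + tol * max(1, inst$budget[k])) {
      bad("budget", inst$interventions[k], spend, inst$budget[k])
    }
    used <- colSums(Yk) * Lk[k]
    for (j in which(used > C[, k] + tol)) {
      bad("capacity", sprintf("[%s,%s]", inst$sites[j], inst$interventions[k]),
          used[j], C[j, k])
    }
    for (j in which(C[, k] > cap_k[k] * X + tol)) {
      bad("capacity-without-opening",
          sprintf("[%s,%s]", inst$sites[j], inst$interventions[k]),
          C[j, k], cap_k[k] * X[j])
    }
  }
  site_flow <- apply(Y, 2, sum)
  for (j in which(rowSums(C) < inst$r_min * X - tol)) {
    bad("min_hours", inst$sites[j], sum(C[j, ]), inst$r_min * X[j])
  }
  for (j in which(site_flow > inst$big_m * X + tol)) {
    bad("open_link", inst$sites[j], site_flow[j], inst$big_m * X[j])
  }
  if (!is.null(inst$phi_k)) {
    for (k in seq_len(n_k)) {
      got <- rowSums(matrix(Y[, , k], nrow = n_i))
      for (i in which(got < inst$phi_k[k] - tol)) {
        bad("min_service", sprintf("[%s,%s]", inst$nodes[i], inst$interventions[k]),
            got[i], inst$phi_k[k])
      }
    }
  } else {
    got <- apply(Y, 1, sum)
    for (i in which(got < inst$phi - tol)) {
      bad("min_service", inst$nodes[i], got[i], inst$phi)
    }
  }
  if (length(out) == 0L) {
    data.frame(constraint = character(0), where = character(0),
               lhs = numeric(0), rhs = numeric(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, out)
  }
}
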