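# Bridge to the exact MILP backend (HiGHS, driven through a small Python
# helper shipped in inst/python). The backend receives the sparse model once
# per batch and solves each objective/epsilon variant on it, so a whole
# epsilon sweep costs a single process launch.

.python_binary <- function() {
  opt <- getOption("equiloc.python", NULL)
  if (!is.null(opt)) return(opt)
  for (cand in c("python", "python3")) {
    p <- Sys.which(cand)
    if (nzchar(p)) return(unname(p))
  }
  stop("no python interpreter found for the MILP backend; ",
       "set options(equiloc.python = ...)", call. = FALSE)
}

.backend_script <- function() {
  p <- system.file("python", "milp_backend.py", package = "equiloc")
  if (!nzchar(p)) stop("milp_backend.py not found in installed package",
                       call. = FALSE)
  p
}

# specs: list of list(objective = "of1"|"of2", epsilon = NULL or numeric
# floor on OF2). Returns a list of solution_allocation / equiloc_infeasible.
.solve_models <- function(instance, specs, gap = 1e-4, model = NULL) {
  if (is.null(model)) model <- build_model(instance)
  problems <- lapply(specs, function(sp) {
    cc <- if (sp$objective == "of2") model$c_of2 else model$c_of1
    p <- list(c = cc)
    if (!is.null(sp$epsilon)) {
      nz <- which(model$c_of2 != 0)
      p$extra <- list(col = nz, val = -model$c_of2[nz], rhs = -sp$epsilon)
    }
    p
  })
  payload <- list(
    n_var = model$n_var, n_con = length(model$b_ub),
    a_row = model$a_row, a_col = model$a_col, a_val = model$a_val,
    b_ub = model$b_ub, lb = model$lb, ub = model$ub,
    integrality = model$integrality, gap = gap,
    problems = problems
  )
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  jsonlite::write_json(payload, infile, auto_unbox = TRUE, digits = NA)
  status <- system2(.python_binary(), c(.backend_script(), infile, outfile),
                    stdout = TRUE, stderr = TRUE)
  if (!file.exists(outfile)) {
    stop("MILP backend failed:\n", paste(status, collapse = "\n"),
         call. = FALSE)
  }
  res <- jsonlite::read_json(outfile, simplifyVector = TRUE)$results
  lay <- model$layout
  out <- vector("list", length(specs))
  for (t in seq_along(specs)) {
    r <- if (is.data.frame(res)) lapply(res, `[[`, t) else res[[t]]
    if (!isTRUE(r$success) || is.null(r$x[[1]])) {
      out[[t]] <- .infeasible_result(instance, r$status)
      next
    }
    x <- round(unlist(r$x))
    Y <- x[seq_len(lay$nY)]
    C <- x[lay$nY + seq_len(lay$nC)]
    X <- x[lay$nY + lay$nC + seq_len(lay$n_j)]
    st <- if (identical(r$status, "optimal")) "optimal" else "gap-limited"
    g <- if (is.null(r$gap) || is.na(r$gap)) 0 else r$gap
    out[[t]] <- solution_allocation(instance, Y, C, X, status = st, gap = g)
  }
  out
}

.infeasible_result <- function(instance, solver_status) {
  msg <- .diagnose_infeasibility(instance)
  structure(
    list(status = "infeasible", solver_status = solver_status,
         message = msg),
    class = "equiloc_infeasible"
  )
}

# Name the first violated necessary feasibility condition, if any.
.diagnose_infeasibility <- function(inst) {
  tot <- rowSums(inst$D)
  phi_req <- if (!is.null(inst$phi_k)) sum(inst$phi_k) else inst$phi
  if (!is.null(inst$phi_k)) {
    for (k in seq_along(inst$phi_k)) {
      short <- which(inst$D[, k] < inst$phi_k[k])
      if (length(short) > 0L) {
        return(sprintf(
          "minimum per-intervention service phi_k[%s]=%g exceeds demand at node %s",
          inst$interventions[k], inst$phi_k[k], inst$nodes[short[1]]))
      }
    }
  } else if (any(tot < inst$phi)) {
    i <- which(tot < inst$phi)[1]
    return(sprintf("minimum service phi=%g exceeds total demand %g at node %s",
                   inst$phi, tot[i], inst$nodes[i]))
  }
  fundable <- floor(inst$budget / inst$hourly_cost)
  if (phi_req > 0 && sum(fundable) < inst$r_min) {
    return(sprintf(
      "budgets fund only %g capacity hours in total, below the R_min=%g needed to open any center",
      sum(fundable), inst$r_min))
  }
  if (phi_req > 0) {
    # cheapest-hours assignment of the phi minimum across interventions
    need <- .phi_assignment(inst)
    hours <- colSums(need) * inst$hours_per_patient
    lack <- which(hours > fundable)
    if (length(lack) > 0L) {
      k <- lack[1]
      return(sprintf(
        "serving the phi minimum needs %.0f %s hours but the budget funds only %g",
        hours[k], inst$interventions[k], fundable[k]))
    }
  }
  "no single violated necessary condition identified; constraints are jointly infeasible"
}

# Greedy per-node assignment of the phi minimum to interventions in order of
# increasing hours-per-patient, respecting the demand caps. Returns an
# |I| x |K| patient matrix.
.phi_assignment <- function(inst) {
  n_i <- length(inst$nodes); n_k <- length(inst$interventions)
  f <- matrix(0, n_i, n_k, dimnames = dimnames(inst$D))
  if (!is.null(inst$phi_k)) {
    for (k in seq_len(n_k)) f[, k] <- pmin(inst$phi_k[k], inst$D[, k])
    return(f)
  }
  if (inst$phi <= 0) return(f)
  ord <- order(inst$hours_per_patient)
  for (i in seq_len(n_i)) {
    left <- inst$phi
    for (k in ord) {
      take <- min(left, inst$D[i, k])
      f[i, k] <- take
      left <- left - take
      if (left <= 0) break
    }
  }
  f
}

#' Test whether a solve result is an infeasibility report
#'
#' @param x result of [build_and_solve()] or a frontier solve.
#' @return logical scalar.
#' @export
is_infeasible <- function(x) inherits(x, "equiloc_infeasible")

#' @export
print.equiloc_infeasible <- function(x, ...) {
  cat("<infeasible> ", x$message, "\n", sep = "")
  invisible(x)
}

#' Solve the location-allocation integer program exactly
#'
#' Builds the capacitated integer program and solves it with the exact MILP
#' backend (HiGHS branch-and-bound) to the requested relative optimality gap.
#' Three scalarisations are available: objective 1 alone (risk-weighted),
#' objective 2 alone (equity-weighted), or objective 1 with an
#' epsilon-constraint floor on objective 2 — the building block of the
#' Pareto sweep.
#'
#' @param instance a [problem_instance()].
#' @param objective `"of1"`, `"of2"`, or `"of1_with_of2_floor"`.
#' @param epsilon floor on objective 2; required when
#'   `objective = "of1_with_of2_floor"`.
#' @param gap relative MIP optimality gap (default `1e-4`).
#' @return a [solution_allocation()] with both objective values recomputed
#'   from the flows, or an infeasibility report (see [is_infeasible()])
#'   naming the first violated necessary condition.
#' @export
build_and_solve <- function(instance,
                            objective = c("of1", "of2", "of1_with_of2_floor"),
                            epsilon = NULL, gap = 1e-4) {
  objective <- match.arg(objective)
  if (objective == "of1_with_of2_floor" && is.null(epsilon)) {
    stop("epsilon is required for of1_with_of2_floor", call. = FALSE)
  }
  spec <- switch(objective,
    of1 = list(objective = "of1", epsilon = NULL),
    of2 = list(objective = "of2", epsilon = NULL),
    of1_with_of2_floor = list(objective = "of1", epsilon = epsilon)
  )
  .solve_models(instance, list(spec), gap = gap)[[1]]
}
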