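# Epsilon-constraint Pareto frontier generation and knee-point selection.

#' Ideal point of the bi-objective model
#'
#' Solves each objective independently at the same constraint set and returns
#' the vector of their optima. The ideal point is generally infeasible
#' jointly; it anchors the knee-point selection.
#'
#' @param instance a [problem_instance()].
#' @param gap relative MIP gap for both solves.
#' @return list with `of1`, `of2` (the two optima) and the two underlying
#'   [solution_allocation()]s (`sol_of1`, `sol_of2`).
#' @export
ideal_point <- function(instance, gap = 1e-4) {
  sols <- .solve_models(instance, list(
    list(objective = "of1", epsilon = NULL),
    list(objective = "of2", epsilon = NULL)
  ), gap = gap)
  if (is_infeasible(sols[[1]]) || is_infeasible(sols[[2]])) {
    bad <- if (is_infeasible(sols[[1]])) sols[[1]] else sols[[2]]
    stop("single-objective problem infeasible: ", bad$message, call. = FALSE)
  }
  list(of1 = sols[[1]]$of1, of2 = sols[[2]]$of2,
       sol_of1 = sols[[1]], sol_of2 = sols[[2]])
}

#' Retain the non-dominated subset of objective pairs
#'
#' A point is kept iff no other point is at least as good in both objectives
#' and strictly better in one. Exact duplicates collapse to their first
#' occurrence.
#'
#' @param points data.frame (or matrix) with columns `of1`, `of2`.
#' @return the retained rows of `points`, in input order.
#' @export
filter_nondominated <- function(points) {
  as.data.frame(points)[.nondominated_idx(points), , drop = FALSE]
}

.nondominated_idx <- function(points) {
  pts <- as.data.frame(points)
  n <- nrow(pts)
  if (n == 0L) return(integer(0))
  keep <- rep(TRUE, n)
  for (p in seq_len(n)) {
    for (q in seq_len(n)) {
      if (p == q) next
      ge <- pts$of1[q] >= pts$of1[p] && pts$of2[q] >= pts$of2[p]
      strict <- pts$of1[q] > pts$of1[p] || pts$of2[q] > pts$of2[p]
      if (ge && strict) { keep[p] <- FALSE; break }
      if (ge && !strict && q < p) { keep[p] <- FALSE; break }  # duplicate
    }
  }
  which(keep)
}

#' Select the best-compromise (knee) frontier point
#'
#' Standardises each objective over the frontier points (z-score with the
#' population standard deviation), standardises the ideal point with the same
#' frontier statistics, and returns the index of the frontier point with
#' minimal Euclidean distance to the standardised ideal. A zero-variance
#' objective contributes nothing to the distance; ties break to the lowest
#' index; a single-point frontier returns index 1.
#'
#' @param of1,of2 numeric vectors of frontier objective values.
#' @param ideal length-2 numeric vector `(of1*, of2*)`.
#' @return integer index into the frontier.
#' @export
select_knee <- function(of1, of2, ideal) {
  n <- length(of1)
  stopifnot(length(of2) == n, n >= 1, length(ideal) == 2)
  if (n == 1L) return(1L)
  zcol <- function(v, target) {
    mu <- mean(v)
    s <- sqrt(mean((v - mu)^2))
    if (s == 0) return(list(z = rep(0, length(v)), zi = 0))
    list(z = (v - mu) / s, zi = (target - mu) / s)
  }
  z1 <- zcol(of1, ideal[1])
  z2 <- zcol(of2, ideal[2])
  d2 <- (z1$z - z1$zi)^2 + (z2$z - z2$zi)^2
  which.min(d2)  # first minimum on ties
}

#' Trace the Pareto frontier with the epsilon-constraint method
#'
#' Maximises objective 1 subject to an increasing floor `epsilon` on
#' objective 2, over a linear grid from the OF2 value attained by the
#' unconstrained OF1 optimum up to the OF2 optimum. Infeasible or gap-limited
#' grid points are recorded and skipped; dominated points are filtered; the
#' knee is selected against the ideal point.
#'
#' @param instance a [problem_instance()].
#' @param n_points number of epsilon grid points (>= 2), or use `grid`.
#' @param grid explicit numeric vector of epsilon values (overrides
#'   `n_points`).
#' @param gap relative MIP gap per solve.
#' @return object of class `pareto_frontier`: list with `points` (data.frame
#'   `epsilon`, `of1`, `of2`, `n_open`, `open_sites`, `is_knee`),
#'   `solutions` (list of [solution_allocation()]s parallel to `points`),
#'   `ideal`, `knee` (row index), `epsilon_grid`, `skipped`.
#' @export
epsilon_sweep <- function(instance, n_points = 20, grid = NULL, gap = 1e-4) {
  if (is.null(grid) && n_points < 2) {
    stop("n_points must be at least 2", call. = FALSE)
  }
  anchors <- ideal_point(instance, gap = gap)
  if (is.null(grid)) {
    lo <- anchors$sol_of1$of2   # OF2 at the unconstrained OF1 optimum
    hi <- anchors$of2
    grid <- seq(lo, hi, length.out = n_points)
  }
  specs <- lapply(grid, function(e) list(objective = "of1", epsilon = e))
  sols <- .solve_models(instance, specs, gap = gap)
  ok <- vapply(sols, function(s) !is_infeasible(s), logical(1))
  skipped <- grid[!ok]
  if (!any(ok)) stop("empty frontier: every epsilon value was infeasible",
                     call. = FALSE)
  grid_ok <- grid[ok]
  sols_ok <- sols[ok]
  of1 <- vapply(sols_ok, `[[`, numeric(1), "of1")
  of2 <- vapply(sols_ok, `[[`, numeric(1), "of2")
  keep <- .nondominated_idx(data.frame(of1 = of1, of2 = of2))
  ord <- keep[order(grid_ok[keep], of2[keep])]
  pts <- data.frame(
    epsilon = grid_ok[ord], of1 = of1[ord], of2 = of2[ord],
    n_open = vapply(sols_ok[ord], function(s) sum(s$X > 0.5), numeric(1)),
    open_sites = vapply(sols_ok[ord], function(s) {
      paste(names(s$X)[s$X > 0.5], collapse = ";")
    }, character(1)),
    stringsAsFactors = FALSE
  )
  knee <- select_knee(pts$of1, pts$of2, c(anchors$of1, anchors$of2))
  pts$is_knee <- seq_len(nrow(pts)) == knee
  structure(
    list(
      points = pts, solutions = sols_ok[ord],
      ideal = c(of1 = anchors$of1, of2 = anchors$of2),
      ideal_solutions = list(of1 = anchors$sol_of1, of2 = anchors$sol_of2),
      knee = knee, epsilon_grid = grid, skipped = skipped
    ),
    class = "pareto_frontier"
  )
}

#' @export
print.pareto_frontier <- function(x, ...) {
  cat("<pareto_frontier> ", nrow(x$points), " non-dominated points (",
      length(x$skipped), " epsilon values skipped)\n", sep = "")
  cat("  ideal: (", format(x$ideal[1]), ", ", format(x$ideal[2]), ")\n",
      sep = "")
  k <- x$points[x$knee, ]
  cat("  knee:  (", format(k$of1), ", ", format(k$of2), ") opening ",
      k$open_sites, "\n", sep = "")
  invisible(x)
}

#' Write a frontier to CSV
#'
#' @param frontier a [epsilon_sweep()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_frontier_csv <- function(frontier, path) {
  write.csv(frontier$points, path, row.names = FALSE)
  invisible(path)
}
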