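#' Per-node share of estimated substance consumers
#'
#' The consumption component of the composite risk index: each node's
#' estimated consumer count divided by the total over all nodes. When no node
#' reports any consumers the whole vector is zero rather than an error, so
#' degenerate synthetic cases remain runnable.
#'
#' @param profiles a [municipality_profiles()] table.
#' @return numeric vector, one share per node, summing to 1 (or all zero).
#' @export
compute_alpha <- function(profiles) {
  .proportion_of(profiles, "consumers")
}

#' Per-node share of negative social-media posts
#'
#' The sentiment component of the risk index: negative post count divided by
#' the total number of negative posts across nodes. Nodes with no posts are
#' assigned zero; this does not imply absence of risk, only absence of signal.
#'
#' @inheritParams compute_alpha
#' @return numeric vector of shares.
#' @export
compute_psi <- function(profiles) {
  .proportion_of(profiles, "posts_negative")
}

#' Per-node share of crime incidents (risk-factor component)
#'
#' Contextual risk factors (homicide, theft, sexual crimes, threats, ...)
#' expressed as each node's incident count over the total, mirroring the
#' construction of the consumption and sentiment shares.
#'
#' @inheritParams compute_alpha
#' @return numeric vector of shares.
#' @export
compute_gamma <- function(profiles) {
  .proportion_of(profiles, "crime_incidents")
}

.proportion_of <- function(profiles, column) {
  if (!is.data.frame(profiles) || nrow(profiles) < 1L) {
    stop("profiles must have at least one row", call. = FALSE)
  }
  v <- as.numeric(profiles[[column]])
  if (any(v < 0)) stop("'", column, "' must be nonnegative", call. = FALSE)
  total <- sum(v)
  if (total <= 0) return(rep(0, length(v)))
  v / total
}

#' Composite consumption-risk index
#'
#' The prevention-risk index is the unweighted mean of the three share
#' components (consumption `alpha`, negative sentiment `psi`, crime `gamma`);
#' the mitigation-risk index is half of it, encoding the working assumption
#' that for every two individuals at mitigation risk there is one at
#' prevention risk.
#'
#' @param alpha,psi,gamma share vectors of equal length with entries in
#'   `[0, 1]` (see [compute_alpha()], [compute_psi()], [compute_gamma()]).
#' @return list with `prevention` and `mitigation` numeric vectors.
#' @export
compute_risk <- function(alpha, psi, gamma) {
  n <- length(alpha)
  if (length(psi) != n || length(gamma) != n) {
    stop("alpha, psi, gamma must have equal length", call. = FALSE)
  }
  for (v in list(alpha, psi, gamma)) {
    if (any(v < 0 | v > 1)) stop("shares must lie in [0, 1]", call. = FALSE)
  }
  r1 <- (alpha + psi + gamma) / 3
  list(prevention = r1, mitigation = r1 / 2)
}

#' Composite equity index
#'
#' Multiplicative aggregation of the multidimensional poverty index and the
#' rurality proportion: only nodes that are both poor and rural receive a
#' high equity priority, with no substitution between the two deprivations.
#' The mitigation index is half the prevention index, as for risk.
#'
#' @param mpi,rurality numeric vectors in `[0, 1]`, equal length.
#' @return list with `prevention` and `mitigation` numeric vectors.
#' @export
compute_equity <- function(mpi, rurality) {
  if (length(mpi) != length(rurality)) {
    stop("mpi and rurality must have equal length", call. = FALSE)
  }
  if (any(mpi < 0 | mpi > 1) || any(rurality < 0 | rurality > 1)) {
    stop("mpi and rurality must lie in [0, 1]", call. = FALSE)
  }
  s1 <- rurality * mpi
  list(prevention = s1, mitigation = s1 / 2)
}

#' Full index table for a profile set
#'
#' Computes the share components and the composite risk and equity indices in
#' one pass. The result is frozen: editing the profile table afterwards does
#' not update a previously computed index table.
#'
#' @inheritParams compute_alpha
#' @return data.frame with columns `node_id`, `alpha`, `psi`, `gamma`, `R1`,
#'   `R2`, `sigma1`, `sigma2`.
#' @export
compute_indices <- function(profiles) {
  alpha <- compute_alpha(profiles)
  psi <- compute_psi(profiles)
  gamma <- compute_gamma(profiles)
  risk <- compute_risk(alpha, psi, gamma)
  eq <- compute_equity(profiles$mpi, profiles$rurality)
  data.frame(
    node_id = as.character(profiles$node_id),
    alpha = alpha, psi = psi, gamma = gamma,
    R1 = risk$prevention, R2 = risk$mitigation,
    sigma1 = eq$prevention, sigma2 = eq$mitigation,
    stringsAsFactors = FALSE
  )
}

#' Write an index table to CSV
#'
#' @param indices result of [compute_indices()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_indices_csv <- function(indices, path) {
  write.csv(indices, path, row.names = FALSE)
  invisible(path)
}
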