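# Seeded synthetic municipality networks with the statistical structure the
# analysis assumes: one dominant city holding most of the population and
# social-media activity, heavy-tailed populations, poverty and rurality
# inversely rank-correlated with population, and per-intervention demand in
# a 2:1 mitigation:prevention ratio.

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic instance generator
#'
#' Defaults describe a department-scale network of 23 municipalities with a
#' single dominant city holding about 60 percent of the population (and,
#' through per-capita rates, the large majority of social-media posts),
#' log-normal populations elsewhere, poverty and rurality decreasing with
#' population, and per-intervention budgets set to a fraction of the cost of
#' serving all demand.
#'
#' @param n_nodes number of municipalities.
#' @param seed mandatory integer seed; the generator never draws from the
#'   global random state implicitly.
#' @param bbox_lat,bbox_lon latitude/longitude bounds (decimal degrees) for
#'   sampled centroids.
#' @param pop_meanlog,pop_sdlog log-normal parameters for non-dominant
#'   populations.
#' @param dominant_share share of the total population held by the dominant
#'   city.
#' @param consumption_rate estimated substance consumers per capita; the
#'   mitigation demand equals the consumer count and the prevention demand is
#'   half of it.
#' @param posts_rate social-media posts per capita.
#' @param sentiment_split length-3 probabilities (negative, neutral,
#'   positive) summing to 1.
#' @param incidents_rate crime incidents per capita.
#' @param mpi_range,rurality_range ranges of the multidimensional poverty
#'   index and the rurality proportion.
#' @param budget_fraction per-intervention budget as a fraction of the cost
#'   of serving the full demand.
#' @param phi_fraction the minimum-service floor `phi` as a fraction of the
#'   smallest node's total demand.
#' @param hourly_cost,hours_per_patient,r_min,delta,pi_weight model scalars;
#'   defaults are the prevention/mitigation salary-derived hourly costs
#'   (COP 1.8m and 6.1m monthly over 160 monthly hours), 0.05 and 1 service
#'   hours per patient, 2080 minimum annual hours, and 0.7 weights.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_nodes = 23, seed,
                             bbox_lat = c(10.25, 11.10),
                             bbox_lon = c(-75.28, -74.71),
                             pop_meanlog = 6.5, pop_sdlog = 1.0,
                             dominant_share = 0.6,
                             consumption_rate = 0.08,
                             posts_rate = 0.02,
                             sentiment_split = c(0.5, 0.3, 0.2),
                             incidents_rate = 0.02,
                             mpi_range = c(0.05, 0.6),
                             rurality_range = c(0.02, 0.85),
                             budget_fraction = 0.5,
                             phi_fraction = 0.5,
                             hourly_cost = c(11250, 38125),
                             hours_per_patient = c(0.05, 1),
                             r_min = 2080,
                             delta = 0.7, pi_weight = 0.7) {
  if (missing(seed)) stop("generator_config requires an explicit seed",
                          call. = FALSE)
  stopifnot(n_nodes >= 1, abs(sum(sentiment_split) - 1) < 1e-9,
            dominant_share > 0, dominant_share < 1,
            budget_fraction > 0, phi_fraction >= 0)
  structure(as.list(environment()), class = "generator_config")
}

#' Generate a synthetic municipality network and problem instance
#'
#' Deterministic for a fixed seed. The dominant city leads both population
#' and post counts; equity indices (MPI x rurality) are larger for small
#' remote nodes; demand follows population with a 2:1 mitigation:prevention
#' split; distances are haversine on the sampled coordinates; indices are
#' computed through [compute_indices()]. If the drawn budgets cannot fund the
#' minimum-service floor the budgets are enlarged stepwise (with a message)
#' until the feasibility precheck passes.
#'
#' @param config a [generator_config()], or a seed given via `...` arguments
#'   forwarded to [generator_config()].
#' @param ... forwarded to [generator_config()] when `config` is missing.
#' @return list with `profiles` (a [municipality_profiles()] table),
#'   `instance` (a [problem_instance()]), and `config`.
#' @export
generate_instance <- function(config = NULL, ...) {
  if (is.null(config)) config <- generator_config(...)
  stopifnot(inherits(config, "generator_config"))
  cfg <- config
  .with_seed(cfg$seed, {
    n <- cfg$n_nodes
    others <- if (n > 1) {
      round(rlnorm(n - 1, cfg$pop_meanlog, cfg$pop_sdlog)) + 100
    } else numeric(0)
    dominant <- if (n > 1) {
      round(cfg$dominant_share / (1 - cfg$dominant_share) * sum(others))
    } else round(exp(cfg$pop_meanlog))
    population <- c(dominant, others)
    ids <- sprintf("M%02d", seq_len(n))
    names_txt <- c("Ciudad Dominante",
                   sprintf("Municipio %02d", seq_len(n)[-1])[seq_len(max(0, n - 1))])

    consumers <- round(population * cfg$consumption_rate *
                         runif(n, 0.8, 1.2))
    d_mit <- consumers
    d_prev <- round(consumers / 2)
    posts_total <- rbinom(n, size = population,
                          prob = pmin(1, cfg$posts_rate))
    neg <- rbinom(n, posts_total, cfg$sentiment_split[1])
    neu <- rbinom(n, posts_total - neg,
                  cfg$sentiment_split[2] / max(1e-12, 1 - cfg$sentiment_split[1]))
    pos <- posts_total - neg - neu
    incidents <- round(population * cfg$incidents_rate * runif(n, 0.7, 1.3))

    # poverty and rurality fall with population rank (dominant city lowest)
    rk <- rank(-population, ties.method = "first")  # 1 = largest
    u <- pmin(1, pmax(0, (rk - 1 + runif(n, -1.5, 1.5)) / max(1, n - 1)))
    mpi <- cfg$mpi_range[1] + u * diff(cfg$mpi_range)
    u2 <- pmin(1, pmax(0, (rk - 1 + runif(n, -1.5, 1.5)) / max(1, n - 1)))
    rurality <- cfg$rurality_range[1] + u2 * diff(cfg$rurality_range)

    lat <- runif(n, cfg$bbox_lat[1], cfg$bbox_lat[2])
    lon <- runif(n, cfg$bbox_lon[1], cfg$bbox_lon[2])

    profiles <- municipality_profiles(data.frame(
      node_id = ids, name = names_txt, latitude = lat, longitude = lon,
      population = population,
      demand_prevention = d_prev, demand_mitigation = d_mit,
      consumers = consumers,
      posts_negative = neg, posts_neutral = neu, posts_positive = pos,
      crime_incidents = incidents, mpi = mpi, rurality = rurality,
      stringsAsFactors = FALSE
    ))

    D <- cbind(prevention = d_prev, mitigation = d_mit)
    phi <- max(1, floor(cfg$phi_fraction * min(rowSums(D))))
    budget <- round(cfg$budget_fraction * cfg$hourly_cost *
                      cfg$hours_per_patient * colSums(D))

    inst <- NULL
    for (attempt in 1:20) {
      inst <- instance_from_profiles(
        profiles, budget = budget,
        hourly_cost = cfg$hourly_cost,
        hours_per_patient = cfg$hours_per_patient,
        r_min = cfg$r_min, phi = phi,
        delta = cfg$delta, pi_weight = cfg$pi_weight
      )
      if (.precheck_feasible(inst)) break
      budget <- ceiling(budget * 1.5)
      message("generate_instance: budgets enlarged to fund the minimum ",
              "service floor (attempt ", attempt, ")")
    }
    list(profiles = profiles, instance = inst, config = cfg)
  })
}

# Necessary-condition feasibility precheck used by the generator.
.precheck_feasible <- function(inst) {
  fundable <- floor(inst$budget / inst$hourly_cost)
  if (any(rowSums(inst$D) < inst$phi)) return(FALSE)
  f <- .phi_assignment(inst)
  reserve <- ceiling(colSums(f) * inst$hours_per_patient)
  all(reserve <= fundable) &&
    (inst$phi == 0 || sum(fundable) >= inst$r_min + sum(reserve))
}

#' Assemble a problem instance from a profile table
#'
#' Computes the risk and equity index tables via [compute_indices()], takes
#' demand from the profile demand columns, and the distance matrix from
#' coordinates ([haversine_matrix()]) unless one is supplied.
#'
#' @param profiles a [municipality_profiles()] table.
#' @param dm optional [distance_matrix()]; defaults to haversine distances.
#' @param budget,hourly_cost,hours_per_patient,r_min,phi,delta,pi_weight,big_m,phi_k
#'   model scalars, see [problem_instance()].
#' @return a [problem_instance()].
#' @export
instance_from_profiles <- function(profiles, dm = NULL, budget,
                                   hourly_cost = c(11250, 38125),
                                   hours_per_patient = c(0.05, 1),
                                   r_min = 2080, phi = 0,
                                   delta = 0.7, pi_weight = 0.7,
                                   big_m = NULL, phi_k = NULL) {
  idx <- compute_indices(profiles)
  if (is.null(dm)) dm <- haversine_matrix(profiles)
  problem_instance(
    nodes = profiles$node_id,
    R = cbind(idx$R1, idx$R2),
    sigma = cbind(idx$sigma1, idx$sigma2),
    D = cbind(profiles$demand_prevention, profiles$demand_mitigation),
    dm = dm, budget = budget, hourly_cost = hourly_cost,
    hours_per_patient = hours_per_patient, r_min = r_min, phi = phi,
    delta = delta, pi_weight = pi_weight, big_m = big_m, phi_k = phi_k
  )
}

#' Random tiny instance within the enumeration guard
#'
#' Draws a small feasible instance (by default 2-3 nodes/sites, total demand
#' at most about ten patients, small minimum-hours floor) suitable for
#' certifying the exact solver against [brute_force_solve()].
#'
#' @param seed integer seed.
#' @param n_i,n_j,n_k set sizes (must respect the enumeration guard).
#' @return list with `instance` and `profiles = NULL`.
#' @export
random_tiny_instance <- function(seed, n_i = 2, n_j = 2, n_k = 2) {
  stopifnot(n_j <= 3, n_k <= 2)
  .with_seed(seed, {
    ids <- sprintf("N%d", seq_len(max(n_i, n_j)))
    nodes <- ids[seq_len(n_i)]
    sites <- ids[seq_len(n_j)]
    coords <- cbind(runif(length(ids), 0, 1), runif(length(ids), 0, 1))
    d <- as.matrix(dist(coords)) * 100
    dm <- distance_matrix(d, ids)
    max_per_cell <- max(1, floor(10 / (n_i * n_k)))
    D <- matrix(sample(0:max_per_cell, n_i * n_k, replace = TRUE), n_i, n_k)
    if (sum(D) > 12) D <- pmax(0, D - 1)
    R <- matrix(runif(n_i * n_k, 0, 1), n_i, n_k)
    # equity runs against risk, as in the domain: nodes with a small share
    # of consumption are the poor remote ones — this makes the two
    # objectives genuinely conflict on most draws
    sigma <- 0.5 * (1 - R / max(R)) * matrix(runif(n_i * n_k, 0.5, 1), n_i, n_k)
    L <- c(0.5, 1)[seq_len(n_k)]
    Fk <- sample(1:3, n_k, replace = TRUE)
    r_min <- sample(1:2, 1)
    # fundable hours strictly below the full-service need, so the budget
    # rations which cells are served and the objectives must trade off
    full_hours <- colSums(D * rep(L, each = n_i))
    budget <- ceiling(Fk * pmax(r_min, full_hours * runif(n_k, 0.35, 0.75)))
    phi <- if (min(rowSums(D)) >= 1 && runif(1) < 0.5) 1 else 0
    inst <- problem_instance(
      nodes = nodes, sites = sites, R = R, sigma = sigma, D = D, dm = dm,
      budget = budget, hourly_cost = Fk, hours_per_patient = L,
      r_min = r_min, phi = phi,
      delta = round(runif(1, 0.3, 0.9), 2),
      pi_weight = round(runif(1, 0.3, 0.9), 2)
    )
    list(instance = inst, profiles = NULL)
  })
}
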