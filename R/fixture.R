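# Named department-scale fixture: 23 municipalities of a Caribbean
# department, with the published scalar parameters (budgets, salary-derived
# hourly costs, service times, minimum hours, objective weights) and the
# published per-municipality post counts. Quantities that are not public at
# municipality level (demand, poverty, rurality, incidents, coordinates) are
# synthesised from a fixed seed and are explicitly labelled synthetic.

.ATLANTICO_NAMES <- c(
  "Barranquilla", "Baranoa", "Campo de La Cruz", "Candelaria", "Galapa",
  "Juan de Acosta", "Luruaco", "Malambo", "Manati", "Palmar de Varela",
  "Piojo", "Polonuevo", "Ponedera", "Puerto Colombia", "Repelon",
  "Sabanagrande", "Sabanalarga", "Santa Lucia", "Santo Tomas", "Soledad",
  "Suan", "Tubara", "Usiacuri"
)

# Published post counts; rows reported for merged municipality groups are
# split evenly with the remainder assigned to the first-listed town.
.ATLANTICO_POSTS <- c(
  Barranquilla = 2741, Baranoa = 18,
  "Campo de La Cruz" = 5, Candelaria = 3, Galapa = 3,   # 11 split 3 ways
  "Juan de Acosta" = 11,
  Luruaco = 12, Malambo = 12,                           # 24 split 2 ways
  Manati = 1, "Palmar de Varela" = 1,
  Piojo = 3, Polonuevo = 2,                             # 5 split 2 ways
  Ponedera = 1, "Puerto Colombia" = 108,
  Repelon = 4, Sabanagrande = 4,                        # 8 split 2 ways
  Sabanalarga = 24,
  "Santa Lucia" = 1, "Santo Tomas" = 0,                 # 1 split 2 ways
  Soledad = 124,
  Suan = 3, Tubara = 2,                                 # 5 split 2 ways
  Usiacuri = 2
)

#' Department-scale named fixture
#'
#' A 23-municipality instance carrying the published scalars: prevention and
#' mitigation budgets of COP 654 million and 3 billion, hourly costs derived
#' from the monthly salaries of a psychologist (COP 1.8 million) and a
#' psychiatrist (COP 6.1 million) over 160 monthly hours, service times of
#' 0.05 and 1 hours per patient, a 2,080-hour minimum annual capacity, and
#' objective weights `delta = pi = 0.7`. Per-municipality post counts follow
#' the published distribution (merged rows split evenly, remainder to the
#' first-listed town). All remaining per-municipality quantities
#' (populations, demands, poverty, rurality, incidents, coordinates and
#' hence distances) are synthetic stand-ins drawn from a fixed internal seed;
#' objective values computed on this fixture are not comparable to published
#' case-study values.
#'
#' @param phi minimum patients served per node; default scales to half the
#'   smallest node's demand as in [generator_config()].
#' @return list with `profiles`, `instance`, and `synthetic_fields` (the
#'   names of the columns that are synthetic stand-ins).
#' @export
atlantico_fixture <- function(phi = NULL) {
  n <- length(.ATLANTICO_NAMES)
  .with_seed(48103171, {
    # synthetic populations: dominant capital, second city next, the rest
    # heavy-tailed small towns
    others <- sort(round(rlnorm(n - 2, 9.6, 0.8)) + 2000, decreasing = TRUE)
    population <- c(1200000, 650000, others)
    ord <- c(match(c("Barranquilla", "Soledad"), .ATLANTICO_NAMES),
             setdiff(seq_len(n), match(c("Barranquilla", "Soledad"),
                                       .ATLANTICO_NAMES)))
    population <- population[order(ord)]

    consumers <- round(population * 0.08 * runif(n, 0.8, 1.2))
    d_mit <- consumers
    d_prev <- round(consumers / 2)

    posts_total <- unname(.ATLANTICO_POSTS[.ATLANTICO_NAMES])
    neg <- rbinom(n, posts_total, 0.5)
    neu <- rbinom(n, posts_total - neg, 0.6)
    pos <- posts_total - neg - neu

    incidents <- round(population * 0.02 * runif(n, 0.7, 1.3))
    rk <- rank(-population, ties.method = "first")
    u <- pmin(1, pmax(0, (rk - 1 + runif(n, -1.5, 1.5)) / (n - 1)))
    mpi <- 0.05 + u * 0.55
    u2 <- pmin(1, pmax(0, (rk - 1 + runif(n, -1.5, 1.5)) / (n - 1)))
    rurality <- 0.02 + u2 * 0.83

    lat <- runif(n, 10.25, 11.10)
    lon <- runif(n, -75.28, -74.71)

    profiles <- municipality_profiles(data.frame(
      node_id = .ATLANTICO_NAMES, name = .ATLANTICO_NAMES,
      latitude = lat, longitude = lon, population = population,
      demand_prevention = d_prev, demand_mitigation = d_mit,
      consumers = consumers,
      posts_negative = neg, posts_neutral = neu, posts_positive = pos,
      crime_incidents = incidents, mpi = mpi, rurality = rurality,
      stringsAsFactors = FALSE
    ))
    if (is.null(phi)) {
      phi <- max(1, floor(0.5 * min(d_prev + d_mit)))
    }
    inst <- instance_from_profiles(
      profiles,
      budget = c(prevention = 654e6, mitigation = 3e9),
      hourly_cost = c(hourly_cost(1.8e6), hourly_cost(6.1e6)),
      hours_per_patient = c(0.05, 1),
      r_min = annual_hours(8, 260), phi = phi,
      delta = 0.7, pi_weight = 0.7
    )
    list(
      profiles = profiles, instance = inst,
      synthetic_fields = c("latitude", "longitude", "population",
                           "demand_prevention", "demand_mitigation",
                           "consumers", "posts_negative", "posts_neutral",
                           "posts_positive", "crime_incidents", "mpi",
                           "rurality")
    )
  })
}
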