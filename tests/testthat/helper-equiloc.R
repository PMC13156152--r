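# Shared fixture builders. Everything is generated in code; nothing is read
# from disk except files the tests themselves write to tempdir().

make_profiles <- function(consumers = c(10, 30, 60),
                          posts_negative = c(3, 1, 0),
                          crime = c(1, 1, 2),
                          mpi = c(0.2, 0.4, 0.5),
                          rurality = c(0.1, 0.6, 0.8),
                          population = c(1000, 500, 200),
                          d_prev = c(5, 3, 2),
                          d_mit = c(10, 6, 4)) {
  n <- length(consumers)
  municipality_profiles(data.frame(
    node_id = sprintf("N%d", seq_len(n)),
    name = sprintf("Town %d", seq_len(n)),
    latitude = seq(10, 10.5, length.out = n),
    longitude = seq(-75, -74.6, length.out = n),
    population = population[seq_len(n)],
    demand_prevention = d_prev[seq_len(n)],
    demand_mitigation = d_mit[seq_len(n)],
    consumers = consumers,
    posts_negative = posts_negative,
    posts_neutral = rep(1, n),
    posts_positive = rep(1, n),
    crime_incidents = crime,
    mpi = mpi[seq_len(n)],
    rurality = rurality[seq_len(n)],
    stringsAsFactors = FALSE
  ))
}

# A fixed, fully hand-specified 2-node / 2-site / 1-intervention instance
# whose optimum is easy to reason about.
make_micro_instance <- function(D = matrix(c(2, 2), 2, 1),
                                R = matrix(c(0.9, 0.1), 2, 1),
                                sigma = matrix(c(0.1, 0.6), 2, 1),
                                d01 = 10, budget = 100,
                                hourly_cost = 2, L = 1, r_min = 1,
                                phi = 0, delta = 0.7, pi_weight = 0.7) {
  dmat <- matrix(c(0, d01, d01, 0), 2, 2)
  dm <- distance_matrix(dmat, c("A", "B"))
  n_k <- ncol(D)
  problem_instance(
    nodes = c("A", "B"), sites = c("A", "B"),
    R = R, sigma = sigma, D = D, dm = dm,
    budget = rep_len(budget, n_k),
    hourly_cost = rep_len(hourly_cost, n_k),
    hours_per_patient = rep_len(L, n_k),
    r_min = r_min, phi = phi, delta = delta, pi_weight = pi_weight
  )
}

# Small generated network for end-to-end runs that must stay quick.
make_small_network <- function(seed = 1, n_nodes = 6) {
  generate_instance(generator_config(n_nodes = n_nodes, seed = seed))
}
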