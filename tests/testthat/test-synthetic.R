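test_that("generation is deterministic for a fixed seed", {
  g1 <- generate_instance(generator_config(seed = 13, n_nodes = 8))
  g2 <- generate_instance(generator_config(seed = 13, n_nodes = 8))
  expect_identical(as.data.frame(g1$profiles), as.data.frame(g2$profiles))
  expect_identical(g1$instance$D, g2$instance$D)
  expect_identical(g1$instance$budget, g2$instance$budget)
  # byte-identical CSV output
  f1 <- tempfile(); f2 <- tempfile()
  write_profiles_csv(g1$profiles, f1)
  write_profiles_csv(g2$profiles, f2)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
  # a different seed changes the draw
  g3 <- generate_instance(generator_config(seed = 14, n_nodes = 8))
  expect_false(identical(g1$profiles$population, g3$profiles$population))
})

test_that("the dominant node leads population and holds most posts", {
  shares <- vapply(1:25, function(s) {
    g <- generate_instance(generator_config(seed = s, n_nodes = 10))
    posts <- g$profiles$posts_negative + g$profiles$posts_neutral +
      g$profiles$posts_positive
    top <- which.max(g$profiles$population)
    posts[top] / max(1, sum(posts))
  }, numeric(1))
  expect_gt(mean(shares > 0.5), 0.9)
})

test_that("generated instances satisfy the index and feasibility invariants", {
  for (s in c(2, 6)) {
    g <- generate_instance(generator_config(seed = s, n_nodes = 7))
    idx <- compute_indices(g$profiles)
    expect_equal(sum(idx$alpha), 1, tolerance = 1e-12)
    expect_equal(sum(idx$gamma), 1, tolerance = 1e-12)
    expect_equal(g$instance$D[, "mitigation"],
                 setNames(g$profiles$demand_mitigation, g$profiles$node_id))
    # 2:1 mitigation:prevention structure
    expect_equal(unname(g$instance$D[, "prevention"]),
                 round(g$profiles$demand_mitigation / 2))
    # the model is actually feasible, not just prechecked
    sol <- build_and_solve(g$instance, "of1")
    expect_false(is_infeasible(sol))
    expect_equal(nrow(verify_solution(g$instance, sol)), 0)
  }
})

test_that("equity indices concentrate in small remote nodes", {
  g <- generate_instance(generator_config(seed = 21, n_nodes = 23))
  idx <- compute_indices(g$profiles)
  pop_rank <- rank(g$profiles$population)
  expect_lt(cor(pop_rank, idx$sigma1, method = "spearman"), 0)
})

test_that("a 23-node network instantiates the published variable counts", {
  g <- generate_instance(generator_config(seed = 1))
  m <- build_model(g$instance)
  expect_equal(m$n_var, 1127)
  expect_equal(sum(m$vartype == "X"), 23)
})

test_that("the named department fixture carries the published scalars", {
  fx <- atlantico_fixture()
  expect_equal(unname(fx$instance$budget),
               c(654e6, 3e9))
  expect_equal(unname(fx$instance$hourly_cost), c(11250, 38125))
  expect_equal(fx$instance$r_min, 2080)
  expect_equal(unname(fx$instance$hours_per_patient), c(0.05, 1))
  expect_equal(fx$instance$delta, 0.7)
  expect_equal(fx$instance$pi_weight, 0.7)
  posts <- fx$profiles$posts_negative + fx$profiles$posts_neutral +
    fx$profiles$posts_positive
  expect_equal(posts[fx$profiles$node_id == "Barranquilla"], 2741)
  expect_equal(sum(posts), 3085)
  expect_equal(nrow(fx$profiles), 23)
  # deterministic
  fx2 <- atlantico_fixture()
  expect_identical(as.data.frame(fx$profiles), as.data.frame(fx2$profiles))
})

test_that("the generator requires an explicit seed", {
  expect_error(generator_config(n_nodes = 5), "seed")
})
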