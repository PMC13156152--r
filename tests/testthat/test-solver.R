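test_that("exact solver agrees with the enumeration oracle on tiny instances", {
  # a short certification run; the broader randomized suite lives in the
  # acceptance tests
  for (s in c(1, 3, 5)) {
    ti <- random_tiny_instance(s)$instance
    for (obj in c("of1", "of2")) {
      m <- build_and_solve(ti, obj)
      b <- brute_force_solve(ti, obj)
      expect_false(is_infeasible(m) != is_infeasible(b))
      if (!is_infeasible(m)) {
        val <- if (obj == "of1") "of1" else "of2"
        expect_equal(m[[val]], b[[val]], tolerance = 1e-9)
        expect_equal(nrow(verify_solution(ti, m)), 0)
        expect_equal(nrow(verify_solution(ti, b)), 0)
      }
    }
  }
})

test_that("impossible minimum service yields a named infeasibility", {
  inst <- make_micro_instance(D = matrix(c(2, 2), 2, 1), phi = 5)
  res <- build_and_solve(inst, "of1")
  expect_true(is_infeasible(res))
  expect_match(res$message, "phi")
  expect_match(res$message, "exceeds total demand")
})

test_that("zero budget with positive minimum hours closes every site", {
  inst <- make_micro_instance(budget = 0, r_min = 5, phi = 0)
  sol <- build_and_solve(inst, "of1")
  expect_false(is_infeasible(sol))
  expect_equal(unname(sol$X), c(0, 0))
  expect_equal(sum(sol$Y), 0)
  expect_equal(sol$of1, 0)
  expect_equal(sol$of2, 0)
  # ... and phi > 0 on top of that is infeasible, naming the budget
  inst2 <- make_micro_instance(budget = 0, r_min = 5, phi = 1)
  res <- build_and_solve(inst2, "of1")
  expect_true(is_infeasible(res))
})

test_that("solutions satisfy every constraint on randomized small networks", {
  for (s in c(2, 8)) {
    gen <- make_small_network(seed = s)
    for (obj in c("of1", "of2")) {
      sol <- build_and_solve(gen$instance, obj)
      expect_false(is_infeasible(sol))
      expect_equal(nrow(verify_solution(gen$instance, sol)), 0)
      expect_true(all(sol$Y == round(sol$Y)))
      expect_true(all(sol$C == round(sol$C)))
      expect_true(all(sol$X %in% c(0, 1)))
    }
  }
})

test_that("raising the risk of a served node cannot lower the pure-risk optimum", {
  ti <- random_tiny_instance(4)$instance
  ti$delta <- 1
  base <- build_and_solve(ti, "of1")
  ti2 <- ti
  ti2$R[1, 1] <- min(1, ti2$R[1, 1] + 0.3)
  up <- build_and_solve(ti2, "of1")
  expect_gte(up$of1, base$of1 - 1e-9)
})

test_that("brute force refuses instances beyond its guard", {
  gen <- make_small_network(seed = 1, n_nodes = 6)
  expect_error(brute_force_solve(gen$instance), "guard")
})
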