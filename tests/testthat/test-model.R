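test_that("variable accounting follows the Y + C + X structure", {
  expect_equal(count_variables(23, 23, 2), c(total = 1127L, binary = 23L))
  expect_equal(count_variables(1, 1, 1), c(total = 3L, binary = 1L))
  expect_equal(count_variables(2, 3, 2), c(total = 21L, binary = 3L))
})

test_that("built model matches the formula counts and flags all-integer", {
  inst <- make_micro_instance()
  m <- build_model(inst)
  cv <- count_variables(2, 2, 1)
  expect_equal(m$n_var, unname(cv["total"]))
  expect_equal(sum(m$vartype == "X"), unname(cv["binary"]))
  expect_true(all(m$integrality == 1))
  expect_equal(sum(m$vartype == "Y"), 4)
  expect_equal(sum(m$vartype == "C"), 2)
})

test_that("default big-M is the total demand", {
  inst <- make_micro_instance(D = matrix(c(3, 2, 1, 4), 2, 2),
                              R = matrix(0.5, 2, 2),
                              sigma = matrix(0.1, 2, 2),
                              hourly_cost = c(2, 2), L = c(1, 1))
  expect_equal(default_big_m(inst), 10)
  z <- make_micro_instance(D = matrix(c(0, 0), 2, 1))
  expect_equal(default_big_m(z), 0)
})

test_that("objective evaluation reproduces hand arithmetic", {
  # single flow: Y=1, R=0.5, d=10, D_Max=20, delta=0.7
  dm <- distance_matrix(matrix(c(0, 20, 10, 0), 2, 2), c("A", "B"))
  inst <- problem_instance(
    nodes = c("A", "B"), R = matrix(c(0.5, 0), 2, 1),
    sigma = matrix(c(0.2, 0), 2, 1), D = matrix(c(1, 0), 2, 1),
    dm = dm, budget = 10, hourly_cost = 1, hours_per_patient = 1,
    r_min = 1, delta = 0.7, pi_weight = 0.5
  )
  Y <- array(0, c(2, 2, 1)); Y[1, 2, 1] <- 1  # d(A,B) = 10, D_Max = 20
  expect_equal(evaluate_of1(inst, Y), 0.7 * 0.5 + 0.3 * (-0.5))
  expect_equal(evaluate_of2(inst, Y), 0.5 * 0.2 + 0.5 * (-0.5))
  expect_equal(evaluate_of1(inst, Y * 0), 0)
  inst$delta <- 1
  expect_equal(evaluate_of1(inst, Y), 0.5)
})

test_that("verify_solution flags each violated constraint family by name", {
  inst <- make_micro_instance(phi = 1)
  # a legitimate solution: both sites open, everyone served locally
  Y <- array(0, c(2, 2, 1)); Y[1, 1, 1] <- 2; Y[2, 2, 1] <- 2
  C <- matrix(c(2, 2), 2, 1); X <- c(1, 1)
  expect_equal(nrow(verify_solution(inst, list(Y = Y, C = C, X = X))), 0)

  # demand exceeded
  Y2 <- Y; Y2[1, 1, 1] <- 5
  v <- verify_solution(inst, list(Y = Y2, C = matrix(c(5, 2), 2, 1), X = X))
  expect_true("demand" %in% v$constraint)
  expect_match(v$where[v$constraint == "demand"], "A")

  # capacity at a closed site
  v <- verify_solution(inst, list(Y = Y * 0, C = matrix(c(3, 0), 2, 1),
                                  X = c(0, 0)))
  expect_true("capacity-without-opening" %in% v$constraint)

  # minimum service unmet
  v <- verify_solution(inst, list(Y = Y * 0, C = C * 0, X = c(0, 0)))
  expect_true("min_service" %in% v$constraint)

  # budget blown
  giant <- matrix(c(1000, 0), 2, 1)
  v <- verify_solution(inst, list(Y = Y * 0, C = giant, X = c(1, 0)))
  expect_true("budget" %in% v$constraint)
})

test_that("instance constructor rejects inconsistent inputs", {
  dm <- distance_matrix(matrix(c(0, 1, 1, 0), 2, 2), c("A", "B"))
  expect_error(problem_instance(
    nodes = c("A", "B"), R = matrix(0.5, 3, 1), sigma = matrix(0.1, 2, 1),
    D = matrix(1, 2, 1), dm = dm, budget = 1, hourly_cost = 1,
    hours_per_patient = 1), "R must be")
  expect_error(problem_instance(
    nodes = c("A", "C"), R = matrix(0.5, 2, 1), sigma = matrix(0.1, 2, 1),
    D = matrix(1, 2, 1), dm = dm, budget = 1, hourly_cost = 1,
    hours_per_patient = 1), "does not cover")
  expect_error(problem_instance(
    nodes = c("A", "B"), R = matrix(0.5, 2, 1), sigma = matrix(0.1, 2, 1),
    D = matrix(1.5, 2, 1), dm = dm, budget = 1, hourly_cost = 1,
    hours_per_patient = 1), "integer")
})
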