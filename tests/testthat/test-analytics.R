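test_that("coverage percentages follow the within-radius served share", {
  # 2 nodes, site B at 30 km from A; all service from B
  dm <- distance_matrix(matrix(c(0, 30, 30, 0), 2, 2), c("A", "B"))
  inst <- problem_instance(
    nodes = c("A", "B"), R = matrix(0.5, 2, 1), sigma = matrix(0.1, 2, 1),
    D = matrix(c(10, 5), 2, 1), dm = dm, budget = 100, hourly_cost = 1,
    hours_per_patient = 1, r_min = 1
  )
  Y <- array(0, c(2, 2, 1)); Y[1, 2, 1] <- 6; Y[2, 2, 1] <- 5
  sol <- solution_allocation(inst, Y, C = matrix(c(0, 11), 2, 1),
                             X = c(0, 1))
  cov <- coverage_report(inst, sol, radius_km = 40)
  expect_equal(cov$per_node[[2]], c(60, 100))  # 6/10 within 30 km; 5/5 local
  # centers beyond the radius contribute nothing
  cov20 <- coverage_report(inst, sol, radius_km = 20)
  expect_equal(cov20$per_node[[2]], c(0, 100))
  expect_true(all(cov$per_node[[2]] >= 0 & cov$per_node[[2]] <= 100))
})

test_that("overall coverage is the mean of the per-intervention averages", {
  gen <- make_small_network(seed = 5)
  sol <- build_and_solve(gen$instance, "of1")
  cov <- coverage_report(gen$instance, sol)
  expect_equal(cov$overall, mean(cov$averages))
  expect_true(all(unlist(cov$per_node[-1]) >= 0 - 1e-9))
  expect_true(all(unlist(cov$per_node[-1]) <= 100 + 1e-9))
  # the published worked example: averages 14.05 and 35.29 give 24.67
  expect_equal(round(mean(c(14.05, 35.29)), 2), 24.67)
})

test_that("capacity report computes utilisation and omits closed sites", {
  dm <- distance_matrix(matrix(c(0, 5, 5, 0), 2, 2), c("A", "B"))
  inst <- problem_instance(
    nodes = c("A", "B"), R = matrix(0.5, 2, 2), sigma = matrix(0.1, 2, 2),
    D = matrix(c(400, 0, 80, 0), 2, 2), dm = dm,
    budget = c(1e4, 1e4), hourly_cost = c(1, 1),
    hours_per_patient = c(0.05, 1), r_min = 1
  )
  Y <- array(0, c(2, 2, 2))
  Y[1, 1, 1] <- 400  # 400 prevention patients -> 20 h
  Y[1, 1, 2] <- 80   # 80 mitigation patients -> 80 h
  sol <- solution_allocation(inst, Y, C = matrix(c(100, 0, 100, 0), 2, 2),
                             X = c(1, 0))
  rep <- capacity_report(inst, sol)
  expect_equal(nrow(rep), 2)  # closed site absent
  prev <- rep[rep$intervention == "prevention", ]
  mit <- rep[rep$intervention == "mitigation", ]
  expect_equal(prev$professional_hours, 20)
  expect_equal(prev$utilization, 0.2)
  expect_equal(mit$utilization, 0.8)
})

test_that("scenario projection reproduces the printed expansion arithmetic", {
  # one extra center replicating the per-center share
  expect_equal(scenario_projection(24.67, 1, 1.0)$headline_pct, 37)
  # +50% capacity on existing centers
  expect_equal(scenario_projection(24.67, 0, 1.5)$headline_pct, 37)
  # identity when nothing changes
  expect_equal(scenario_projection(24.67, 0, 1.0)$projected_pct, 24.67)
  expect_equal(scenario_projection(10, 0, 1)$projected_pct, 10)
})

test_that("epsilon variation takes the max consecutive relative change", {
  fr <- data.frame(epsilon = 1:3, of1 = c(100, 120, 121))
  expect_equal(epsilon_variation(fr), 20)
  expect_equal(epsilon_variation(data.frame(epsilon = 1:2, of1 = c(50, 40))), 20)
  expect_equal(epsilon_variation(data.frame(epsilon = 1:3, of1 = rep(7, 3))), 0)
  # invariant under uniform positive scaling of OF1
  expect_equal(epsilon_variation(data.frame(epsilon = 1:3, of1 = c(100, 120, 121) * 55)),
               20)
  expect_error(epsilon_variation(data.frame(epsilon = 1, of1 = 5)),
               "at least two")
})

test_that("workforce constants derive from daily schedules and salaries", {
  expect_equal(annual_hours(8, 260), 2080)
  expect_equal(annual_hours(1, 1), 1)
  expect_equal(annual_hours(8, 130), 1040)
  expect_equal(hourly_cost(6.1e6), 38125)
  expect_equal(hourly_cost(1.8e6), 11250)
  expect_equal(hourly_cost(160), 1)
})

test_that("weight sweep emits one row per weight and variant within bounds", {
  gen <- make_small_network(seed = 5)
  sw <- weight_sweep(gen$instance, values = c(0.2, 0.8),
                     variants = c("of1", "of2"))
  expect_equal(nrow(sw), 4)
  ok <- sw$status != "infeasible"
  expect_true(all(sw$coverage_pct[ok] >= 0 & sw$coverage_pct[ok] <= 100))
  # delta = 1 removes the distance term: OF1 equals the pure risk value
  inst <- gen$instance; inst$delta <- 1
  sol <- build_and_solve(inst, "of1")
  risk_only <- sum(inst$R * apply(sol$Y, c(1, 3), sum))
  expect_equal(sol$of1, risk_only, tolerance = 1e-9)
})
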