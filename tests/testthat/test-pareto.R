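test_that("non-dominated filtering drops dominated and duplicate points", {
  pts <- data.frame(of1 = c(1, 3, 2, 5), of2 = c(5, 3, 2, 1))
  kept <- filter_nondominated(pts)
  expect_equal(kept$of1, c(1, 3, 5))  # (2,2) dominated by (3,3)
  expect_equal(filter_nondominated(pts[1, ])$of1, 1)
  dup <- data.frame(of1 = c(2, 2, 2), of2 = c(2, 2, 2))
  expect_equal(nrow(filter_nondominated(dup)), 1)
})

test_that("knee selection picks the balanced point and is scale invariant", {
  of1 <- c(0, 5, 10); of2 <- c(10, 5, 0)
  expect_equal(select_knee(of1, of2, c(10, 10)), 2L)
  # rescaling one objective by 1000 cannot change the standardized choice
  expect_equal(select_knee(of1 * 1000, of2, c(10000, 10)), 2L)
  # affine shifts do not change it either
  expect_equal(select_knee(of1 * 3 + 7, of2, c(37, 10)), 2L)
  # single point
  expect_equal(select_knee(4, 4, c(9, 9)), 1L)
  # zero-variance coordinate contributes nothing
  expect_equal(select_knee(c(1, 1, 1), c(0, 5, 10), c(1, 10)), 3L)
})

test_that("knee selection matches a direct standardized-distance computation", {
  set.seed(77)
  for (rep in 1:8) {
    n <- sample(3:8, 1)
    of1 <- sort(runif(n, 0, 100), decreasing = TRUE)
    of2 <- sort(runif(n, -50, 50))
    ideal <- c(max(of1), max(of2))
    zs <- function(v) (v - mean(v)) / sqrt(mean((v - mean(v))^2))
    z1 <- zs(of1); z2 <- zs(of2)
    zi1 <- (ideal[1] - mean(of1)) / sqrt(mean((of1 - mean(of1))^2))
    zi2 <- (ideal[2] - mean(of2)) / sqrt(mean((of2 - mean(of2))^2))
    expected <- which.min((z1 - zi1)^2 + (z2 - zi2)^2)
    expect_equal(select_knee(of1, of2, ideal), expected)
  }
})

test_that("tiny epsilon sweep matches the enumeration oracle pointwise", {
  found_conflict <- FALSE
  for (s in c(6, 9, 13)) {
    ti <- random_tiny_instance(s)$instance
    b1 <- brute_force_solve(ti, "of1")
    b2 <- brute_force_solve(ti, "of2")
    if (is_infeasible(b1) || is_infeasible(b2)) next
    fr <- epsilon_sweep(ti, n_points = 5)
    # ideal matches two independent enumerations
    expect_equal(unname(fr$ideal["of1"]), b1$of1, tolerance = 1e-9)
    expect_equal(unname(fr$ideal["of2"]), b2$of2, tolerance = 1e-9)
    # each frontier point attains the oracle's constrained optimum
    for (r in seq_len(nrow(fr$points))) {
      bo <- brute_force_solve(ti, "of1", of2_floor = fr$points$epsilon[r])
      expect_equal(fr$points$of1[r], bo$of1, tolerance = 1e-9)
    }
    # frontier structure
    expect_true(all(diff(fr$points$of1) <= 1e-9))
    expect_true(all(fr$ideal["of1"] >= fr$points$of1 - 1e-9))
    expect_true(all(fr$ideal["of2"] >= fr$points$of2 - 1e-9))
    if (b1$of2 < b2$of2 - 1e-9) found_conflict <- TRUE
  }
  expect_true(found_conflict)  # at least one seed exercises a real trade-off
})

test_that("two-point sweep returns the trade-off endpoints", {
  ti <- random_tiny_instance(3)$instance
  fr <- epsilon_sweep(ti, n_points = 2)
  expect_lte(nrow(fr$points), 2)
  expect_equal(max(fr$points$of1), unname(fr$ideal["of1"]), tolerance = 1e-9)
})
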