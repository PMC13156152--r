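test_that("share components normalise to 1 and handle degenerate totals", {
  p <- make_profiles(consumers = c(10, 30, 60),
                     posts_negative = c(3, 1, 0),
                     crime = c(1, 1, 2))
  expect_equal(compute_alpha(p), c(0.1, 0.3, 0.6))
  expect_equal(compute_psi(p), c(0.75, 0.25, 0))
  expect_equal(compute_gamma(p), c(0.25, 0.25, 0.5))

  # all-zero totals give all-zero shares, not an error
  p0 <- make_profiles(consumers = c(0, 0, 0),
                      posts_negative = c(0, 0, 0),
                      crime = c(0, 0, 0))
  expect_equal(compute_alpha(p0), c(0, 0, 0))
  expect_equal(compute_psi(p0), c(0, 0, 0))
  expect_equal(compute_gamma(p0), c(0, 0, 0))

  # single node carries the whole share
  p1 <- make_profiles(consumers = 5, posts_negative = 7, crime = 9,
                      mpi = 0.3, rurality = 0.3,
                      population = 100, d_prev = 1, d_mit = 1)
  expect_equal(compute_alpha(p1), 1)
  expect_equal(compute_psi(p1), 1)
  expect_equal(compute_gamma(p1), 1)

  expect_error(compute_alpha(data.frame()), "at least one row")
})

test_that("risk index is the component mean and mitigation is half of it", {
  r <- compute_risk(c(0.2, 0, 1), c(0.4, 0, 1), c(0.6, 0, 1))
  expect_equal(r$prevention, c(0.4, 0, 1))
  expect_equal(r$mitigation, r$prevention / 2)
  expect_error(compute_risk(c(0.1), c(0.1, 0.2), c(0.1)), "equal length")
  expect_error(compute_risk(1.2, 0.5, 0.5), "\\[0, 1\\]")
})

test_that("equity index multiplies poverty and rurality, halved for mitigation", {
  e <- compute_equity(mpi = c(0.4, 0.5, 1), rurality = c(0.5, 0, 1))
  expect_equal(e$prevention, c(0.2, 0, 1))
  expect_equal(e$mitigation, c(0.1, 0, 0.5))
})

test_that("index table satisfies the normalisation and bound invariants", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(2:8, 1)
    p <- make_profiles(
      consumers = sample(0:50, n, replace = TRUE),
      posts_negative = sample(0:20, n, replace = TRUE),
      crime = sample(0:30, n, replace = TRUE),
      mpi = runif(n), rurality = runif(n),
      population = sample(100:1000, n),
      d_prev = sample(1:5, n, replace = TRUE),
      d_mit = sample(1:9, n, replace = TRUE)
    )
    idx <- compute_indices(p)
    for (col in c("alpha", "psi", "gamma")) {
      s <- sum(idx[[col]])
      expect_true(abs(s - 1) < 1e-12 || s == 0)
    }
    expect_true(all(idx$R1 >= 0 & idx$R1 <= 1))
    expect_equal(idx$R2, idx$R1 / 2)
    expect_equal(idx$sigma2, idx$sigma1 / 2)
    expect_true(all(idx$sigma1 <= pmin(p$mpi, p$rurality) + 1e-12))
  }
})

test_that("risk is monotone in each share component", {
  base <- compute_risk(0.2, 0.3, 0.1)$prevention
  expect_gt(compute_risk(0.3, 0.3, 0.1)$prevention, base)
  expect_gt(compute_risk(0.2, 0.4, 0.1)$prevention, base)
  expect_gt(compute_risk(0.2, 0.3, 0.2)$prevention, base)
})

test_that("profile and index CSV round-trips preserve values", {
  p <- make_profiles()
  f <- tempfile(fileext = ".csv")
  write_profiles_csv(p, f)
  p2 <- read_profiles_csv(f)
  expect_equal(as.data.frame(p2), as.data.frame(p))
  idx <- compute_indices(p)
  f2 <- tempfile(fileext = ".csv")
  write_indices_csv(idx, f2)
  expect_equal(read.csv(f2, stringsAsFactors = FALSE)$alpha, idx$alpha)
  unlink(c(f, f2))
})

test_that("profile validation rejects malformed tables", {
  df <- as.data.frame(make_profiles())
  bad <- df; bad$mpi[1] <- 1.5
  expect_error(municipality_profiles(bad), "mpi")
  bad <- df; bad$consumers[2] <- -1
  expect_error(municipality_profiles(bad), "consumers")
  bad <- df; bad$node_id[2] <- bad$node_id[1]
  expect_error(municipality_profiles(bad), "duplicate")
  bad <- df[, -3]
  expect_error(municipality_profiles(bad), "missing columns")
})
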