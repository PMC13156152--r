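test_that("haversine matrix reproduces the closed-form one-degree arc", {
  p <- make_profiles()
  p$latitude <- c(0, 0, 10)
  p$longitude <- c(0, 1, 10)
  dm <- haversine_matrix(p)
  # 1 degree of longitude at the equator with R = 6371 km
  expect_equal(dm$d[1, 2], 2 * pi * 6371 / 360, tolerance = 1e-6)
  # independent spherical-law-of-cosines check
  slc <- 6371 * acos(pmin(1, cos(0) * cos(0) * cos(pi / 180)))
  expect_equal(dm$d[1, 2], slc, tolerance = 1e-6)
  expect_true(isSymmetric(unname(dm$d)))
  expect_equal(unname(diag(dm$d)), rep(0, 3))
  expect_equal(dm$d_max, max(dm$d))
})

test_that("distance CSV round-trips in square form and validates long form", {
  p <- make_profiles()
  dm <- haversine_matrix(p)
  f <- tempfile(fileext = ".csv")
  write_distance_csv(dm, f)
  dm2 <- load_distance_csv(f)
  expect_equal(dm2$d, dm$d, tolerance = 1e-9)
  expect_equal(dm2$d_max, dm$d_max, tolerance = 1e-9)
  unlink(f)

  # long form, complete
  long <- expand.grid(origin = dm$node_ids, destination = dm$node_ids,
                      stringsAsFactors = FALSE)
  long$km <- dm$d[cbind(long$origin, long$destination)]
  f <- tempfile(fileext = ".csv")
  write.csv(long, f, row.names = FALSE)
  dm3 <- load_distance_csv(f, node_ids = dm$node_ids)
  expect_equal(dm3$d, dm$d, tolerance = 1e-9)

  # missing pair named in the error
  write.csv(long[-2, ], f, row.names = FALSE)
  expect_error(load_distance_csv(f, node_ids = dm$node_ids),
               "missing pair \\(N2, N1\\)")

  # negative distance named
  long2 <- long; long2$km[2] <- -5
  write.csv(long2, f, row.names = FALSE)
  expect_error(load_distance_csv(f), "negative distance")
  unlink(f)
})

test_that("radius mask uses an inclusive threshold and is monotone in radius", {
  d <- matrix(c(0, 39.9, 40.0, 39.9, 0, 40.1, 40.0, 40.1, 0), 3, 3)
  dm <- distance_matrix(d, c("A", "B", "C"))
  m <- within_radius(dm, 40)
  expect_true(m["A", "B"])   # 39.9
  expect_true(m["A", "C"])   # exactly 40
  expect_false(m["B", "C"])  # 40.1
  # monotone: smaller radius mask is a subset
  m30 <- within_radius(dm, 30)
  expect_true(all(!m30 | m))
  expect_error(within_radius(dm, -1), "positive")
})

test_that("normalised distances lie in the unit interval", {
  set.seed(99)
  p <- make_profiles(consumers = sample(1:9, 5, replace = TRUE),
                     posts_negative = sample(0:5, 5, replace = TRUE),
                     crime = sample(0:5, 5, replace = TRUE),
                     mpi = runif(5), rurality = runif(5),
                     population = sample(100:900, 5),
                     d_prev = rep(1, 5), d_mit = rep(2, 5))
  p$latitude <- runif(5, 10, 11); p$longitude <- runif(5, -75, -74)
  dm <- haversine_matrix(p)
  expect_true(all(dm$d / dm$d_max >= 0 & dm$d / dm$d_max <= 1))
})
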