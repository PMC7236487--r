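test_that("cohort CSV round trip preserves content", {
  x <- toy_cohort()
  op <- withr::local_tempfile(fileext = ".csv")
  ep <- withr::local_tempfile(fileext = ".csv")
  write_cohort(x, op, ep)
  y <- read_long_cohort(op, ep)
  expect_equal(y$observations, x$observations, ignore_attr = TRUE)
  expect_equal(y$patients$entry_age, x$patients$entry_age)
  expect_equal(y$patients$mrsa_age, x$patients$mrsa_age)
  expect_identical(attr(y, "dropped"), 0L)
})

test_that("reader drops rows outside the eligibility window with a count", {
  x <- toy_cohort()
  bad <- data.frame(patient_id = "A", age = 4.0, outcome = "FEV1", value = 90)
  op <- withr::local_tempfile(fileext = ".csv")
  ep <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(rbind(x$observations, bad), op, row.names = FALSE, na = "")
  utils::write.csv(x$patients, ep, row.names = FALSE, na = "")
  y <- read_long_cohort(op, ep, window = c(6, 20))
  expect_identical(attr(y, "dropped"), 1L)
  expect_equal(nrow(y$observations), nrow(x$observations))
})

test_that("structural problems are errors naming the offender", {
  x <- toy_cohort()
  pat <- x$patients
  pat$entry_age[1] <- 13  # > exit would be 12
  expect_error(cohort_data(x$observations, pat), "entry_age.*A")
  obs <- x$observations
  obs$patient_id[1] <- "ZZ"
  expect_error(cohort_data(obs, x$patients), "unknown patient")
  op <- withr::local_tempfile(fileext = ".csv")
  ep <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(x$observations[, -1], op, row.names = FALSE)
  utils::write.csv(x$patients, ep, row.names = FALSE)
  expect_error(read_long_cohort(op, ep), "missing required column")
  expect_error(cohort_data(within(x$observations, value[2] <- 120), x$patients),
               "percentile")
})

test_that("natural spline basis has df columns and linear tails", {
  ages <- seq(6, 20, by = 0.5)
  for (df in c(1, 2, 3, 5)) {
    B <- build_spline_basis(ages, spline_basis_spec(df))
    expect_identical(ncol(B), as.integer(df))
  }
  ## beyond the upper boundary knot every column must be exactly linear:
  ## second differences of three collinear points vanish
  sp <- spline_basis_spec(3, boundary_knots = c(6, 20))
  sp <- cfjoint:::resolve_spline_spec(sp, ages)
  B <- build_spline_basis(c(21, 23, 25), sp)
  expect_lt(max(abs(B[1, ] - 2 * B[2, ] + B[3, ])), 1e-10)
  Blo <- build_spline_basis(c(1, 3, 5), sp)
  expect_lt(max(abs(Blo[1, ] - 2 * Blo[2, ] + Blo[3, ])), 1e-10)
  expect_error(spline_basis_spec(0), "at least 1|>= 1")
  expect_error(build_spline_basis(c(6, 20), spline_basis_spec(4)), "distinct ages")
})

test_that("spline basis spans the natural cubic splines on its knots", {
  ages <- seq(6, 20, length.out = 200)
  ik <- c(10, 13, 16)
  sp <- spline_basis_spec(4, boundary_knots = c(6, 20), interior_knots = ik)
  B <- cbind(1, build_spline_basis(ages, sp))
  ## independent construction of a natural cubic spline on the same knots
  set.seed(4)
  target <- drop(splines::ns(ages, knots = ik, Boundary.knots = c(6, 20),
                             intercept = TRUE) %*% rnorm(5))
  fit <- stats::lm.fit(B, target)
  expect_lt(max(abs(fit$residuals)), 1e-9)
})

test_that("encounter counts use the closed prior-year window", {
  expect_identical(encounters_in_prior_year(c(8.0, 8.4, 8.9), 9.0), 3L)
  expect_identical(encounters_in_prior_year(8.0, 9.5), 0L)
  expect_identical(encounters_in_prior_year(numeric(0), 10), 0L)
  ## both endpoints count: one year ago today and today itself
  expect_identical(encounters_in_prior_year(c(8, 9), 9), 2L)
  set.seed(11)
  ages <- runif(100, 6, 20)
  for (t in c(7.3, 12, 19.9)) {
    brute <- sum(ages >= t - 1 & ages <= t)
    expect_identical(encounters_in_prior_year(ages, t), brute)
  }
})

test_that("shard splitting is an event-balanced patient partition", {
  s <- small_sim()
  cohort <- s$sim$cohort
  expect_identical(split_into_shards(cohort, 1)[[1]]$patients, cohort$patients)

  ## exact arithmetic case: 300 patients, 90 events, 3 shards
  pat <- data.frame(patient_id = sprintf("S%03d", 1:300),
                    entry_age = 6, exit_age = 10,
                    event = rep(c(1L, 0L), c(90, 210)))
  obs <- data.frame(patient_id = pat$patient_id, age = 6,
                    outcome = "FEV1", value = 90)
  big <- cohort_data(obs, pat)
  sh <- split_into_shards(big, 3, seed = 5)
  expect_equal(vapply(sh, function(x) nrow(x$patients), 0), rep(100, 3))
  expect_equal(vapply(sh, function(x) sum(x$patients$event), 0), rep(30, 3))
  ids <- sort(unlist(lapply(sh, function(x) x$patients$patient_id)))
  expect_identical(ids, sort(pat$patient_id))

  ## three-way split of a realistic cohort: event fractions within 1 point
  sh2 <- split_into_shards(cohort, 3, seed = 9)
  fr <- vapply(sh2, function(x) mean(x$patients$event), 0)
  expect_lt(max(fr) - min(fr), 0.011)
  ## determinism
  sh3 <- split_into_shards(cohort, 3, seed = 9)
  expect_identical(lapply(sh2, function(x) x$patients$patient_id),
                   lapply(sh3, function(x) x$patients$patient_id))
  expect_error(split_into_shards(cohort, 1e6), "exceeds")
})
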