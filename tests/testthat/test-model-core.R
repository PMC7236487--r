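test_that("parameter packing is a bijection", {
  s <- small_sim()
  model <- s$model
  set.seed(8)
  params <- cfjoint:::param_template(model)
  for (k in model$outcomes) params$beta[[k]][] <- rnorm(length(params$beta[[k]]))
  params$sigma[] <- runif(2, 0.5, 5)
  A <- matrix(rnorm(16), 4)
  params$Sigma <- crossprod(A) + diag(4)
  params$a[] <- rnorm(2, 0, 0.05)
  params$theta[] <- rnorm(5)
  flat <- params_pack(params, model)
  back <- params_unpack(flat, model)
  expect_equal(back$beta, params$beta, tolerance = 1e-12)
  expect_equal(back$Sigma, params$Sigma, tolerance = 1e-10)
  expect_equal(back$a, params$a, tolerance = 1e-12)
  expect_equal(params_pack(back, model), flat, tolerance = 1e-10)
})

test_that("longitudinal mean is the advertised linear predictor", {
  tp <- toy_model_params()
  model <- tp$model; params <- tp$params
  p1 <- tp$cohort$patients[1, ]
  ## zero case
  p0 <- params
  for (k in model$outcomes) p0$beta[[k]][] <- 0
  expect_equal(longitudinal_mean(model, p0, rep(0, 4), c(8, 12), p1), c(0, 0))
  ## a random intercept shifts the mean by exactly that amount everywhere
  b <- c(3.7, 0, 0, 0)
  base <- longitudinal_mean(model, params, rep(0, 4), c(7, 10, 15), p1)
  expect_equal(longitudinal_mean(model, params, b, c(7, 10, 15), p1), base + 3.7)
  ## brute-force dot product oracle
  set.seed(9)
  bb <- rnorm(4)
  t <- 11.3
  sp <- model$submodels$FEV1$age_basis
  x <- c(1, build_spline_basis(t, sp))
  manual <- sum(x * params$beta$FEV1) + bb[1] + bb[2] * (t - 6)
  expect_equal(longitudinal_mean(model, params, bb, t, p1), manual, tolerance = 1e-12)
})

test_that("hazard follows the proportional-hazards form with current-value association", {
  tp <- toy_model_params(a = c(FEV1 = -0.0305, BMIp = 0))
  model <- tp$model; params <- tp$params
  p1 <- tp$cohort$patients[1, ]
  ## null association: hazard equals the baseline for every patient
  null <- params; null$a[] <- 0
  h0 <- exp(drop(cfjoint:::baseline_design(model, 12) %*% params$theta))
  expect_equal(hazard(model, null, rnorm(4), 12, p1), h0, tolerance = 1e-12)
  ## raising the biomarker by one unit multiplies the hazard by exp(a1)
  b <- c(0, 0, 0, 0); b_up <- c(1, 0, 0, 0)
  hr <- hazard(model, params, b_up, 12, p1) / hazard(model, params, b, 12, p1)
  expect_equal(hr, exp(-0.0305), tolerance = 1e-12)
  ## term-by-term oracle for the log hazard
  set.seed(10)
  bb <- rnorm(4)
  t <- 13.7
  lh <- log(hazard(model, params, bb, t, p1))
  manual <- drop(cfjoint:::baseline_design(model, t) %*% params$theta)
  for (k in model$outcomes)
    manual <- manual + params$a[[k]] *
      (longitudinal_mean(model, params, bb, t, p1, outcome = k) - model$centering[[k]])
  expect_equal(lh, manual, tolerance = 1e-10)
  ## log hazard is linear in each biomarker with slope a_k (finite differences)
  for (d in c(0.5, 1, 2)) {
    bd <- b; bd[1] <- d
    expect_equal(log(hazard(model, params, bd, 12, p1)) - log(hazard(model, params, b, 12, p1)),
                 -0.0305 * d, tolerance = 1e-10)
  }
})

test_that("cumulative hazard integrates exactly and additively", {
  tp <- toy_model_params()
  model <- tp$model
  p1 <- tp$cohort$patients[1, ]
  ## constant hazard: only the log-baseline intercept is active
  cpar <- tp$params
  cpar$a[] <- 0; cpar$theta[] <- c(log(0.4), 0, 0, 0, 0)
  expect_equal(cumulative_hazard(model, cpar, rep(0, 4), 7, 13, p1), 0.4 * 6,
               tolerance = 1e-12)
  expect_equal(survival_probability(model, cpar, rep(0, 4), 8, 13, p1),
               exp(-0.4 * 5), tolerance = 1e-12)
  ## time-varying case against a dense trapezoid oracle
  params <- tp$params
  set.seed(12)
  bb <- rnorm(4)
  tt <- seq(7, 15, length.out = 1e5)
  hh <- hazard(model, params, bb, tt, p1)
  trap <- sum((hh[-1] + hh[-length(hh)]) / 2) * diff(tt[1:2])
  quad <- cumulative_hazard(model, params, bb, 7, 15, p1)
  expect_lt(abs(quad - trap) / trap, 1e-6)
  ## additivity and multiplicativity
  expect_equal(cumulative_hazard(model, params, bb, 7, 11, p1) +
                 cumulative_hazard(model, params, bb, 11, 15, p1),
               quad, tolerance = 1e-10)
  expect_equal(survival_probability(model, params, bb, 7, 11, p1) *
                 survival_probability(model, params, bb, 11, 15, p1),
               survival_probability(model, params, bb, 7, 15, p1),
               tolerance = 1e-10)
  expect_identical(survival_probability(model, params, bb, 9, 9, p1), 1)
  expect_error(cumulative_hazard(model, params, bb, 9, 8, p1), "exceed")
})

test_that("complete-data log-likelihood assembles the three advertised pieces", {
  tp <- toy_model_params()
  model <- tp$model; params <- tp$params
  cohort <- tp$cohort
  small <- cfjoint:::subset_cohort(cohort, cohort$patients$patient_id[1:6])
  jd <- prepare_jm_data(model, small)
  set.seed(14)
  b <- matrix(rnorm(6 * 4, sd = 0.5), 6, 4)

  ## factorization at null association: longitudinal + survival + prior,
  ## each computed independently of the likelihood code path
  null <- params; null$a[] <- 0
  ll <- complete_data_log_likelihood(model, null, b, jd)
  long_manual <- 0
  for (i in 1:6) {
    pid <- small$patients$patient_id[i]
    for (k in model$outcomes) {
      o <- small$observations[small$observations$patient_id == pid &
                                small$observations$outcome == k, ]
      off <- if (k == "FEV1") 0 else 2
      m <- longitudinal_mean(model, null, c(rep(0, off), b[i, off + 1:2], rep(0, 2 - off)),
                             o$age, small$patients[i, ], outcome = k)
      long_manual <- long_manual + sum(dnorm(o$value, m, null$sigma[[k]], log = TRUE))
    }
  }
  surv_manual <- 0
  for (i in 1:6) {
    prow <- small$patients[i, ]
    surv_manual <- surv_manual +
      prow$event * log(hazard(model, null, b[i, ], prow$exit_age, prow)) -
      cumulative_hazard(model, null, b[i, ], prow$entry_age, prow$exit_age, prow)
  }
  Sinv <- solve(null$Sigma)
  prior_manual <- sum(vapply(1:6, function(i)
    as.numeric(-0.5 * drop(b[i, ] %*% Sinv %*% b[i, ]) -
      0.5 * (4 * log(2 * pi) + determinant(null$Sigma)$modulus)), 0))
  expect_equal(ll, long_manual + surv_manual + prior_manual, tolerance = 1e-8)

  ## duplicating every patient doubles the log-likelihood
  dbl_pat <- small$patients
  dbl_pat$patient_id <- paste0(dbl_pat$patient_id, "x")
  dbl_obs <- small$observations
  dbl_obs$patient_id <- paste0(dbl_obs$patient_id, "x")
  doubled <- cohort_data(rbind(small$observations, dbl_obs),
                         rbind(small$patients, dbl_pat), validate = FALSE)
  ll2 <- complete_data_log_likelihood(model, null, rbind(b, b), prepare_jm_data(model, doubled))
  expect_equal(ll2, 2 * ll, tolerance = 1e-8)

  bad <- params; bad$Sigma <- matrix(c(1, 2, 2, 1), 2) %x% diag(2)
  expect_error(complete_data_log_likelihood(model, bad, b, jd), "positive definite")
})

test_that("marginal likelihood matches the closed-form Gaussian integral", {
  ## one outcome, intercept-only random effect, association and hazard off:
  ## the marginal longitudinal density is multivariate normal with
  ## covariance Z Sigma Z' + sigma^2 I, and the survival factor is a known
  ## constant that b does not enter
  cfg <- cf_registry_config(n_patients = 8, a = c(FEV1 = 0, BMIp = 0), seed = 17)
  sim <- simulate_cohort(cfg)
  sub <- longitudinal_submodel("FEV1", df = 2, random = "intercept")
  model <- joint_model_spec(sub, baseline_df = 5)
  model <- prepare_model(model, sim$cohort)
  jd <- prepare_jm_data(model, sim$cohort)
  params <- cfjoint:::param_template(model)
  params$beta$FEV1[] <- c(90, -10, -15)
  params$sigma[] <- 6
  params$Sigma <- matrix(12^2, 1, 1)
  params$a[] <- 0
  params$theta[] <- c(log(0.05), 0, 0, 0, 0)
  got <- marginal_log_likelihood(model, params, jd, control = list(order = 9))
  manual <- 0
  for (i in seq_len(jd$n)) {
    pid <- jd$pid[i]
    o <- sim$cohort$observations
    o <- o[o$patient_id == pid & o$outcome == "FEV1", ]
    X <- cbind(1, build_spline_basis(o$age, model$submodels$FEV1$age_basis))
    mu <- drop(X %*% params$beta$FEV1)
    V <- matrix(12^2, nrow(o), nrow(o)) + diag(6^2, nrow(o))
    r <- o$value - mu
    manual <- manual - 0.5 * (nrow(o) * log(2 * pi) +
                                determinant(V)$modulus + drop(r %*% solve(V) %*% r))
    pi_ <- sim$cohort$patients[match(pid, sim$cohort$patients$patient_id), ]
    manual <- manual + pi_$event * log(0.05) - 0.05 * (pi_$exit_age - pi_$entry_age)
  }
  expect_equal(got, as.numeric(manual), tolerance = 1e-6)
})

test_that("quadrature order refinement is converged", {
  tp <- toy_model_params()
  small <- cfjoint:::subset_cohort(tp$cohort, tp$cohort$patients$patient_id[1:3])
  jd <- prepare_jm_data(tp$model, small)
  m5 <- marginal_log_likelihood(tp$model, tp$params, jd, control = list(order = 5))
  m15 <- marginal_log_likelihood(tp$model, tp$params, jd, control = list(order = 15))
  expect_lt(abs(m15 - m5), 1e-4)
})

test_that("likelihood is invariant to patient ordering", {
  tp <- toy_model_params()
  ids <- tp$cohort$patients$patient_id[1:8]
  small <- cfjoint:::subset_cohort(tp$cohort, ids)
  perm <- rev(seq_along(ids))
  small2 <- cohort_data(small$observations,
                        small$patients[perm, ], validate = FALSE)
  set.seed(20)
  b <- matrix(rnorm(8 * 4, sd = 0.3), 8, 4)
  l1 <- complete_data_log_likelihood(tp$model, tp$params, b, prepare_jm_data(tp$model, small))
  l2 <- complete_data_log_likelihood(tp$model, tp$params, b[perm, ],
                                     prepare_jm_data(tp$model, small2))
  expect_equal(l1, l2, tolerance = 1e-9)
})

test_that("model specifications survive a JSON round trip", {
  s <- small_sim()
  model <- prepare_model(s$model, s$sim$cohort)
  path <- withr::local_tempfile(fileext = ".json")
  model_to_json(model, path)
  back <- model_from_json(path)
  expect_identical(back$outcomes, model$outcomes)
  expect_equal(back$centering, model$centering)
  expect_equal(back$submodels$FEV1$age_basis$interior_knots,
               model$submodels$FEV1$age_basis$interior_knots)
  ages <- c(7.5, 12, 18)
  expect_equal(build_spline_basis(ages, back$baseline_basis),
               build_spline_basis(ages, model$baseline_basis))
})
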