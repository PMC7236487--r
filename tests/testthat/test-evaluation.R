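test_that("Kaplan-Meier reproduces the hand-computed product limit", {
  km <- kaplan_meier(toy_patients())
  sv <- function(t) {
    cv <- km$curve
    if (all(cv$age > t)) return(1)
    cv$survival[max(which(cv$age <= t))]
  }
  expect_equal(sv(2), 0.8)
  expect_equal(sv(4), 0.8 * 2 / 3)
  expect_equal(sv(5), 0.8 * (2 / 3) * 0.5)
  ## no censoring before the last event and entries at zero: the curve is the
  ## empirical survival function
  pat2 <- data.frame(patient_id = letters[1:4], entry_age = 0,
                     exit_age = 1:4, event = 1L)
  km2 <- kaplan_meier(pat2)
  expect_equal(km2$curve$survival, c(0.75, 0.5, 0.25, 0))
  expect_equal(km2$median, 2)
})

test_that("Kaplan-Meier reports a flat curve and no median when all are censored", {
  pat <- toy_patients()
  pat$event <- 0L
  km <- kaplan_meier(pat)
  expect_true(all(km$curve$survival == 1))
  expect_true(is.na(km$median))
})

test_that("Kaplan-Meier median of the registry-like cohort is in late adolescence", {
  s <- small_sim()
  km <- kaplan_meier(s$sim$cohort)
  expect_gt(km$median, 12)
  expect_lt(km$median, 20)
})

test_that("landmark AUC scores pairs the way the definition says", {
  ## printed four-patient example: events risks .9/.4, survivors .6/.1
  pat <- data.frame(patient_id = c("e1", "e2", "s1", "s2"),
                    entry_age = 6, exit_age = c(12.5, 12.8, 14, 14),
                    event = c(1L, 1L, 0L, 0L))
  risk <- c(e1 = 0.9, e2 = 0.4, s1 = 0.6, s2 = 0.1)
  got <- dynamic_auc(risk, pat, landmark = 12, window = 1)
  expect_equal(got$auc, 3 / 4)
  expect_identical(got$n_comparable_pairs, 4L)
  ## perfect separation
  risk2 <- c(e1 = 0.9, e2 = 0.8, s1 = 0.6, s2 = 0.1)
  expect_equal(dynamic_auc(risk2, pat, 12, 1)$auc, 1)
  ## ties count one half
  risk3 <- c(e1 = 0.5, e2 = 0.5, s1 = 0.5, s2 = 0.5)
  expect_equal(dynamic_auc(risk3, pat, 12, 1)$auc, 0.5)
  ## monotone transformations leave the AUC unchanged
  expect_equal(dynamic_auc(plogis(10 * risk), pat, 12, 1)$auc, 3 / 4)
  ## zero comparable pairs yields an undefined marker, not an error
  none <- dynamic_auc(risk, pat, landmark = 18, window = 1)
  expect_true(is.na(none$auc))
  expect_identical(none$n_comparable_pairs, 0L)
})

test_that("censored-in-window patients are excluded and risks must cover the risk set", {
  pat <- data.frame(patient_id = c("e1", "c1", "s1"),
                    entry_age = 6, exit_age = c(12.5, 12.6, 14),
                    event = c(1L, 0L, 0L))
  risk <- c(e1 = 0.9, c1 = 0.7, s1 = 0.2)
  got <- dynamic_auc(risk, pat, 12, 1)
  expect_identical(got$n_comparable_pairs, 1L)  # c1 dropped
  expect_equal(got$auc, 1)
  expect_error(dynamic_auc(risk[-3], pat, 12, 1), "missing")
})

test_that("permuted risks give chance-level discrimination", {
  set.seed(9)
  n <- 500
  pat <- data.frame(patient_id = sprintf("p%03d", 1:n), entry_age = 6,
                    exit_age = runif(n, 11, 16), event = rbinom(n, 1, 0.5))
  risk <- stats::setNames(runif(n), pat$patient_id)  # independent of outcomes
  got <- dynamic_auc(risk, pat, 12, 2)
  se <- sqrt((got$n_cases + got$n_controls + 1) / (12 * got$n_cases * got$n_controls))
  expect_lt(abs(got$auc - 0.5), 3 * se)
})

test_that("recovery report computes bias, RMSE and coverage by name", {
  truth <- c(`a[FEV1]` = -0.03, `sigma[FEV1]` = 7)
  mk <- function(est1, est2) data.frame(parameter = c("a[FEV1]", "sigma[FEV1]"),
                                        mean = c(est1, est2), sd = 0.01,
                                        hpd_lower = c(est1, est2) - 0.005,
                                        hpd_upper = c(est1, est2) + 0.005,
                                        p = 0.5)
  perfect <- parameter_recovery_report(truth, list(mk(-0.03, 7), mk(-0.03, 7)))
  expect_equal(perfect$bias, c(0, 0))
  expect_equal(perfect$rmse, c(0, 0))
  expect_equal(perfect$coverage, c(1, 1))
  expect_identical(nrow(perfect), 2L)
  mixed <- parameter_recovery_report(truth, list(mk(-0.02, 7), mk(-0.033, 7)))
  expect_equal(mixed$bias[1], 0.0035, tolerance = 1e-12)
  expect_equal(mixed$rmse[1], sqrt(mean(c(0.01, 0.003)^2)))
  expect_equal(mixed$coverage[1], 0.5)
  expect_error(parameter_recovery_report(c(zz = 1), list(mk(0, 0))), "common")
})

test_that("cross-validation is deterministic and covers every fold cell", {
  s <- small_sim()
  model <- s$model
  cv <- cv_control(n_folds = 2, subsample_size = 60, n_repetitions = 1,
                   landmark_ages = 12, windows = c(1, 2), n_mc = 50, seed = 5)
  ctl <- mcmc_control(n_iterations = 150, n_burn_in = 75, seed = 1)
  r1 <- cross_validated_auc(s$sim$cohort, model, mcmc = ctl, cv = cv)
  expect_identical(nrow(r1), 1L * 2L * 1L * 2L)  # reps x folds x landmarks x windows
  expect_true(all(r1$n_cases + r1$n_controls <= 60))
  r2 <- cross_validated_auc(s$sim$cohort, model, mcmc = ctl, cv = cv)
  expect_identical(r1, r2)
  expect_error(cross_validated_auc(s$sim$cohort, model, mcmc = ctl,
                                   cv = cv_control(subsample_size = 1e5)),
               "exceeds")
})
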