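test_that("retained draws are bit-identical given the seed", {
  s <- small_sim()
  ids <- s$sim$cohort$patients$patient_id[1:50]
  small <- cfjoint:::subset_cohort(s$sim$cohort, ids)
  ctl <- mcmc_control(n_iterations = 120, n_burn_in = 60, seed = 77)
  f1 <- fit_mcmc(small, s$model, control = ctl)
  f2 <- fit_mcmc(small, s$model, control = ctl)
  expect_identical(f1$draws, f2$draws)
  ctl$seed <- 78
  f3 <- fit_mcmc(small, s$model, control = ctl)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("draw bookkeeping follows the control settings", {
  s <- small_sim()
  ids <- s$sim$cohort$patients$patient_id[1:30]
  small <- cfjoint:::subset_cohort(s$sim$cohort, ids)
  ctl <- mcmc_control(n_iterations = 100, n_burn_in = 40, thinning = 3, seed = 1)
  f <- fit_mcmc(small, s$model, control = ctl)
  expect_identical(nrow(f$draws), 20L)
  expect_true(all(c("a[FEV1]", "sigma[FEV1]", "theta_h.1") %in% colnames(f$draws)))
  expect_identical(nrow(f$diagnostics), ncol(f$draws))
  expect_error(mcmc_control(n_iterations = 100, n_burn_in = 100), "smaller")
})

test_that("prior-only sampling recovers the association prior", {
  s <- small_sim()
  ids <- s$sim$cohort$patients$patient_id[1:10]
  small <- cfjoint:::subset_cohort(s$sim$cohort, ids)
  pri <- cfj_priors(a_scale = 2)
  ctl <- mcmc_control(n_iterations = 6000, n_burn_in = 1000, seed = 3,
                      n_survival_inner = 10, prior_only = TRUE)
  f <- fit_mcmc(small, s$model, priors = pri, control = ctl)
  a <- f$draws[, "a[FEV1]"]
  ess <- cfjoint:::ess_draws(a)
  se <- 2 / sqrt(ess)
  expect_lt(abs(mean(a)), 3 * se)
  expect_gt(sd(a), 2 * (1 - 3 / sqrt(ess)))
  expect_lt(sd(a), 2 * (1 + 3 / sqrt(ess)))
})

test_that("a single replicate recovers the lung-function association", {
  fit <- small_fit()  # 120 patients, truth a1 = -0.03
  s <- posterior_summary(fit)
  a1 <- s[s$parameter == "a[FEV1]", ]
  expect_lt(a1$hpd_lower, -0.03 + 3 * a1$sd)
  expect_gt(a1$hpd_upper, -0.03 - 3 * a1$sd)
  expect_lt(a1$mean, 0)  # clearly negative
  expect_lt(a1$hpd_upper, 0.01)
})

test_that("posterior for the association contracts roughly like sqrt(n)", {
  sd_for <- function(n, seed) {
    cfg <- cf_registry_config(n_patients = n, seed = seed)
    sim <- simulate_cohort(cfg)
    f <- fit_mcmc(sim$cohort, config_model(cfg),
                  control = mcmc_control(n_iterations = 500, n_burn_in = 250,
                                         seed = seed))
    s <- posterior_summary(f)
    s$sd[s$parameter == "a[FEV1]"]
  }
  ## average two replicates per size to damp replicate noise
  sd_small <- mean(c(sd_for(150, 61), sd_for(150, 62)))
  sd_large <- mean(c(sd_for(300, 63), sd_for(300, 64)))
  ratio <- sd_small / sd_large
  expect_gt(ratio, sqrt(2) * 0.7)
  expect_lt(ratio, sqrt(2) * 1.3)
})

test_that("sampler agrees with an independent random-walk Metropolis on the marginal likelihood", {
  ## tiny single-outcome model so that the marginal likelihood (adaptive
  ## Gauss-Hermite over the random intercept) is cheap: the Gibbs sampler
  ## and a from-scratch random-walk sampler on the marginalised posterior
  ## must agree on the posterior mean of the association
  cfg <- cf_registry_config(n_patients = 25, a = c(FEV1 = -0.03, BMIp = 0), seed = 41)
  sim <- simulate_cohort(cfg)
  sub <- longitudinal_submodel("FEV1", df = 1, random = "intercept")
  model <- prepare_model(joint_model_spec(sub, baseline_df = 2), sim$cohort)
  jd <- prepare_jm_data(model, sim$cohort)
  pri <- cfj_priors()
  fit <- fit_mcmc(jd, model, priors = pri,
                  control = mcmc_control(n_iterations = 3000, n_burn_in = 1000, seed = 9))
  gibbs_mean <- colMeans(fit$draws)

  ## independent oracle: adaptive RW Metropolis on the packed vector using
  ## marginal_log_likelihood + the same priors
  packed <- colMeans(fit$draws)  # start near the mass; correctness not speed
  log_post <- function(v) {
    p <- params_unpack(v, model)
    if (p$sigma[[1]] <= 0) return(-Inf)
    lp <- marginal_log_likelihood(model, p, jd, control = list(order = 9))
    lp + sum(dnorm(v[grep("^beta", names(v))], 0, pri$beta_scale, log = TRUE)) +
      dnorm(v[["a[FEV1]"]], 0, pri$a_scale, log = TRUE) +
      sum(dnorm(v[grep("^theta", names(v))], 0, pri$theta_scale, log = TRUE)) +
      ## half-Cauchy on sigma and log-Cholesky prior matching the
      ## inverse-Wishart(d + 2, I) with d = 1: IW density in L plus Jacobian
      stats::dcauchy(v[["sigma[FEV1]"]], 0, pri$sigma_scale, log = TRUE) +
      (function(l) { s2 <- exp(2 * l); -(3 / 2 + 1) * 2 * l - 0.5 / s2 + 2 * l })(v[["Sigma.L1.1"]])
  }
  set.seed(99)
  v <- packed
  lp <- log_post(v)
  sc <- c(`beta[FEV1].(Intercept)` = 1, `beta[FEV1].ns1` = 1.5,
          `sigma[FEV1]` = 0.15, Sigma.L1.1 = 0.12,
          `a[FEV1]` = 0.006, theta_h.1 = 0.35, theta_h.2 = 0.6)[names(packed)]
  keep <- matrix(NA_real_, 1500, length(v), dimnames = list(NULL, names(v)))
  n_acc <- 0
  for (it in 1:3500) {
    vn <- v + rnorm(length(v)) * sc
    lpn <- log_post(vn)
    if (is.finite(lpn) && log(runif(1)) < lpn - lp) { v <- vn; lp <- lpn; n_acc <- n_acc + 1 }
    if (it > 2000) keep[it - 2000, ] <- v
  }
  expect_gt(n_acc / 3500, 0.05)
  rw_mean <- colMeans(keep)
  for (par in c("a[FEV1]", "beta[FEV1].(Intercept)", "sigma[FEV1]")) {
    se <- sqrt(sd(fit$draws[, par])^2 / cfjoint:::ess_draws(fit$draws[, par]) +
                 sd(keep[, par])^2 / max(cfjoint:::ess_draws(keep[, par]), 5))
    expect_lt(abs(gibbs_mean[[par]] - rw_mean[[par]]), 4 * se + 1e-8)
  }
})
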