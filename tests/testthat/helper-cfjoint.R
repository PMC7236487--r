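## Shared fixtures, memoized so expensive objects are built once per test run.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

## small simulated registry + model, reused across files
small_sim <- function() memo("small_sim", {
  cfg <- cf_registry_config(n_patients = 120, seed = 7)
  sim <- simulate_cohort(cfg)
  list(cfg = cfg, sim = sim, model = config_model(cfg))
})

## a short but converged fit on the small registry
small_fit <- function() memo("small_fit", {
  s <- small_sim()
  fit_mcmc(s$sim$cohort, s$model,
           control = mcmc_control(n_iterations = 500, n_burn_in = 250, seed = 42))
})

## hand-built five-patient toy event table (delayed entry all zero)
toy_patients <- function() {
  data.frame(patient_id = paste0("T", 1:5),
             entry_age = rep(0, 5),
             exit_age = c(2, 3, 4, 5, 6),
             event = c(1, 0, 1, 1, 0),
             stringsAsFactors = FALSE)
}

## minimal valid cohort for IO tests
toy_cohort <- function() {
  pat <- data.frame(patient_id = c("A", "B"),
                    entry_age = c(6.5, 8), exit_age = c(12, 15),
                    event = c(1L, 0L),
                    genotype = c("homozygous", "none"), sex = c("F", "M"),
                    hispanic = c(0L, 1L), ses = c(1L, 0L),
                    birth_cohort = c("1990-1994", ">1999"),
                    mrsa_age = c(9.5, NA), pa_age = c(NA, NA),
                    cfrd_age = c(NA, 10), enzymes_age = c(6.5, NA),
                    stringsAsFactors = FALSE)
  obs <- data.frame(patient_id = rep(c("A", "B"), each = 4),
                    age = c(6.5, 8, 10, 11.5, 8, 10, 12, 14.5),
                    outcome = rep(c("FEV1", "BMIp"), 4),
                    value = c(95, 50, 88, 45, 92, 60, 85, 55),
                    stringsAsFactors = FALSE)
  cohort_data(obs, pat)
}

## a registry model + generating parameters with a chosen association,
## convenient for single-patient hazard checks
toy_model_params <- function(a = c(FEV1 = -0.03, BMIp = 0)) {
  cfg <- cf_registry_config(n_patients = 50, a = a, seed = 1)
  model <- config_model(cfg)
  sim <- memo(paste0("toy_mp_", paste(a, collapse = "_")), simulate_cohort(cfg))
  params <- sim$truth$params
  params$theta[] <- c(log(0.1), 0.2, 0.1, 0, 0)
  list(model = model, params = params, cohort = sim$cohort)
}

## shared fixture: a patient history from the small simulated registry and
## the cached fit
pred_fixture <- function() memo("pred_fixture", {
  s <- small_sim()
  fit <- small_fit()
  pats <- s$sim$cohort$patients
  obs <- s$sim$cohort$observations
  ok <- pats$exit_age - pats$entry_age > 3
  p1 <- pats[which(ok)[1], ]
  o1 <- obs[obs$patient_id == p1$patient_id, ]
  lm_age <- p1$entry_age + 2
  list(model = fit$model, fit = fit,
       hist = patient_history(p1, o1, lm_age), patient = p1, lm = lm_age)
})

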