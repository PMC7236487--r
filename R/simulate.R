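## Synthetic registry generator. Emulates the statistical structure the
## analysis assumes: irregular encounter ages in the 6-20 year window,
## declining FEV1 with large between- and within-patient variability, growth
## percentiles, switch-on time-varying covariates, and event times drawn from
## the joint model's own hazard by inverse-transform sampling. Ground truth
## is retained for parameter-recovery tests.

#' Simulation configuration
#'
#' @param n_patients cohort size.
#' @param eligibility_window ages (years) delimiting follow-up.
#' @param visit_rate expected encounters per year (exponential gaps).
#' @param baseline_covariate_frequencies named list: `male`, `genotype`
#'   (named probabilities), `hispanic`, `ses_low`, `birth_cohort` (named).
#' @param switch_baseline named prevalence of each switch-on covariate being
#'   already on at entry.
#' @param switch_hazards named yearly onset rates after entry.
#' @param outcome_specs list per outcome: `name`, `df`, `fixed` (coefficients
#'   on intercept + natural-spline age basis with equally spaced interior
#'   knots), `residual_sd`.
#' @param re_covariance joint covariance of the stacked random effects
#'   (per-outcome intercept and age slope, in outcome order).
#' @param association named per-outcome log-hazard slopes a_k on the current
#'   biomarker value.
#' @param centering named constants subtracted from each biomarker inside the
#'   hazard (shifts only the baseline hazard, never the a_k).
#' @param baseline_hazard list: `family = "weibull"` with `shape`, `scale`;
#'   `family = "constant"` with `rate`; or `family = "spline"` with `coef`
#'   (length 5, on the intercept + natural-spline log-hazard basis).
#' @param entry_beta shape parameters of the Beta distribution mapped onto
#'   the eligibility window to draw entry ages.
#' @param dropout_rate yearly censoring (loss to follow-up) rate; follow-up
#'   also ends administratively at the upper window edge.
#' @param seed integer.
#' @return an object of class `cfj_sim_config`.
#' @export
simulation_config <- function(n_patients,
                              eligibility_window = c(6, 20),
                              visit_rate = 4,
                              baseline_covariate_frequencies = list(),
                              switch_baseline = numeric(0),
                              switch_hazards = numeric(0),
                              outcome_specs,
                              re_covariance,
                              association,
                              centering = NULL,
                              baseline_hazard = list(family = "weibull", shape = 1.7, scale = 13.5),
                              entry_beta = c(0.45, 1.8),
                              dropout_rate = 0.2,
                              seed = 1L) {
  if (visit_rate <= 0) stop("visit_rate must be positive")
  if (n_patients < 1) stop("n_patients must be at least 1")
  outs <- vapply(outcome_specs, `[[`, character(1), "name")
  names(outcome_specs) <- outs
  d <- 2L * length(outs)
  re_covariance <- as.matrix(re_covariance)
  if (!isTRUE(all.equal(re_covariance, t(re_covariance))) ||
      min(eigen(re_covariance, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    stop("re_covariance must be symmetric positive semi-definite")
  if (nrow(re_covariance) != d)
    stop("re_covariance must be ", d, " x ", d, " (intercept + slope per outcome)")
  if (!all(outs %in% names(association))) stop("association must name every outcome")
  p <- unlist(baseline_covariate_frequencies)
  if (length(p) && (any(p < 0) || any(p > 1))) stop("frequencies must lie in [0, 1]")
  if (is.null(centering))
    centering <- stats::setNames(vapply(outcome_specs, function(o) o$fixed[1], 0), outs)
  structure(list(n_patients = as.integer(n_patients),
                 eligibility_window = eligibility_window, visit_rate = visit_rate,
                 baseline_covariate_frequencies = baseline_covariate_frequencies,
                 switch_baseline = switch_baseline, switch_hazards = switch_hazards,
                 outcome_specs = outcome_specs, re_covariance = re_covariance,
                 association = association[outs], centering = centering[outs],
                 baseline_hazard = baseline_hazard, entry_beta = entry_beta,
                 dropout_rate = dropout_rate, seed = as.integer(seed)),
            class = "cfj_sim_config")
}

#' Default registry-like configuration
#'
#' Emulates the analysis cohort: entry ages with median near 8 years,
#' quarterly encounters, baseline covariate frequencies near the registry's
#' overall column (e.g. 51.6% male), FEV1 declining nonlinearly from the
#' mid-90s %-predicted with large between-patient spread, BMIp near the 50th
#' percentile, a per-unit FEV1 log-hazard of -0.03 (hazard ratio 0.97) and a
#' null growth association, and roughly a third of patients experiencing an
#' exacerbation before censoring.
#'
#' @param n_patients cohort size.
#' @param a named association overrides.
#' @param seed integer.
#' @param ... further overrides passed to [simulation_config()].
#' @return a [simulation_config()] object.
#' @export
cf_registry_config <- function(n_patients = 1000,
                               a = c(FEV1 = -0.03, BMIp = 0),
                               seed = 1L, ...) {
  outcome_specs <- list(
    list(name = "FEV1", df = 3,
         ## intercept + ns coefficients approximating 95 - 1.2 (age-6) - 0.04 (age-6)^2
         fixed = c(95.1, -12.694, -26.517, -21.125),
         residual_sd = 7),
    list(name = "BMIp", df = 3,
         ## mild decline from the 52nd percentile
         fixed = c(52.0, -2.406, -4.917, -3.411),
         residual_sd = 8))
  outcome_specs <- outcome_specs[match(names(a), c("FEV1", "BMIp"))]
  sds <- c(FEV1_b0 = 14, FEV1_b1 = 1.1, BMIp_b0 = 22, BMIp_b1 = 1.0)
  R <- diag(4)
  R[1, 2] <- R[2, 1] <- -0.2   # within-outcome intercept-slope
  R[3, 4] <- R[4, 3] <- -0.2
  R[1, 3] <- R[3, 1] <- 0.3    # cross-outcome intercepts
  R[2, 4] <- R[4, 2] <- 0.2    # cross-outcome slopes
  Sig <- diag(sds) %*% R %*% diag(sds)
  simulation_config(
    n_patients = n_patients,
    baseline_covariate_frequencies = list(
      male = 0.516,
      genotype = c(homozygous = 0.481, heterozygous = 0.382, none = 0.137),
      hispanic = 0.087, ses_low = 0.498,
      birth_cohort = c("<1981" = 0.188, "1981-1989" = 0.253, "1990-1994" = 0.166,
                       "1995-1999" = 0.261, ">1999" = 0.132)),
    switch_baseline = c(mrsa = 0.074, pa = 0.196, cfrd = 0.039, enzymes = 0.39),
    switch_hazards = c(mrsa = 0.02, pa = 0.05, cfrd = 0.015, enzymes = 0.05),
    outcome_specs = outcome_specs,
    re_covariance = Sig,
    association = a,
    centering = c(FEV1 = 90.6, BMIp = 48.6),
    seed = seed, ...)
}

## the joint-model spec implied by a simulation config; generator and fitter
## share this one basis code path (equally spaced interior knots)
#' Model specification implied by a simulation configuration
#'
#' Returns the prepared [joint_model_spec()] whose design (spline bases,
#' centering) is exactly the one the generator draws from, so that fitted and
#' true parameter layouts coincide in recovery studies.
#'
#' @param config a [simulation_config()].
#' @return a prepared `cfj_model`.
#' @export
config_model <- function(config) {
  w <- config$eligibility_window
  subs <- lapply(config$outcome_specs, function(o)
    longitudinal_submodel(o$name, df = o$df))
  model <- joint_model_spec(subs, baseline_df = 5, window = w)
  for (k in model$outcomes) {
    df <- model$submodels[[k]]$df
    ik <- if (df > 1) w[1] + diff(w) * seq_len(df - 1) / df else numeric(0)
    model$submodels[[k]]$age_basis <-
      spline_basis_spec(df, boundary_knots = w, interior_knots = ik)
  }
  model$baseline_basis <- spline_basis_spec(
    4L, boundary_knots = w, interior_knots = w[1] + diff(w) * (1:3) / 4)
  model$centering[] <- unlist(config$centering)[model$outcomes]
  model$prepared <- TRUE
  model
}

log_h0_fun <- function(baseline_hazard, model = NULL) {
  fam <- baseline_hazard$family
  if (fam == "weibull") {
    k <- baseline_hazard$shape; lam <- baseline_hazard$scale
    function(t) log(k / lam) + (k - 1) * log(pmax(t, 1e-12) / lam)
  } else if (fam == "constant") {
    r <- baseline_hazard$rate
    function(t) rep(log(r), length(t))
  } else if (fam == "spline") {
    coef <- baseline_hazard$coef
    function(t) drop(baseline_design(model, t) %*% coef)
  } else stop("unknown baseline hazard family: ", fam)
}

#' Draw one event time by inverse-transform sampling
#'
#' Draws E ~ Exponential(1) and solves Lambda(T) - Lambda(entry) = E on the
#' quadrature-based cumulative hazard (Gauss-Legendre per smooth piece,
#' pieces split at `breaks` and at doubling horizons so arbitrarily distant
#' maxima stay cheap). Returns the censoring pair (`max_age`, 0) when the
#' total hazard up to `max_age` is insufficient.
#'
#' @param hazard_fun vectorised hazard function of age.
#' @param entry_age,max_age bounds (years).
#' @param breaks ages at which the hazard may jump (quadrature splits there).
#' @param order Gauss-Legendre order per piece.
#' @return list with `time` and `event` (1 = event at `time`).
#' @export
simulate_event_time <- function(hazard_fun, entry_age, max_age, breaks = NULL,
                                order = 15L) {
  E <- stats::rexp(1)
  g <- gl_unit(order)
  seg_int <- function(a, b) {
    h <- hazard_fun(a + (b - a) * g$x)
    if (any(!is.finite(h))) stop("non-finite hazard between ages ", a, " and ", b)
    (b - a) * sum(g$w * h)
  }
  br <- sort(unique(c(entry_age, breaks[breaks > entry_age & breaks < max_age])))
  cum <- 0; cur <- entry_age; step <- 1
  bq <- c(br[-1], Inf); bi <- 1L
  repeat {
    nxt <- min(cur + step, bq[bi], max_age)
    lam <- seg_int(cur, nxt)
    if (cum + lam >= E) {
      f <- function(t) cum + seg_int(cur, t) - E
      root <- stats::uniroot(f, lower = cur, upper = nxt, tol = 1e-10)$root
      return(list(time = root, event = 1L))
    }
    cum <- cum + lam
    if (nxt >= max_age) return(list(time = max_age, event = 0L))
    if (nxt == bq[bi]) bi <- bi + 1L else step <- min(step * 2, 64)
    cur <- nxt
  }
}

#' Draw an encounter schedule
#'
#' First encounter at entry; subsequent gaps are exponential with mean
#' `1/visit_rate`; all ages are at most `exit_age`.
#'
#' @param entry_age,exit_age follow-up bounds (years).
#' @param visit_rate expected encounters per year.
#' @return increasing numeric vector of encounter ages.
#' @export
simulate_visit_schedule <- function(entry_age, exit_age, visit_rate) {
  if (exit_age <= entry_age) stop("exit_age must exceed entry_age")
  if (visit_rate <= 0) stop("visit_rate must be positive")
  ages <- entry_age
  cur <- entry_age
  repeat {
    cur <- cur + stats::rexp(1, rate = visit_rate)
    if (cur > exit_age) break
    ages <- c(ages, cur)
  }
  ages
}

rcat <- function(n, probs) {
  names(probs)[1 + findInterval(stats::runif(n), cumsum(probs / sum(probs)))]
}

#' Simulate a registry cohort from the joint model
#'
#' Draws baseline covariates, entry ages, random effects, switch-on covariate
#' onset ages, censoring, event times from the model's own hazard, an
#' irregular encounter schedule, and noisy biomarker measurements at each
#' encounter (all modelled outcomes measured at entry and at every visit).
#'
#' @param config a [simulation_config()].
#' @return list with elements `cohort` (a [cohort_data()]) and `truth`
#'   (class `cfj_truth`: the generating parameters in the fitted layout).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cfj_sim_config"))
  model <- config_model(config)
  w <- config$eligibility_window
  n <- config$n_patients
  outs <- model$outcomes
  freq <- config$baseline_covariate_frequencies

  with_seed(derive_seed(config$seed, "cohort"), {
    sex <- if (!is.null(freq$male)) ifelse(stats::runif(n) < freq$male, "M", "F") else rep("M", n)
    genotype <- if (!is.null(freq$genotype)) rcat(n, freq$genotype) else rep("none", n)
    hispanic <- if (!is.null(freq$hispanic)) as.integer(stats::runif(n) < freq$hispanic) else 0L
    ses <- if (!is.null(freq$ses_low)) as.integer(stats::runif(n) < freq$ses_low) else 0L
    bc <- if (!is.null(freq$birth_cohort)) rcat(n, freq$birth_cohort) else rep("1990-1994", n)
    entry <- w[1] + diff(w) * stats::rbeta(n, config$entry_beta[1], config$entry_beta[2])
    entry <- pmin(entry, w[2] - 0.25)

    b <- MASS::mvrnorm(n, mu = rep(0, nrow(config$re_covariance)),
                       Sigma = config$re_covariance)
    if (is.null(dim(b))) b <- matrix(b, nrow = n)

    sw_names <- union(names(config$switch_baseline), names(config$switch_hazards))
    sw <- matrix(NA_real_, n, length(sw_names), dimnames = list(NULL, sw_names))
    for (s in sw_names) {
      p0 <- config$switch_baseline[s]; p0 <- if (is.na(p0)) 0 else p0
      rate <- config$switch_hazards[s]; rate <- if (is.na(rate)) 0 else rate
      on0 <- stats::runif(n) < p0
      onset <- entry + stats::rexp(n, rate = max(rate, 1e-12))
      onset[rate <= 0] <- Inf
      age <- ifelse(on0, entry, onset)
      sw[, s] <- ifelse(age <= w[2], age, NA_real_)
    }

    pat <- data.frame(patient_id = sprintf("P%05d", seq_len(n)),
                      entry_age = entry, exit_age = NA_real_, event = NA_integer_,
                      genotype = genotype, sex = sex, hispanic = hispanic, ses = ses,
                      birth_cohort = bc, stringsAsFactors = FALSE)
    for (s in sw_names) pat[[paste0(s, "_age")]] <- sw[, s]
    pate <- expand_patient_covariates(pat)

    logh0 <- log_h0_fun(config$baseline_hazard, model)
    cols <- re_cols(model)
    a_vec <- unlist(config$association)[outs]
    cc <- unlist(config$centering)[outs]

    m_fun <- function(i, k, t) {
      X <- long_fixed_design(model, k, pate, rep(i, length(t)), t)
      Z <- long_random_design(model, k, t)
      drop(X %*% config$outcome_specs[[k]]$fixed) + drop(Z %*% b[i, cols[[k]]])
    }

    exit <- numeric(n); event <- integer(n)
    for (i in seq_len(n)) {
      cens <- min(w[2], entry[i] + max(stats::rexp(1, max(config$dropout_rate, 1e-12)), 0.1))
      if (config$dropout_rate <= 0) cens <- w[2]
      hfun <- function(t) {
        lp <- logh0(t)
        for (j in seq_along(outs))
          lp <- lp + a_vec[j] * (m_fun(i, outs[j], t) - cc[j])
        exp(lp)
      }
      ev <- simulate_event_time(hfun, entry[i], cens,
                                breaks = sw[i, ][is.finite(sw[i, ])])
      exit[i] <- ev$time; event[i] <- ev$event
      if (exit[i] <= entry[i]) exit[i] <- entry[i] + 1e-3
    }
    pat$exit_age <- exit; pat$event <- event

    obs_list <- vector("list", n)
    for (i in seq_len(n)) {
      ages <- simulate_visit_schedule(entry[i], exit[i], config$visit_rate)
      rows <- lapply(outs, function(k) {
        mu <- m_fun(i, k, ages)
        v <- mu + stats::rnorm(length(ages), 0, config$outcome_specs[[k]]$residual_sd)
        if (k == "FEV1") v <- pmax(v, 1) else v <- pmin(pmax(v, 0), 100)
        data.frame(patient_id = pat$patient_id[i], age = ages, outcome = k,
                   value = v, stringsAsFactors = FALSE)
      })
      obs_list[[i]] <- do.call(rbind, rows)
    }
    obs <- do.call(rbind, obs_list)
  })

  cohort <- cohort_data(obs, pat, window = w)
  params <- param_template(model)
  for (k in outs) params$beta[[k]][] <- config$outcome_specs[[k]]$fixed
  params$sigma[] <- vapply(config$outcome_specs, `[[`, 0, "residual_sd")[outs]
  params$Sigma <- config$re_covariance
  params$a[] <- unlist(config$association)[outs]
  flat <- params_pack(params, model)
  if (config$baseline_hazard$family == "spline") {
    params$theta[] <- config$baseline_hazard$coef
    flat[paste0("theta_h.", seq_along(params$theta))] <- config$baseline_hazard$coef
  } else {
    flat <- flat[!grepl("^theta_h\\.", names(flat))]
  }
  truth <- structure(list(flat = flat, params = params, model = model,
                          config = config), class = "cfj_truth")
  list(cohort = cohort, truth = truth)
}
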