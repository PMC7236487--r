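## Joint-model core: submodel mean functions, proportional hazard with
## current-value association, quadrature cumulative hazard, and the
## complete-data / marginal log-likelihoods.
##
## Model, for outcome k of patient i at age t:
##   y_ki(t) = x_ki(t)' beta_k + z_ki(t)' b_ki + eps_ki(t) = m_ki(t) + eps
##   h_i(t)  = h0(t) exp( gamma' w_i(t) + sum_k a_k m_ki(t) )
## with b_i = (b_1i, ..., b_Ki) jointly multivariate normal and h0 a
## log-spline baseline. Patients enter the risk set at entry_age (left
## truncation); exp(a_k) is the hazard ratio per unit of biomarker k.

#' Longitudinal submodel specification
#'
#' Fixed effects are an intercept, a natural cubic spline in age (nonlinear
#' age trend), optional baseline covariates (linear and, via
#' `spline_interactions`, covariate-specific age trends), optional switch-on
#' time-varying covariates, and optionally the encounter count in the prior
#' year. Random effects are per-patient intercept and age slope by default.
#'
#' @param outcome one of `"FEV1"`, `"BMIp"`, `"WFA"`, `"HFA"`.
#' @param df spline degrees of freedom for the age trend (3 in the standard
#'   configurations, 2 in the most parameter-heavy three-outcome one).
#' @param covariates names of numeric baseline covariate columns (after dummy
#'   expansion, e.g. `"sex_male"`, `"genotype_homozygous"`).
#' @param spline_interactions subset of `covariates` whose age trend differs
#'   (covariate-by-spline interaction columns).
#' @param tv_covariates names among `mrsa`, `pa`, `cfrd`, `enzymes`.
#' @param encounter_count include the prior-year encounter count covariate.
#' @param random `"intercept_slope"` (default) or `"intercept"`.
#' @param residual_sd optional fixed value used only as an initial value.
#' @return an object of class `cfj_submodel`.
#' @export
longitudinal_submodel <- function(outcome, df = 3, covariates = character(),
                                  spline_interactions = character(),
                                  tv_covariates = character(),
                                  encounter_count = FALSE,
                                  random = c("intercept_slope", "intercept"),
                                  residual_sd = NULL) {
  outcome <- match.arg(outcome, OUTCOME_NAMES)
  random <- match.arg(random)
  if (!all(spline_interactions %in% covariates))
    stop("spline_interactions must be a subset of covariates")
  if (!all(tv_covariates %in% SWITCH_COVARIATES))
    stop("unknown time-varying covariate(s): ",
         paste(setdiff(tv_covariates, SWITCH_COVARIATES), collapse = ", "))
  structure(list(outcome = outcome, df = as.integer(df), covariates = covariates,
                 spline_interactions = spline_interactions,
                 tv_covariates = tv_covariates,
                 encounter_count = isTRUE(encounter_count), random = random,
                 residual_sd = residual_sd, age_basis = NULL),
            class = "cfj_submodel")
}

#' Joint model specification
#'
#' Couples 1–3 longitudinal submodels to the proportional-hazards
#' exacerbation submodel through current-value association coefficients
#' (one `a_k` per submodel). The log baseline hazard is a natural cubic
#' spline in age with `baseline_df` coefficients (intercept plus
#' `baseline_df - 1` spline columns), strictly positive by construction.
#'
#' Internally the biomarkers are centred (constants stored in `centering`,
#' set from the data by the fitting routines) inside the hazard's linear
#' predictor; this only shifts the baseline-hazard coefficients and leaves
#' every `a_k` and hazard ratio untouched.
#'
#' @param submodels list of [longitudinal_submodel()] objects (unique outcomes).
#' @param event_covariates numeric baseline covariate columns entering the
#'   hazard (coefficient vector gamma).
#' @param event_tv_covariates switch-on covariates entering the hazard.
#' @param baseline_df number of log-baseline-hazard coefficients (default 5).
#' @param window eligibility window (years of age).
#' @return an object of class `cfj_model`.
#' @export
joint_model_spec <- function(submodels, event_covariates = character(),
                             event_tv_covariates = character(),
                             baseline_df = 5, window = c(6, 20)) {
  if (inherits(submodels, "cfj_submodel")) submodels <- list(submodels)
  stopifnot(length(submodels) >= 1, length(submodels) <= 3,
            all(vapply(submodels, inherits, logical(1), "cfj_submodel")))
  outs <- unname(vapply(submodels, `[[`, character(1), "outcome"))
  if (anyDuplicated(outs)) stop("duplicate outcomes across submodels")
  names(submodels) <- outs
  if (!all(event_tv_covariates %in% SWITCH_COVARIATES))
    stop("unknown event time-varying covariate(s)")
  structure(list(submodels = submodels, outcomes = outs,
                 event_covariates = event_covariates,
                 event_tv_covariates = event_tv_covariates,
                 baseline_df = as.integer(baseline_df),
                 window = as.numeric(window),
                 baseline_basis = NULL,
                 centering = stats::setNames(rep(0, length(outs)), outs),
                 prepared = FALSE),
            class = "cfj_model")
}

#' @export
print.cfj_model <- function(x, ...) {
  cat(sprintf("<cfj_model> outcomes: %s (df %s); association: current value\n",
              paste(x$outcomes, collapse = ", "),
              paste(vapply(x$submodels, `[[`, integer(1), "df"), collapse = "/")))
  cat(sprintf("  event covariates: %s; baseline log-hazard df %d\n",
              if (length(c(x$event_covariates, x$event_tv_covariates)))
                paste(c(x$event_covariates, x$event_tv_covariates), collapse = ", ")
              else "(none)", x$baseline_df))
  invisible(x)
}

## number of random effects per submodel and in total
n_random_k <- function(sub) if (sub$random == "intercept_slope") 2L else 1L
n_random <- function(model) sum(vapply(model$submodels, n_random_k, integer(1)))
re_offsets <- function(model) {
  d <- vapply(model$submodels, n_random_k, integer(1))
  stats::setNames(cumsum(c(0L, d[-length(d)])), model$outcomes)
}

#' Freeze a model's bases and centering on a cohort
#'
#' Resolves data-driven quantities — interior knots of each age spline (from
#' observed encounter ages), knots of the baseline-hazard spline (from exit
#' ages), and the biomarker centering constants (observed means) — so every
#' later evaluation, simulation or prediction reuses identical bases.
#'
#' @param model a [joint_model_spec()].
#' @param cohort a [cohort_data()] object.
#' @return the model with `prepared = TRUE`.
#' @export
prepare_model <- function(model, cohort) {
  stopifnot(inherits(model, "cfj_model"), inherits(cohort, "cfj_cohort"))
  if (model$prepared) return(model)
  obs <- cohort$observations
  for (k in model$outcomes) {
    sub <- model$submodels[[k]]
    ages <- obs$age[obs$outcome == k]
    if (!length(ages)) stop("no observations for outcome ", k)
    spec <- spline_basis_spec(sub$df, boundary_knots = model$window)
    model$submodels[[k]]$age_basis <- resolve_spline_spec(spec, ages)
    model$centering[k] <- mean(obs$value[obs$outcome == k])
  }
  exits <- cohort$patients$exit_age
  bspec <- spline_basis_spec(model$baseline_df - 1L, boundary_knots = model$window)
  model$baseline_basis <- resolve_spline_spec(bspec, exits)
  model$prepared <- TRUE
  model
}

## ---- design builders (internal) -------------------------------------------

## fixed-effect design rows for submodel k; `idx` indexes rows of `patients`
## (already dummy-expanded), parallel to `ages`; `enc` optional counts
long_fixed_design <- function(model, k, patients, idx, ages, enc = NULL) {
  sub <- model$submodels[[k]]
  S <- build_spline_basis(ages, sub$age_basis)
  X <- cbind(`(Intercept)` = rep(1, length(ages)), S)
  for (cv in sub$covariates) {
    if (!cv %in% names(patients)) stop("missing covariate column: ", cv)
    X <- cbind(X, stats::setNames(data.frame(patients[[cv]][idx]), cv))
  }
  X <- as.matrix(X)
  for (cv in sub$spline_interactions) {
    XI <- S * patients[[cv]][idx]
    colnames(XI) <- paste0(cv, ":", colnames(S))
    X <- cbind(X, XI)
  }
  for (tv in sub$tv_covariates) {
    X <- cbind(X, switch_indicator(patients, tv, idx, ages))
    colnames(X)[ncol(X)] <- tv
  }
  if (sub$encounter_count) {
    if (is.null(enc)) stop("encounter counts required for this submodel")
    X <- cbind(X, encounters = enc)
  }
  X
}

long_random_design <- function(model, k, ages) {
  sub <- model$submodels[[k]]
  if (sub$random == "intercept_slope")
    cbind(b0 = rep(1, length(ages)), b1 = ages - model$window[1])
  else
    cbind(b0 = rep(1, length(ages)))
}

event_design <- function(model, patients, idx, ages) {
  q <- length(model$event_covariates) + length(model$event_tv_covariates)
  if (q == 0L) return(matrix(0, length(ages), 0))
  W <- NULL
  for (cv in model$event_covariates) {
    if (!cv %in% names(patients)) stop("missing covariate column: ", cv)
    W <- cbind(W, patients[[cv]][idx])
  }
  for (tv in model$event_tv_covariates)
    W <- cbind(W, switch_indicator(patients, tv, idx, ages))
  colnames(W) <- c(model$event_covariates, model$event_tv_covariates)
  W
}

baseline_design <- function(model, ages) {
  cbind(h0 = rep(1, length(ages)), build_spline_basis(ages, model$baseline_basis))
}

## ---- parameter vector ------------------------------------------------------

## parameter container: list(beta = list per outcome, sigma, Sigma, gamma, a, theta)
param_template <- function(model, cohort = NULL) {
  stopifnot(model$prepared)
  pats <- if (!is.null(cohort)) expand_patient_covariates(cohort$patients) else NULL
  beta <- list()
  for (k in model$outcomes) {
    if (!is.null(pats)) {
      X <- long_fixed_design(model, k, pats, 1L, model$window[1],
                             enc = if (model$submodels[[k]]$encounter_count) 0 else NULL)
      beta[[k]] <- stats::setNames(numeric(ncol(X)), colnames(X))
    } else {
      sub <- model$submodels[[k]]
      nm <- c("(Intercept)", paste0("ns", seq_len(sub$df)), sub$covariates,
              unlist(lapply(sub$spline_interactions, function(cv)
                paste0(cv, ":ns", seq_len(sub$df)))),
              sub$tv_covariates, if (sub$encounter_count) "encounters")
      beta[[k]] <- stats::setNames(numeric(length(nm)), nm)
    }
  }
  d <- n_random(model)
  q <- length(model$event_covariates) + length(model$event_tv_covariates)
  list(beta = beta,
       sigma = stats::setNames(rep(1, length(model$outcomes)), model$outcomes),
       Sigma = diag(d),
       gamma = stats::setNames(numeric(q),
                               c(model$event_covariates, model$event_tv_covariates)),
       a = stats::setNames(numeric(length(model$outcomes)), model$outcomes),
       theta = stats::setNames(numeric(model$baseline_df),
                               paste0("theta", seq_len(model$baseline_df))))
}

#' Flatten joint-model parameters to a named vector
#'
#' The flat layout (regression coefficients, residual SDs, the random-effects
#' covariance as its unconstrained log-Cholesky entries, event coefficients,
#' association coefficients, baseline-hazard coefficients) is the currency of
#' posterior draws; [params_unpack()] inverts it exactly.
#'
#' @param params parameter list as produced by the fitting routines.
#' @param model a prepared [joint_model_spec()].
#' @return named numeric vector.
#' @export
params_pack <- function(params, model) {
  out <- numeric(0)
  for (k in model$outcomes)
    out <- c(out, stats::setNames(params$beta[[k]],
                                  paste0("beta[", k, "].", names(params$beta[[k]]))))
  out <- c(out, stats::setNames(params$sigma, paste0("sigma[", model$outcomes, "]")))
  L <- t(chol(params$Sigma))
  d <- nrow(L)
  for (i in seq_len(d)) for (j in seq_len(i)) {
    v <- if (i == j) log(L[i, i]) else L[i, j]
    out <- c(out, stats::setNames(v, sprintf("Sigma.L%d.%d", i, j)))
  }
  if (length(params$gamma))
    out <- c(out, stats::setNames(params$gamma, paste0("gamma.", names(params$gamma))))
  out <- c(out, stats::setNames(params$a, paste0("a[", model$outcomes, "]")))
  out <- c(out, stats::setNames(params$theta, paste0("theta_h.", seq_along(params$theta))))
  out
}

#' @rdname params_pack
#' @param vec named numeric vector in the [params_pack()] layout.
#' @export
params_unpack <- function(vec, model) {
  tmpl <- param_template(model)
  pos <- 1L
  take <- function(n) { v <- vec[pos:(pos + n - 1L)]; pos <<- pos + n; unname(v) }
  for (k in model$outcomes)
    tmpl$beta[[k]][] <- take(length(tmpl$beta[[k]]))
  tmpl$sigma[] <- take(length(tmpl$sigma))
  d <- nrow(tmpl$Sigma)
  L <- matrix(0, d, d)
  for (i in seq_len(d)) for (j in seq_len(i)) {
    v <- take(1L)
    L[i, j] <- if (i == j) exp(v) else v
  }
  tmpl$Sigma <- L %*% t(L)
  if (length(tmpl$gamma)) tmpl$gamma[] <- take(length(tmpl$gamma))
  tmpl$a[] <- take(length(tmpl$a))
  tmpl$theta[] <- take(length(tmpl$theta))
  tmpl
}

## ---- single-patient evaluations (exported surface) -------------------------

## normalize a one-row patient record + b_i for the evaluators below
as_patient_row <- function(patient) {
  p <- expand_patient_covariates(as.data.frame(patient))
  stopifnot(nrow(p) == 1L)
  p
}

#' Model-implied biomarker mean for one patient
#'
#' Computes m_k(t) = x_k(t)'beta_k + z_k(t)'b_k, the error-free current value
#' whose association coefficient a_k the hazard acts on.
#'
#' @param model prepared [joint_model_spec()].
#' @param params parameter list (or packed vector).
#' @param b_i the patient's random-effect vector (all outcomes, stacked).
#' @param t age(s) in years; linear extrapolation outside the boundary knots.
#' @param patient one-row patient record (baseline covariates, switch ages).
#' @param outcome which submodel; default the first.
#' @param encounter_ages encounter history, needed only when the submodel
#'   uses the prior-year encounter count.
#' @return numeric vector of means at `t`.
#' @export
longitudinal_mean <- function(model, params, b_i, t, patient,
                              outcome = model$outcomes[1], encounter_ages = NULL) {
  if (is.numeric(params) && !is.list(params)) params <- params_unpack(params, model)
  k <- match.arg(outcome, model$outcomes)
  p <- as_patient_row(patient)
  enc <- if (model$submodels[[k]]$encounter_count)
    encounters_in_prior_year(encounter_ages %||% numeric(0), t) else NULL
  X <- long_fixed_design(model, k, p, rep(1L, length(t)), t, enc = enc)
  if (ncol(X) != length(params$beta[[k]]))
    stop("coefficient length mismatch for outcome ", k)
  Z <- long_random_design(model, k, t)
  off <- re_offsets(model)[k]
  bk <- b_i[off + seq_len(n_random_k(model$submodels[[k]]))]
  drop(X %*% params$beta[[k]] + Z %*% bk)
}

## linear predictor of the hazard at ages t for one patient
hazard_lp <- function(model, params, b_i, t, p, encounter_ages = NULL) {
  B <- baseline_design(model, t)
  lp <- drop(B %*% params$theta)
  W <- event_design(model, p, rep(1L, length(t)), t)
  if (ncol(W)) lp <- lp + drop(W %*% params$gamma)
  for (k in model$outcomes) {
    m <- longitudinal_mean(model, params, b_i, t, p, outcome = k,
                           encounter_ages = encounter_ages)
    lp <- lp + params$a[[k]] * (m - model$centering[[k]])
  }
  lp
}

#' Subject-specific hazard of first exacerbation
#'
#' h(t) = h0(t) exp(gamma' w(t) + sum_k a_k m_k(t)): a unit increase in the
#' underlying value of biomarker k multiplies the hazard by exp(a_k).
#'
#' @inheritParams longitudinal_mean
#' @return hazard (events per year), strictly positive.
#' @export
hazard <- function(model, params, b_i, t, patient, encounter_ages = NULL) {
  if (is.numeric(params) && !is.list(params)) params <- params_unpack(params, model)
  p <- as_patient_row(patient)
  h <- exp(hazard_lp(model, params, b_i, t, p, encounter_ages))
  if (any(!is.finite(h))) stop("non-finite hazard at age ", t[which(!is.finite(h))[1]])
  h
}

## Gauss-Legendre nodes/weights on [0,1], cached by order
gl_unit <- local({
  cache <- list()
  function(order) {
    key <- as.character(order)
    if (is.null(cache[[key]])) {
      g <- pracma::gaussLegendre(order, 0, 1)
      cache[[key]] <<- g
    }
    cache[[key]]
  }
})

## piece boundaries for quadrature: split at switch ages inside (t0, t1)
quad_pieces <- function(model, p, t0, t1) {
  sw <- unique(unlist(lapply(union(model$event_tv_covariates,
                                   unlist(lapply(model$submodels, `[[`, "tv_covariates"))),
                             function(tv) {
    col <- paste0(tv, "_age")
    if (col %in% names(p)) p[[col]][1] else NA_real_
  })))
  sw <- sw[is.finite(sw) & sw > t0 & sw < t1]
  sort(unique(c(t0, sw, t1)))
}

#' Cumulative hazard over an age interval
#'
#' Integrates the subject-specific hazard by fixed-order Gauss–Legendre
#' quadrature applied piecewise between covariate switch ages, where the
#' integrand is smooth.
#'
#' @inheritParams longitudinal_mean
#' @param t0,t1 interval bounds (years), `t0 <= t1`.
#' @param order quadrature order per smooth piece.
#' @return nonnegative scalar, additive over abutting intervals.
#' @export
cumulative_hazard <- function(model, params, b_i, t0, t1, patient,
                              encounter_ages = NULL, order = 15L) {
  if (t0 > t1) stop("t0 must not exceed t1")
  if (t0 == t1) return(0)
  if (is.numeric(params) && !is.list(params)) params <- params_unpack(params, model)
  p <- as_patient_row(patient)
  ## yearly sub-pieces anchored at integer ages, so abutting intervals share
  ## an identical decomposition and the integral is additive to machine
  ## precision
  yr <- seq(ceiling(t0), floor(t1))
  br <- sort(unique(c(quad_pieces(model, p, t0, t1), yr[yr > t0 & yr < t1])))
  g <- gl_unit(order)
  total <- 0
  for (j in seq_len(length(br) - 1L)) {
    a <- br[j]; b <- br[j + 1L]
    tt <- a + (b - a) * g$x
    h <- exp(hazard_lp(model, params, b_i, tt, p, encounter_ages))
    total <- total + (b - a) * sum(g$w * h)
  }
  total
}

#' Event-free (survival) probability over an age interval
#'
#' S(t0, t1) = exp(-integral of the hazard), conditional on being event-free
#' at `t0`; supports delayed entry and dynamic prediction.
#'
#' @inheritParams cumulative_hazard
#' @return probability in (0, 1]; exactly 1 when `t0 == t1`.
#' @export
survival_probability <- function(model, params, b_i, t0, t1, patient,
                                 encounter_ages = NULL, order = 15L) {
  exp(-cumulative_hazard(model, params, b_i, t0, t1, patient,
                         encounter_ages = encounter_ages, order = order))
}
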