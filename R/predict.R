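## Subject-specific dynamic prediction: the exacerbation-free probability
## over (landmark, horizon] for a patient event-free at the landmark, with
## the biomarker history up to the landmark, averaging over posterior
## parameter draws and the conditional distribution of the patient's random
## effects (the standard subject-specific joint-model predictor).

#' Patient history up to a landmark age
#'
#' The conditioning set of a dynamic prediction: baseline covariates and
#' switch ages, biomarker observations at ages up to the landmark, and the
#' fact that the patient is exacerbation-free at the landmark.
#'
#' @param patient one-row data.frame of covariates (as in the event table;
#'   `entry_age` required, event status unknown).
#' @param observations data.frame `patient_id, age, outcome, value`.
#' @param landmark_age years; observations after it are dropped.
#' @return an object of class `cfj_history`.
#' @export
patient_history <- function(patient, observations, landmark_age) {
  patient <- as.data.frame(patient)
  stopifnot(nrow(patient) == 1L)
  obs <- as.data.frame(observations)
  obs <- obs[obs$age <= landmark_age + 1e-9, , drop = FALSE]
  if (landmark_age <= patient$entry_age)
    stop("landmark_age must exceed the patient's entry age")
  structure(list(patient = patient, observations = obs,
                 landmark_age = landmark_age),
            class = "cfj_history")
}

## a one-patient design bundle conditioned on being event-free at landmark:
## exit = landmark, delta = 0
history_jmdata <- function(model, history) {
  p <- history$patient
  p$exit_age <- history$landmark_age
  p$event <- 0L
  obs <- history$observations
  pid <- as.character(p$patient_id %||% "X")
  if (is.na(pid) || !length(pid)) pid <- "X"
  p$patient_id <- pid
  if (nrow(obs)) obs$patient_id <- pid
  cohort <- cohort_data(obs, p, window = model$window, validate = FALSE)
  prepare_jm_data(model, cohort)
}

#' Draw random effects conditional on a patient's history
#'
#' Samples p(b | history, event-free at landmark, theta) by independence
#' Metropolis-Hastings with a normal proposal centred at the conditional
#' mode and scaled by the local curvature.
#'
#' @param history a [patient_history()].
#' @param model prepared [joint_model_spec()].
#' @param theta_draw parameter list or packed vector (one posterior draw).
#' @param n number of retained draws.
#' @param burn_in discarded MH steps.
#' @param jd optional precomputed [history_jmdata] bundle (internal reuse).
#' @param mode optional precomputed mode/curvature (internal reuse).
#' @return matrix `n` x (random-effect dimension); acceptance rate in
#'   `attr(, "acceptance")`.
#' @export
sample_conditional_random_effects <- function(history, model, theta_draw, n = 1L,
                                              burn_in = 20L, jd = NULL, mode = NULL) {
  if (!inherits(history, "cfj_history")) stop("history must be a patient_history()")
  if (is.null(jd)) jd <- history_jmdata(model, history)
  params <- if (is.list(theta_draw)) theta_draw else params_unpack(theta_draw, jd$model)
  d <- n_random(jd$model)
  fn <- patient_loglik_fn(jd, 1L, params, include_prior = TRUE)
  if (is.null(mode)) mode <- patient_re_mode(fn, d)
  Lc <- t(chol(mobj_cov(mode)))
  n_tot <- n + burn_in
  prop <- sweep(matrix(stats::rnorm(n_tot * d), n_tot, d) %*% t(Lc), 2, mode$mode, `+`)
  lp_target <- fn(prop)
  dev <- sweep(prop, 2, mode$mode)
  sol <- forwardsolve(Lc, t(dev))
  lp_prop <- -0.5 * colSums(sol^2)
  w <- lp_target - lp_prop
  cur <- 1L
  keep <- integer(n_tot)
  n_acc <- 0L
  u <- log(stats::runif(n_tot))
  for (j in seq_len(n_tot)) {
    if (u[j] < w[j] - w[cur] || j == 1L) { cur <- j; n_acc <- n_acc + 1L }
    keep[j] <- cur
  }
  out <- prop[keep[(burn_in + 1L):n_tot], , drop = FALSE]
  attr(out, "acceptance") <- n_acc / n_tot
  out
}

mobj_cov <- function(mode) {
  C <- mode$cov
  (C + t(C)) / 2
}

## Precomputed quadrature designs for forecasting S(t0, h) at several
## horizons for one patient: segments split at switch ages and horizon
## boundaries, Gauss-Legendre nodes per segment, all design matrices built
## once so each posterior draw costs a few small matrix products.
forecast_nodes <- function(model, p, t0, horizons, enc, order = 15L) {
  hmax <- max(horizons)
  if (hmax <= t0 + 1e-12)
    return(list(empty = TRUE, horizons = horizons, t0 = t0))
  br <- sort(unique(c(t0, pmin(pmax(horizons, t0), hmax),
                      quad_pieces(model, p, t0, hmax))))
  g <- gl_unit(order)
  nseg <- length(br) - 1L
  age <- w <- numeric(0); seg <- integer(0)
  for (j in seq_len(nseg)) {
    a <- br[j]; b <- br[j + 1L]
    age <- c(age, a + (b - a) * g$x)
    w <- c(w, (b - a) * g$w)
    seg <- c(seg, rep.int(j, order))
  }
  any_enc <- any(vapply(model$submodels, `[[`, logical(1), "encounter_count"))
  idx <- rep(1L, length(age))
  B <- baseline_design(model, age)
  W <- event_design(model, p, idx, age)
  X <- Z <- list()
  for (k in model$outcomes) {
    e <- if (model$submodels[[k]]$encounter_count)
      findInterval(age, enc) - findInterval(age - 1, enc, left.open = TRUE) else NULL
    X[[k]] <- long_fixed_design(model, k, p, idx, age, enc = e)
    Z[[k]] <- long_random_design(model, k, age)
  }
  ## horizon h includes all segments ending at or before h
  seg_count <- vapply(horizons, function(h) sum(br[-1] <= h + 1e-12), integer(1))
  list(empty = FALSE, B = B, W = W, X = X, Z = Z, w = w, seg = seg,
       nseg = nseg, seg_count = seg_count, horizons = horizons, t0 = t0,
       centering = model$centering)
}

## conditional survival at each horizon for one (params, b) draw
forecast_survival <- function(nodes, model, params, b_i) {
  if (isTRUE(nodes$empty)) return(rep(1, length(nodes$horizons)))
  lp <- drop(nodes$B %*% params$theta)
  if (ncol(nodes$W)) lp <- lp + drop(nodes$W %*% params$gamma)
  cols <- re_cols(model)
  for (j in seq_along(model$outcomes)) {
    k <- model$outcomes[j]
    m <- drop(nodes$X[[k]] %*% params$beta[[k]]) +
      drop(nodes$Z[[k]] %*% b_i[cols[[k]]])
    lp <- lp + params$a[[j]] * (m - nodes$centering[[k]])
  }
  seg_int <- group_sum(nodes$w * exp(lp), nodes$seg, nodes$nseg)
  cum <- cumsum(seg_int)
  S <- ifelse(nodes$seg_count == 0L, 1, exp(-cum[pmax(nodes$seg_count, 1L)]))
  as.numeric(S)
}

#' Dynamic exacerbation-free probability
#'
#' Monte-Carlo estimate of Pr(event-free through `horizon_age` | event-free
#' at the landmark, history, data): whole parameter draws are sampled from
#' the posterior, the patient's random effects are drawn conditionally on the
#' history under each, and the conditional survival
#' S(landmark, horizon | b, theta) is averaged. The credible interval is the
#' central band of the Monte-Carlo distribution of that conditional survival.
#'
#' @param history a [patient_history()].
#' @param posterior a `cfj_posterior` from [fit_mcmc()].
#' @param horizon_age one or more horizon ages (>= landmark).
#' @param n_mc number of posterior parameter draws (1 conditional
#'   random-effect draw each).
#' @param seed integer.
#' @param level credible level of the band.
#' @return data.frame of class `cfj_prediction` with one row per horizon:
#'   `landmark_age, horizon_age, estimate, lower, upper, n_monte_carlo`.
#' @export
pe_free_probability <- function(history, posterior, horizon_age, n_mc = 200L,
                                seed = 1L, level = 0.95) {
  stopifnot(inherits(posterior, "cfj_posterior"))
  if (any(horizon_age < history$landmark_age - 1e-9))
    stop("horizon_age must be at least landmark_age")
  if (n_mc < 50L) warning("n_mc below 50 gives imprecise credible bands")
  model <- posterior$model
  jd <- history_jmdata(model, history)
  t0 <- history$landmark_age
  enc <- sort(unique(history$observations$age))
  p <- jd$patients[1, , drop = FALSE]
  nodes <- forecast_nodes(model, p, t0, horizon_age, enc)
  S <- matrix(NA_real_, n_mc, length(horizon_age))
  with_seed(derive_seed(seed, "dynpred"), {
    rows <- sample.int(nrow(posterior$draws), n_mc, replace = TRUE)
    ## mode/curvature at the posterior-mean parameters, reused as the
    ## proposal anchor for every draw
    pm <- params_unpack(colMeans(posterior$draws), model)
    fn <- patient_loglik_fn(jd, 1L, pm, include_prior = TRUE)
    anchor <- patient_re_mode(fn, n_random(model))
    for (j in seq_len(n_mc)) {
      prm <- params_unpack(posterior$draws[rows[j], ], model)
      bj <- sample_conditional_random_effects(history, model, prm, n = 1L,
                                              burn_in = 15L, jd = jd, mode = anchor)
      S[j, ] <- forecast_survival(nodes, model, prm, drop(bj))
    }
  })
  alpha <- (1 - level) / 2
  out <- data.frame(landmark_age = t0, horizon_age = horizon_age,
                    estimate = colMeans(S),
                    lower = apply(S, 2, stats::quantile, alpha),
                    upper = apply(S, 2, stats::quantile, 1 - alpha),
                    n_monte_carlo = n_mc)
  class(out) <- c("cfj_prediction", "data.frame")
  out
}
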