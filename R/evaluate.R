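## Predictive-performance evaluation: Kaplan-Meier on the age scale with
## delayed entry, landmark/window time-dependent AUC, the subsample
## cross-validation harness, and parameter-recovery reporting.

#' Kaplan-Meier estimate of time to first exacerbation
#'
#' Product-limit estimator on the age scale with delayed entry (a patient is
#' in the risk set at ages between entry and exit), Greenwood-based
#' confidence bands, and the median onset age (earliest age with survival
#' at or below one half; `NA` when never reached).
#'
#' @param patients per-patient event table (`entry_age`, `exit_age`, `event`)
#'   or a [cohort_data()] object.
#' @param conf_level confidence level.
#' @return object of class `cfj_km`: `curve` (data.frame `age, survival,
#'   lower, upper, n_risk, n_event`), `median` and `median_ci`.
#' @export
kaplan_meier <- function(patients, conf_level = 0.95) {
  if (inherits(patients, "cfj_cohort")) patients <- patients$patients
  stopifnot(nrow(patients) >= 1)
  fit <- survival::survfit(
    survival::Surv(entry_age, exit_age, event) ~ 1,
    data = patients, conf.int = conf_level, conf.type = "log")
  curve <- data.frame(age = fit$time, survival = fit$surv,
                      lower = fit$lower, upper = fit$upper,
                      n_risk = fit$n.risk, n_event = fit$n.event)
  ## median: earliest age at which the curve drops to one half or below
  med <- if (any(curve$survival <= 0.5)) min(curve$age[curve$survival <= 0.5]) else NA_real_
  qs <- stats::quantile(fit, probs = 0.5)
  med_ci <- c(unname(qs$lower), unname(qs$upper))
  structure(list(curve = curve, median = med, median_ci = med_ci,
                 conf_level = conf_level), class = "cfj_km")
}

#' @export
print.cfj_km <- function(x, ...) {
  cat(sprintf("<cfj_km> %d distinct ages; median onset %s (%.0f%% CI %s-%s)\n",
              nrow(x$curve),
              if (is.na(x$median)) "not reached" else sprintf("%.2f y", x$median),
              100 * x$conf_level,
              ifelse(is.na(x$median_ci[1]), "NA", sprintf("%.2f", x$median_ci[1])),
              ifelse(is.na(x$median_ci[2]), "NA", sprintf("%.2f", x$median_ci[2]))))
  invisible(x)
}

#' Landmark/window time-dependent AUC
#'
#' Discrimination of predicted risks over the window (t, t + w]: among pairs
#' where one patient has an observed event inside the window (case) and the
#' other is known event-free through its end (control), the proportion in
#' which the case received the higher risk (ties count one half). Patients
#' censored inside the window are excluded from pair formation.
#'
#' @param risk named numeric vector of predicted risks (1 minus the
#'   event-free probability at t + w), names = patient ids; must cover every
#'   patient at risk at the landmark.
#' @param patients event table (or [cohort_data()]).
#' @param landmark landmark age t (years).
#' @param window prediction window w (years).
#' @return data.frame row of class `cfj_auc`: `landmark_age, window, auc,
#'   n_cases, n_controls, n_comparable_pairs` (`auc` is `NA` with zero pairs).
#' @export
dynamic_auc <- function(risk, patients, landmark, window) {
  if (inherits(patients, "cfj_cohort")) patients <- patients$patients
  at_risk <- patients$entry_age < landmark & patients$exit_age > landmark
  p <- patients[at_risk, , drop = FALSE]
  end <- landmark + window
  case <- p$event == 1 & p$exit_age <= end
  control <- p$exit_age > end
  ids_case <- p$patient_id[case]; ids_ctrl <- p$patient_id[control]
  miss <- setdiff(c(ids_case, ids_ctrl), names(risk))
  if (length(miss))
    stop("risk scores missing for patient(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  x <- risk[ids_case]; y <- risk[ids_ctrl]
  n1 <- length(x); n0 <- length(y)
  auc <- if (n1 == 0 || n0 == 0) NA_real_ else {
    r <- rank(c(x, y))
    (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  out <- data.frame(landmark_age = landmark, window = window, auc = auc,
                    n_cases = n1, n_controls = n0,
                    n_comparable_pairs = n1 * n0)
  class(out) <- c("cfj_auc", "data.frame")
  out
}

#' Cross-validation control settings
#'
#' The reference procedure subsamples 700 patients, splits them into 5
#' patient-level folds, fits on 4 and computes the landmark AUC on the held
#' out fold, repeating 100 times; all of that is configuration here.
#'
#' @param n_folds folds per repetition (>= 2).
#' @param subsample_size patients drawn per repetition.
#' @param n_repetitions repetitions.
#' @param landmark_ages landmark ages (years).
#' @param windows prediction windows (years).
#' @param n_mc posterior draws per patient-level prediction.
#' @param seed integer; folds, subsamples and fit seeds all derive from it.
#' @return an object of class `cfj_cv_control`.
#' @export
cv_control <- function(n_folds = 5L, subsample_size = 700L, n_repetitions = 100L,
                       landmark_ages = c(12, 16), windows = c(0.5, 1, 2),
                       n_mc = 50L, seed = 1L) {
  if (n_mc < 50L) warning("n_mc below 50 gives imprecise risk estimates")
  if (n_folds < 2L) stop("n_folds must be at least 2")
  structure(list(n_folds = as.integer(n_folds),
                 subsample_size = as.integer(subsample_size),
                 n_repetitions = as.integer(n_repetitions),
                 landmark_ages = landmark_ages, windows = windows,
                 n_mc = as.integer(n_mc), seed = as.integer(seed)),
            class = "cfj_cv_control")
}

## risks for every at-risk patient of a test cohort at one landmark
landmark_risks <- function(test, posterior, landmark, windows, n_mc, seed) {
  pats <- test$patients
  at_risk <- pats$entry_age < landmark & pats$exit_age > landmark
  ids <- pats$patient_id[at_risk]
  out <- matrix(NA_real_, length(ids), length(windows),
                dimnames = list(ids, NULL))
  for (i in seq_along(ids)) {
    obs_i <- test$observations[test$observations$patient_id == ids[i] &
                                 test$observations$age <= landmark + 1e-9, , drop = FALSE]
    if (!nrow(obs_i)) next
    hist_i <- patient_history(pats[pats$patient_id == ids[i], , drop = FALSE],
                              obs_i, landmark)
    pred <- pe_free_probability(hist_i, posterior, landmark + windows,
                                n_mc = n_mc, seed = derive_seed(seed, ids[i]))
    out[i, ] <- 1 - pred$estimate
  }
  out
}

#' Cross-validated landmark AUC
#'
#' Per repetition: subsample patients, split into patient-level folds, fit
#' the joint model on the training folds, compute each held-out patient's
#' dynamically predicted risk at every landmark, and score the landmark AUC
#' per window. Returns every replicate cell for box-plot style summaries.
#'
#' @param cohort a [cohort_data()] object.
#' @param model a [joint_model_spec()].
#' @param priors a [cfj_priors()].
#' @param mcmc a [mcmc_control()] used for each training fit.
#' @param cv a [cv_control()].
#' @return data.frame with columns `replicate_id, fold, landmark_age, window,
#'   auc, n_cases, n_controls, n_comparable_pairs`.
#' @export
cross_validated_auc <- function(cohort, model, priors = cfj_priors(),
                                mcmc = mcmc_control(), cv = cv_control()) {
  stopifnot(inherits(cohort, "cfj_cohort"), inherits(cv, "cfj_cv_control"))
  pats <- cohort$patients
  if (cv$subsample_size > nrow(pats))
    stop("subsample_size exceeds the cohort size")
  res <- list()
  for (rep_i in seq_len(cv$n_repetitions)) {
    rep_seed <- derive_seed(cv$seed, paste0("cvrep", rep_i))
    with_seed(rep_seed, {
      ids <- sample(pats$patient_id, cv$subsample_size)
      fold_of <- stats::setNames(sample(rep_len(seq_len(cv$n_folds),
                                                cv$subsample_size)), ids)
    })
    sub <- subset_cohort(cohort, ids)
    for (f in seq_len(cv$n_folds)) {
      test_ids <- ids[fold_of[ids] == f]
      train <- subset_cohort(sub, setdiff(ids, test_ids))
      test <- subset_cohort(sub, test_ids)
      ctl <- mcmc
      ctl$seed <- derive_seed(rep_seed, paste0("fold", f))
      m <- prepare_model(model, train)
      fit <- fit_mcmc(train, m, priors, ctl)
      for (t in cv$landmark_ages) {
        risks <- landmark_risks(test, fit, t, cv$windows, cv$n_mc,
                                seed = derive_seed(ctl$seed, paste0("lm", t)))
        for (wi in seq_along(cv$windows)) {
          r <- risks[, wi]
          r <- r[!is.na(r)]
          cell <- if (length(r))
            dynamic_auc(r, restrict_patients(test$patients, names(r)), t, cv$windows[wi])
          else data.frame(landmark_age = t, window = cv$windows[wi], auc = NA_real_,
                          n_cases = 0L, n_controls = 0L, n_comparable_pairs = 0L)
          cell$replicate_id <- rep_i; cell$fold <- f
          res[[length(res) + 1L]] <- cell
        }
      }
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[, c("replicate_id", "fold", "landmark_age", "window", "auc",
          "n_cases", "n_controls", "n_comparable_pairs")]
}

subset_cohort <- function(cohort, ids) {
  cohort_data(cohort$observations[cohort$observations$patient_id %in% ids, , drop = FALSE],
              cohort$patients[cohort$patients$patient_id %in% ids, , drop = FALSE],
              window = cohort$window, validate = FALSE)
}

restrict_patients <- function(patients, ids) {
  patients[patients$patient_id %in% ids, , drop = FALSE]
}

#' Parameter-recovery report over simulation replicates
#'
#' Monte-Carlo bias, RMSE and HPD coverage per parameter, comparing posterior
#' summaries from replicate fits against the generating values. Parameters
#' are matched by name; truth entries without a fitted counterpart (e.g. a
#' parametric generating baseline against a fitted spline baseline) are
#' ignored, but an empty intersection is an error.
#'
#' @param truth named numeric vector of generating values (`cfj_truth$flat`)
#'   or a `cfj_truth`.
#' @param summaries list of [posterior_summary()] data.frames, one per
#'   replicate.
#' @return data.frame: `parameter, truth, bias, rmse, coverage, n_replicates`.
#' @export
parameter_recovery_report <- function(truth, summaries) {
  if (inherits(truth, "cfj_truth")) truth <- truth$flat
  stopifnot(length(summaries) >= 1)
  common <- Reduce(intersect, c(list(names(truth)),
                                lapply(summaries, `[[`, "parameter")))
  if (!length(common))
    stop("no parameters in common between truth and fitted summaries")
  rows <- lapply(common, function(p) {
    est <- vapply(summaries, function(s) s$mean[s$parameter == p], 0)
    lo <- vapply(summaries, function(s) s$hpd_lower[s$parameter == p], 0)
    hi <- vapply(summaries, function(s) s$hpd_upper[s$parameter == p], 0)
    tv <- truth[[p]]
    data.frame(parameter = p, truth = tv, bias = mean(est) - tv,
               rmse = sqrt(mean((est - tv)^2)),
               coverage = mean(lo <= tv & tv <= hi),
               n_replicates = length(summaries))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
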