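## Cohort containers and plumbing: long-format biomarker observations plus a
## one-row-per-patient event table, natural cubic spline bases, the
## encounter-frequency covariate, and event-stratified shard splitting.

OUTCOME_NAMES <- c("FEV1", "BMIp", "WFA", "HFA")
SWITCH_COVARIATES <- c("mrsa", "pa", "cfrd", "enzymes")

#' Assemble a cohort from observation and patient tables
#'
#' A cohort couples a long-format table of biomarker measurements (one row per
#' encounter and outcome) with a per-patient event table carrying entry age,
#' exit age, the exacerbation indicator, baseline covariates and onset ages of
#' the time-varying binary covariates (MRSA, Pa, CFRD, pancreatic enzymes —
#' step functions that switch on once and stay on).
#'
#' @param observations data.frame with columns `patient_id`, `age` (decimal
#'   years), `outcome` (one of FEV1, BMIp, WFA, HFA) and `value` (FEV1 in
#'   percent predicted, growth outcomes as percentiles in \[0, 100\]).
#' @param patients data.frame with columns `patient_id`, `entry_age`,
#'   `exit_age`, `event` (1 = exacerbation observed at `exit_age`), optional
#'   baseline covariate columns and optional `<name>_age` switch-age columns
#'   (`NA` = never switches on).
#' @param window eligibility window in years of age; observations outside it
#'   are invalid.
#' @param validate check invariants (referential integrity, entry < exit,
#'   value ranges, ages within each patient's follow-up window).
#' @return an object of class `cfj_cohort` with elements `observations`,
#'   `patients` and `window`.
#' @export
cohort_data <- function(observations, patients, window = c(6, 20), validate = TRUE) {
  observations <- as.data.frame(observations)
  patients <- as.data.frame(patients)
  need_obs <- c("patient_id", "age", "outcome", "value")
  need_pat <- c("patient_id", "entry_age", "exit_age", "event")
  miss <- setdiff(need_obs, names(observations))
  if (length(miss)) stop("observations table missing column(s): ", paste(miss, collapse = ", "))
  miss <- setdiff(need_pat, names(patients))
  if (length(miss)) stop("patient table missing column(s): ", paste(miss, collapse = ", "))
  observations$patient_id <- as.character(observations$patient_id)
  patients$patient_id <- as.character(patients$patient_id)
  x <- structure(list(observations = observations, patients = patients,
                      window = as.numeric(window)),
                 class = "cfj_cohort")
  if (validate) validate_cohort(x)
  x
}

validate_cohort <- function(x) {
  obs <- x$observations; pat <- x$patients
  if (anyDuplicated(pat$patient_id))
    stop("duplicated patient_id in patient table")
  bad <- pat$entry_age >= pat$exit_age
  if (any(bad))
    stop("entry_age >= exit_age for patient(s): ",
         paste(utils::head(pat$patient_id[bad], 5), collapse = ", "))
  if (!all(pat$event %in% c(0, 1))) stop("event must be 0 or 1")
  unknown <- !(obs$patient_id %in% pat$patient_id)
  if (any(unknown))
    stop("observation references unknown patient(s): ",
         paste(utils::head(unique(obs$patient_id[unknown]), 5), collapse = ", "))
  if (!all(obs$outcome %in% OUTCOME_NAMES))
    stop("unknown outcome name(s): ",
         paste(setdiff(unique(obs$outcome), OUTCOME_NAMES), collapse = ", "))
  pct <- obs$outcome %in% c("BMIp", "WFA", "HFA")
  if (any(obs$value[pct] < 0 | obs$value[pct] > 100, na.rm = TRUE))
    stop("percentile outcomes must lie in [0, 100]")
  if (any(obs$value[obs$outcome == "FEV1"] <= 0, na.rm = TRUE))
    stop("FEV1 values must be positive")
  if (any(obs$age < x$window[1] - 1e-9 | obs$age > x$window[2] + 1e-9))
    stop("observation age outside eligibility window [",
         x$window[1], ", ", x$window[2], "]")
  idx <- match(obs$patient_id, pat$patient_id)
  out_of_fu <- obs$age < pat$entry_age[idx] - 1e-9 | obs$age > pat$exit_age[idx] + 1e-9
  if (any(out_of_fu))
    stop("observation age outside the patient's follow-up window for patient(s): ",
         paste(utils::head(unique(obs$patient_id[out_of_fu]), 5), collapse = ", "))
  sw <- intersect(paste0(SWITCH_COVARIATES, "_age"), names(pat))
  for (s in sw) {
    v <- pat[[s]]
    if (any(is.finite(v) & v < 0)) stop("negative switch age in column ", s)
  }
  invisible(x)
}

#' @export
print.cfj_cohort <- function(x, ...) {
  ev <- sum(x$patients$event)
  cat(sprintf("<cfj_cohort> %d patients, %d observations, %d events (%.1f%%)\n",
              nrow(x$patients), nrow(x$observations), ev,
              100 * ev / max(1, nrow(x$patients))))
  cat(sprintf("  outcomes: %s; eligibility window [%g, %g] years\n",
              paste(sort(unique(x$observations$outcome)), collapse = ", "),
              x$window[1], x$window[2]))
  invisible(x)
}

#' Read a cohort from delimited text
#'
#' Reads the two-file CSV interchange format (long observation table and
#' per-patient event table). Observation rows whose age falls outside the
#' eligibility window, or outside their patient's follow-up interval, are
#' dropped with a logged count; structural problems are errors.
#'
#' @param observations_path CSV with columns `patient_id,age,outcome,value`.
#' @param events_path CSV with columns `patient_id,entry_age,exit_age,event`
#'   plus covariate columns (empty switch-age cell = never switches on).
#' @param window eligibility window in years of age.
#' @return a [cohort_data()] object; the number of dropped rows is available
#'   as `attr(x, "dropped")`.
#' @export
read_long_cohort <- function(observations_path, events_path, window = c(6, 20)) {
  if (!file.exists(observations_path)) stop("no such file: ", observations_path)
  if (!file.exists(events_path)) stop("no such file: ", events_path)
  obs <- utils::read.csv(observations_path, stringsAsFactors = FALSE)
  pat <- utils::read.csv(events_path, stringsAsFactors = FALSE)
  need_obs <- c("patient_id", "age", "outcome", "value")
  need_pat <- c("patient_id", "entry_age", "exit_age", "event")
  miss <- c(setdiff(need_obs, names(obs)), setdiff(need_pat, names(pat)))
  if (length(miss)) stop("missing required column(s): ", paste(miss, collapse = ", "))
  obs$patient_id <- as.character(obs$patient_id)
  pat$patient_id <- as.character(pat$patient_id)
  bad <- pat$entry_age >= pat$exit_age
  if (any(bad))
    stop("entry_age >= exit_age for patient(s): ",
         paste(utils::head(pat$patient_id[bad], 5), collapse = ", "))
  keep <- obs$age >= window[1] - 1e-9 & obs$age <= window[2] + 1e-9
  idx <- match(obs$patient_id, pat$patient_id)
  if (anyNA(idx))
    stop("observation references unknown patient(s): ",
         paste(utils::head(unique(obs$patient_id[is.na(idx)]), 5), collapse = ", "))
  keep <- keep & obs$age >= pat$entry_age[idx] - 1e-9 & obs$age <= pat$exit_age[idx] + 1e-9
  dropped <- sum(!keep)
  if (dropped > 0)
    cfj_log(1L, sprintf("dropped %d observation row(s) outside the eligibility window", dropped))
  x <- cohort_data(obs[keep, , drop = FALSE], pat, window = window)
  attr(x, "dropped") <- dropped
  x
}

#' Write a cohort to the two-file CSV interchange format
#'
#' @param cohort a [cohort_data()] object.
#' @param observations_path,events_path output CSV paths.
#' @return the input, invisibly.
#' @export
write_cohort <- function(cohort, observations_path, events_path) {
  stopifnot(inherits(cohort, "cfj_cohort"))
  utils::write.csv(cohort$observations, observations_path, row.names = FALSE, na = "")
  utils::write.csv(cohort$patients, events_path, row.names = FALSE, na = "")
  invisible(cohort)
}

## ---- natural cubic spline bases -------------------------------------------

#' Natural cubic spline basis specification
#'
#' The basis has exactly `df` columns, is cubic between the boundary knots and
#' linear beyond them (natural constraint). When `interior_knots` is `NULL`
#' they are placed at equally spaced quantiles of the ages supplied to
#' [build_spline_basis()] (df − 1 interior knots).
#'
#' @param df degrees of freedom (number of basis columns), at least 1.
#' @param boundary_knots ages (years) delimiting the cubic range; defaults to
#'   the 6–20 year eligibility window.
#' @param interior_knots optional explicit interior knot ages.
#' @return an object of class `cfj_spline_spec`.
#' @export
spline_basis_spec <- function(df, boundary_knots = c(6, 20), interior_knots = NULL) {
  df <- as.integer(df)
  if (is.na(df) || df < 1L) stop("spline degrees of freedom must be an integer >= 1")
  structure(list(df = df, boundary_knots = as.numeric(boundary_knots),
                 interior_knots = interior_knots),
            class = "cfj_spline_spec")
}

## fill data-driven interior knots so later evaluations reuse the same basis
resolve_spline_spec <- function(spec, ages) {
  if (!is.null(spec$interior_knots) || spec$df == 1L) {
    if (is.null(spec$interior_knots)) spec$interior_knots <- numeric(0)
    return(spec)
  }
  probs <- seq_len(spec$df - 1L) / spec$df
  k <- unname(stats::quantile(ages, probs = probs, type = 7))
  if (anyDuplicated(k) || length(unique(ages)) < spec$df + 1L)
    stop("too few distinct ages to place ", spec$df - 1L, " interior knot(s)")
  spec$interior_knots <- k
  spec
}

#' Evaluate a natural cubic spline basis
#'
#' @param ages evaluation ages (years); extrapolation beyond the boundary
#'   knots is linear.
#' @param spec a [spline_basis_spec()].
#' @return numeric matrix with `length(ages)` rows and `spec$df` columns.
#' @export
build_spline_basis <- function(ages, spec) {
  stopifnot(inherits(spec, "cfj_spline_spec"))
  if (!all(is.finite(ages))) stop("ages must be finite")
  if (!length(ages))
    return(matrix(0, 0, spec$df, dimnames = list(NULL, paste0("ns", seq_len(spec$df)))))
  spec <- resolve_spline_spec(spec, ages)
  if (spec$df == 1L) {
    b <- splines::ns(ages, Boundary.knots = spec$boundary_knots, df = 1)
  } else {
    b <- splines::ns(ages, knots = spec$interior_knots,
                     Boundary.knots = spec$boundary_knots)
  }
  m <- unclass(b)[, , drop = FALSE]
  attributes(m) <- list(dim = dim(m), dimnames = list(NULL, paste0("ns", seq_len(ncol(m)))))
  if (ncol(m) != spec$df) stop("internal: basis column count != df")
  m
}

## ---- encounter frequency ---------------------------------------------------

#' Number of encounters in the prior year
#'
#' Counts distinct encounter ages in the closed window [t − 1, t]; used as
#' a time-varying covariate to adjust for irregular sampling (patients seen
#' more often contribute more measurements). An encounter exactly one year
#' back counts: the covariate answers "how often was this patient seen in
#' the last year, including today and one year ago today".
#'
#' @param encounter_ages ages (years) of a patient's encounters.
#' @param t evaluation age(s); vectorised.
#' @return integer count(s).
#' @export
encounters_in_prior_year <- function(encounter_ages, t) {
  a <- sort(unique(encounter_ages))
  vapply(t, function(ti) sum(a >= ti - 1 & a <= ti), integer(1))
}

## ---- shard splitting -------------------------------------------------------

#' Split a cohort into event-balanced shards
#'
#' Patient-level partition into `n_shards` pieces, stratified on the event
#' indicator so every shard has (as nearly as possible) the cohort's overall
#' exacerbation fraction — the device used to fit very large registries in
#' memory-sized pieces whose posteriors are pooled afterwards.
#'
#' @param cohort a [cohort_data()] object.
#' @param n_shards number of pieces.
#' @param seed integer; the split is deterministic given the seed.
#' @return list of `n_shards` cohorts partitioning the input.
#' @export
split_into_shards <- function(cohort, n_shards, seed = 1L) {
  stopifnot(inherits(cohort, "cfj_cohort"))
  n_shards <- as.integer(n_shards)
  if (n_shards < 1L) stop("n_shards must be >= 1")
  pat <- cohort$patients
  if (n_shards > nrow(pat)) stop("n_shards exceeds the number of patients")
  if (n_shards == 1L) return(list(cohort))
  assign_shard <- integer(nrow(pat))
  with_seed(derive_seed(seed, "shards"), {
    for (ev in unique(pat$event)) {
      idx <- which(pat$event == ev)
      idx <- idx[sample.int(length(idx))]
      assign_shard[idx] <- rep_len(seq_len(n_shards), length(idx))
    }
  })
  lapply(seq_len(n_shards), function(s) {
    ids <- pat$patient_id[assign_shard == s]
    cohort_data(cohort$observations[cohort$observations$patient_id %in% ids, , drop = FALSE],
                pat[assign_shard == s, , drop = FALSE],
                window = cohort$window, validate = FALSE)
  })
}

## ---- covariate helpers -----------------------------------------------------

## dummy-code the registry's baseline covariates onto numeric columns
expand_patient_covariates <- function(patients) {
  p <- patients
  if ("sex" %in% names(p) && !is.numeric(p$sex))
    p$sex_male <- as.numeric(p$sex %in% c("M", "male", "Male", "1"))
  if ("sex" %in% names(p) && is.numeric(p$sex)) p$sex_male <- p$sex
  if ("genotype" %in% names(p)) {
    p$genotype_homozygous <- as.numeric(p$genotype == "homozygous")
    p$genotype_heterozygous <- as.numeric(p$genotype == "heterozygous")
  }
  if ("hispanic" %in% names(p)) p$hispanic <- as.numeric(p$hispanic)
  if ("ses" %in% names(p)) p$ses_low <- as.numeric(p$ses)
  if ("birth_cohort" %in% names(p) && !is.numeric(p$birth_cohort)) {
    lev <- c("<1981", "1981-1989", "1990-1994", "1995-1999", ">1999")
    for (l in lev[-1]) {
      nm <- paste0("bc_", gsub("[^0-9a-z]+", "_", tolower(l)))
      p[[nm]] <- as.numeric(p$birth_cohort == l)
    }
  }
  p
}

## value of a switch-on covariate (0/1) for given patients at given ages
switch_indicator <- function(patients, name, idx, ages) {
  col <- paste0(name, "_age")
  if (!col %in% names(patients)) return(numeric(length(ages)))
  sw <- patients[[col]][idx]
  as.numeric(!is.na(sw) & ages >= sw)
}
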