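## JSON round trips for model specifications and posterior draws, so that
## fits, predictions and evaluations can live in separate processes.

#' Write / read a model definition as JSON
#'
#' Captures the full prepared specification: outcomes, spline degrees of
#' freedom and knots, covariate lists, association structure, baseline-hazard
#' basis and centering constants.
#'
#' @param model a [joint_model_spec()] (prepared or not).
#' @param path JSON file path.
#' @return `model_to_json` the path, invisibly; `model_from_json` a
#'   `cfj_model`.
#' @export
model_to_json <- function(model, path) {
  stopifnot(inherits(model, "cfj_model"))
  subs <- lapply(model$submodels, function(s) {
    list(outcome = s$outcome, df = s$df, covariates = s$covariates,
         spline_interactions = s$spline_interactions,
         tv_covariates = s$tv_covariates, encounter_count = s$encounter_count,
         random = s$random,
         age_knots = if (!is.null(s$age_basis)) list(
           boundary = s$age_basis$boundary_knots,
           interior = s$age_basis$interior_knots) else NULL)
  })
  obj <- list(submodels = unname(subs),
              event_covariates = model$event_covariates,
              event_tv_covariates = model$event_tv_covariates,
              baseline_df = model$baseline_df, window = model$window,
              baseline_knots = if (!is.null(model$baseline_basis)) list(
                boundary = model$baseline_basis$boundary_knots,
                interior = model$baseline_basis$interior_knots) else NULL,
              centering = as.list(model$centering),
              prepared = model$prepared)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname model_to_json
#' @export
model_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sl <- obj$submodels
  n_sub <- length(sl$outcome)
  subs <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    s <- longitudinal_submodel(
      sl$outcome[i], df = sl$df[i],
      covariates = unlist(sl$covariates[i]) %||% character(0),
      spline_interactions = unlist(sl$spline_interactions[i]) %||% character(0),
      tv_covariates = unlist(sl$tv_covariates[i]) %||% character(0),
      encounter_count = isTRUE(sl$encounter_count[i]),
      random = sl$random[i])
    kn <- sl$age_knots
    if (!is.null(kn)) {
      s$age_basis <- spline_basis_spec(sl$df[i],
                                       boundary_knots = unlist(kn$boundary[i]),
                                       interior_knots = unlist(kn$interior[i]))
    }
    subs[[i]] <- s
  }
  model <- joint_model_spec(subs,
                            event_covariates = obj$event_covariates %||% character(0),
                            event_tv_covariates = obj$event_tv_covariates %||% character(0),
                            baseline_df = obj$baseline_df, window = obj$window)
  if (!is.null(obj$baseline_knots))
    model$baseline_basis <- spline_basis_spec(
      model$baseline_df - 1L,
      boundary_knots = unlist(obj$baseline_knots$boundary),
      interior_knots = unlist(obj$baseline_knots$interior))
  model$centering[] <- unlist(obj$centering)[model$outcomes]
  model$prepared <- isTRUE(obj$prepared)
  model
}

#' Write / read posterior draws
#'
#' Draws go to CSV (one column per parameter, one row per retained draw, an
#' optional `shard_id` column); [read_posterior()] restores a `cfj_posterior`
#' against a model definition.
#'
#' @param posterior a `cfj_posterior`.
#' @param path CSV file path.
#' @export
write_posterior <- function(posterior, path) {
  stopifnot(inherits(posterior, "cfj_posterior"))
  df <- as.data.frame(posterior$draws, check.names = FALSE)
  if (!is.null(posterior$shard_id)) df$shard_id <- posterior$shard_id
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_posterior
#' @param model the `cfj_model` the draws belong to.
#' @export
read_posterior <- function(path, model) {
  df <- utils::read.csv(path, check.names = FALSE)
  shard_id <- NULL
  if ("shard_id" %in% names(df)) {
    shard_id <- df$shard_id
    df$shard_id <- NULL
  }
  draws <- as.matrix(df)
  structure(list(draws = draws, model = model, control = NULL, priors = NULL,
                 acceptance = NULL,
                 diagnostics = data.frame(parameter = colnames(draws),
                                          ess = apply(draws, 2, ess_draws),
                                          rhat = apply(draws, 2, split_rhat),
                                          row.names = NULL),
                 b_draws = NULL, shard_id = shard_id, n_patients = NA_integer_),
            class = "cfj_posterior")
}
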