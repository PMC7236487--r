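## Posterior pooling across shards and summaries (HPD intervals, posterior
## tail probabilities reported like p-values).

#' Pool posterior draws from shard fits
#'
#' Default combining rule: simple concatenation of retained draws with equal
#' shard weight, keeping shard provenance. The pooled draw count is the sum
#' of the shard draw counts. The rule is isolated here because concatenation
#' does not account for all between-shard variability; alternative weightings
#' can be passed as `weights` (draws are then resampled proportionally).
#'
#' @param shard_fits list of `cfj_posterior` objects with one parameter layout.
#' @param weights optional per-shard weights for resampled pooling.
#' @return a pooled `cfj_posterior`.
#' @export
combine_shard_posteriors <- function(shard_fits, weights = NULL) {
  stopifnot(length(shard_fits) >= 1,
            all(vapply(shard_fits, inherits, logical(1), "cfj_posterior")))
  layouts <- lapply(shard_fits, function(f) colnames(f$draws))
  if (!all(vapply(layouts, identical, logical(1), layouts[[1]])))
    stop("shard fits do not share one parameter layout")
  mats <- lapply(shard_fits, `[[`, "draws")
  ids <- unlist(lapply(seq_along(mats), function(s)
    rep.int(s, nrow(mats[[s]]))))
  draws <- do.call(rbind, mats)
  if (!is.null(weights)) {
    stopifnot(length(weights) == length(shard_fits), all(weights >= 0))
    pr <- (weights / sum(weights))[ids] / tabulate(ids)[ids]
    keep <- sample.int(nrow(draws), nrow(draws), replace = TRUE, prob = pr)
    draws <- draws[keep, , drop = FALSE]; ids <- ids[keep]
  }
  out <- shard_fits[[1]]
  out$draws <- draws
  out$shard_id <- ids
  out$n_patients <- sum(vapply(shard_fits, `[[`, 0, "n_patients"))
  out$diagnostics <- data.frame(parameter = colnames(draws),
                                ess = apply(draws, 2, ess_draws),
                                rhat = apply(draws, 2, split_rhat),
                                row.names = NULL)
  out$acceptance <- Reduce(`+`, lapply(shard_fits, `[[`, "acceptance")) /
    length(shard_fits)
  out
}

## narrowest interval containing `level` mass, by sorted-window search
hpd_interval <- function(x, level = 0.95) {
  x <- sort(x)
  n <- length(x)
  m <- max(1L, ceiling(level * n))
  if (m >= n) return(c(x[1], x[n]))
  widths <- x[(m + 1):n] - x[1:(n - m)]
  j <- which.min(widths)
  c(x[j], x[j + m])
}

#' Summarise posterior draws
#'
#' Per parameter: posterior mean, SD, highest-posterior-density interval
#' (narrowest interval containing `level` mass) and the posterior tail
#' probability 2 min(Pr(>0), Pr(<0)), reported like a p-value.
#'
#' @param samples a `cfj_posterior` (or bare draw matrix with named columns).
#' @param level credibility level for the HPD interval.
#' @return data.frame with one row per parameter.
#' @export
posterior_summary <- function(samples, level = 0.95) {
  draws <- if (inherits(samples, "cfj_posterior")) samples$draws else as.matrix(samples)
  if (nrow(draws) < 100)
    warning("fewer than 100 retained draws; summaries are imprecise")
  hp <- t(apply(draws, 2, hpd_interval, level = level))
  data.frame(parameter = colnames(draws),
             mean = colMeans(draws),
             sd = apply(draws, 2, stats::sd),
             hpd_lower = hp[, 1], hpd_upper = hp[, 2],
             p = apply(draws, 2, function(x)
               min(1, 2 * min(mean(x > 0), mean(x < 0)))),
             row.names = NULL)
}

#' Fit a model on event-balanced shards and pool the posteriors
#'
#' The large-registry strategy: split the cohort into `n_shards` pieces with
#' matching event fractions, fit each by [fit_mcmc()], pool by
#' [combine_shard_posteriors()].
#'
#' @inheritParams fit_mcmc
#' @param n_shards number of pieces (1 = ordinary single fit).
#' @return list with `pooled` (a `cfj_posterior`) and `shards` (the per-shard
#'   fits).
#' @export
fit_mcmc_sharded <- function(cohort, model, n_shards = 3L,
                             priors = cfj_priors(), control = mcmc_control()) {
  model <- prepare_model(model, cohort)
  if (n_shards == 1L) {
    fit <- fit_mcmc(cohort, model, priors, control)
    return(list(pooled = fit, shards = list(fit)))
  }
  shards <- split_into_shards(cohort, n_shards, seed = control$seed)
  fits <- vector("list", n_shards)
  for (s in seq_len(n_shards)) {
    ctl <- control
    ctl$seed <- derive_seed(control$seed, paste0("shard", s))
    cfj_log(1L, sprintf("fitting shard %d/%d (%d patients, %.1f%% events)",
                        s, n_shards, nrow(shards[[s]]$patients),
                        100 * mean(shards[[s]]$patients$event)))
    fits[[s]] <- fit_mcmc(shards[[s]], model, priors, ctl)
    fits[[s]]$shard_id <- rep.int(s, nrow(fits[[s]]$draws))
  }
  list(pooled = combine_shard_posteriors(fits), shards = fits)
}
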