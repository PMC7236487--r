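## Bayesian estimation by blocked Metropolis-within-Gibbs:
##   - all patients' random effects in one vectorised MH sweep (conditionally
##     independent given the parameters, so acceptance is per patient)
##   - each beta_k by an independence proposal from its Gaussian longitudinal
##     full conditional, accepted on the survival likelihood ratio
##   - residual SDs by random-walk MH on the log scale (half-Cauchy prior)
##   - the random-effects covariance by its exact inverse-Wishart conditional
##   - the survival block (baseline-hazard coefficients, event covariates,
##     associations) by adaptive random-walk MH with empirical proposal
##     covariance, repeated several times per sweep (it is cheap and is where
##     the scientifically central a_k live)

#' MCMC control settings
#'
#' Defaults mirror the reference analysis (900 iterations, first 600
#' discarded); with only 300 retained draws the reported effective sample
#' sizes should always be checked, and longer runs used when they are low.
#'
#' @param n_iterations total Gibbs sweeps.
#' @param n_burn_in sweeps discarded (also the adaptation phase).
#' @param thinning keep every `thinning`-th retained sweep.
#' @param seed integer; draws are deterministic given it.
#' @param n_survival_inner survival-block repeats per sweep.
#' @param store_random_effects retain per-patient random-effect draws.
#' @param prior_only sample from the prior (likelihood switched off).
#' @return an object of class `cfj_mcmc_control`.
#' @export
mcmc_control <- function(n_iterations = 900L, n_burn_in = 600L, thinning = 1L,
                         seed = 1L, n_survival_inner = 5L,
                         store_random_effects = FALSE, prior_only = FALSE) {
  n_iterations <- as.integer(n_iterations); n_burn_in <- as.integer(n_burn_in)
  if (n_burn_in >= n_iterations) stop("n_burn_in must be smaller than n_iterations")
  if (thinning < 1L) stop("thinning must be >= 1")
  structure(list(n_iterations = n_iterations, n_burn_in = n_burn_in,
                 thinning = as.integer(thinning), seed = as.integer(seed),
                 n_survival_inner = as.integer(n_survival_inner),
                 store_random_effects = isTRUE(store_random_effects),
                 prior_only = isTRUE(prior_only)),
            class = "cfj_mcmc_control")
}

#' Prior settings
#'
#' Weakly informative defaults: zero-mean normals with large scales on the
#' regression, association and baseline-hazard coefficients; half-Cauchy on
#' the residual SDs; inverse-Wishart (df = dim + 2, identity scale) on the
#' random-effects covariance.
#'
#' @param beta_scale,gamma_scale,a_scale,theta_scale normal prior SDs.
#' @param sigma_scale half-Cauchy scale for residual SDs.
#' @param Sigma_df_add added to the random-effect dimension for the
#'   inverse-Wishart degrees of freedom.
#' @param Sigma_scale scalar multiplying the identity scale matrix.
#' @return an object of class `cfj_priors`.
#' @export
cfj_priors <- function(beta_scale = 100, gamma_scale = 10, a_scale = 10,
                       theta_scale = 20, sigma_scale = 10,
                       Sigma_df_add = 2, Sigma_scale = 1) {
  structure(list(beta_scale = beta_scale, gamma_scale = gamma_scale,
                 a_scale = a_scale, theta_scale = theta_scale,
                 sigma_scale = sigma_scale, Sigma_df_add = Sigma_df_add,
                 Sigma_scale = Sigma_scale),
            class = "cfj_priors")
}

## survival log-likelihood pieces from cached linear predictors
surv_parts <- function(jd, theta, gamma, a, mc_T, mc_q) {
  lp_T <- drop(jd$B_T %*% theta) + drop(mc_T %*% a)
  lp_q <- drop(jd$B_q %*% theta) + drop(mc_q %*% a)
  if (ncol(jd$W_T)) {
    lp_T <- lp_T + drop(jd$W_T %*% gamma)
    lp_q <- lp_q + drop(jd$W_q %*% gamma)
  }
  Lam <- group_sum(jd$qw * exp(lp_q), jd$qpid, jd$n)
  list(lp_T = lp_T, lp_q = lp_q, Lam = Lam,
       ll = sum(jd$delta * lp_T) - sum(Lam))
}

#' Fit the joint model by MCMC
#'
#' @param cohort a [cohort_data()] object.
#' @param model a [joint_model_spec()] (prepared on the cohort if needed).
#' @param priors a [cfj_priors()] object.
#' @param control an [mcmc_control()] object.
#' @return an object of class `cfj_posterior`: retained draws (matrix with
#'   named columns in the [params_pack()] layout), per-parameter diagnostics
#'   (effective sample size, split-chain Rhat), acceptance rates, and the
#'   prepared model.
#' @export
fit_mcmc <- function(cohort, model, priors = cfj_priors(), control = mcmc_control()) {
  jd <- if (inherits(cohort, "cfj_jmdata")) cohort else prepare_jm_data(model, cohort)
  model <- jd$model
  n <- jd$n
  K <- length(model$outcomes)
  d <- n_random(model)
  cols <- re_cols(model)
  lw <- if (control$prior_only) 0 else 1   # likelihood weight

  ## ---- initial state -------------------------------------------------------
  params <- param_template(model)
  for (k in model$outcomes) {
    L <- jd$long[[k]]
    fit0 <- stats::lm.fit(L$X, L$y)
    cf <- fit0$coefficients; cf[is.na(cf)] <- 0
    params$beta[[k]][] <- cf
    params$sigma[[k]] <- max(stats::sd(fit0$residuals), 1e-3)
  }
  sig_init <- unlist(lapply(model$outcomes, function(k) {
    s <- stats::sd(jd$long[[k]]$y)
    if (n_random_k(model$submodels[[k]]) == 2L) c((0.5 * s)^2, (0.05 * s)^2)
    else (0.5 * s)^2
  }))
  params$Sigma <- diag(sig_init, d)
  exposure <- sum(jd$exit - jd$entry)
  params$theta[1] <- log(max(sum(jd$delta), 1) / exposure)
  b <- matrix(0, n, d)

  nsp <- length(params$theta) + length(params$gamma) + K  # survival block dim
  phi_scales <- c(rep(0.1, length(params$theta)), rep(0.1, length(params$gamma)),
                  rep(0.01, K))
  C_surv <- diag(phi_scales^2, nsp)
  s_surv <- 0.5
  s_b <- rep(0.4, n)
  s_sig <- rep(0.2, K)
  acc_counts <- c(b = 0, beta = 0, sigma = 0, surv = 0)
  prop_counts <- c(b = 0, beta = 0, sigma = 0, surv = 0)

  n_retained <- (control$n_iterations - control$n_burn_in) %/% control$thinning
  flat0 <- params_pack(params, model)
  draws <- matrix(NA_real_, n_retained, length(flat0),
                  dimnames = list(NULL, names(flat0)))
  b_draws <- if (control$store_random_effects)
    array(NA_real_, c(n_retained, n, d)) else NULL
  phi_hist <- matrix(NA_real_, control$n_burn_in, nsp)

  with_seed(derive_seed(control$seed, "mcmc"), {
    ## caches
    resid <- list()
    for (k in model$outcomes) {
      L <- jd$long[[k]]
      resid[[k]] <- L$y - drop(L$X %*% params$beta[[k]]) -
        rowSums(L$Z * b[L$id, cols[[k]], drop = FALSE])
    }
    mc <- centred_m(jd, params, b)
    sp <- surv_parts(jd, params$theta, params$gamma, params$a, mc$T, mc$q)
    if (!is.finite(sp$ll * lw))
      stop("non-finite log-posterior at initialization (survival block)")
    Sinv <- solve(params$Sigma)
    Lprop <- t(chol(params$Sigma))

    for (iter in seq_len(control$n_iterations)) {
      adapting <- iter <= control$n_burn_in
      arate <- 1 / sqrt(1 + iter / 10)

      ## ---- random effects, all patients at once ----------------------------
      eps <- (matrix(stats::rnorm(n * d), n, d) %*% t(Lprop)) * s_b
      dlong <- numeric(n)
      dfit <- list()
      for (k in model$outcomes) {
        L <- jd$long[[k]]
        df_k <- rowSums(L$Z * eps[L$id, cols[[k]], drop = FALSE])
        dfit[[k]] <- df_k
        rs <- resid[[k]] - df_k
        dlong <- dlong + group_sum(-0.5 * ((rs / params$sigma[[k]])^2 -
                                             (resid[[k]] / params$sigma[[k]])^2),
                                   L$id, n)
      }
      bnew <- b + eps
      dprior <- -0.5 * (rowSums((bnew %*% Sinv) * bnew) - rowSums((b %*% Sinv) * b))
      if (lw > 0) {
        mcT_new <- mc$T; mcq_new <- mc$q
        for (j in seq_len(K)) {
          k <- model$outcomes[j]
          mcT_new[, j] <- mc$T[, j] + rowSums(jd$Z_T[[k]] * eps[, cols[[k]], drop = FALSE])
          mcq_new[, j] <- mc$q[, j] + rowSums(jd$Z_q[[k]] * eps[jd$qpid, cols[[k]], drop = FALSE])
        }
        lpT_new <- sp$lp_T + drop((mcT_new - mc$T) %*% params$a)
        lpq_new <- sp$lp_q + drop((mcq_new - mc$q) %*% params$a)
        Lam_new <- group_sum(jd$qw * exp(lpq_new), jd$qpid, n)
        dsurv <- jd$delta * (lpT_new - sp$lp_T) - (Lam_new - sp$Lam)
        acc <- log(stats::runif(n)) < dlong + dsurv + dprior
      } else {
        acc <- log(stats::runif(n)) < dprior
      }
      if (any(acc)) {
        b[acc, ] <- bnew[acc, ]
        for (k in model$outcomes) {
          L <- jd$long[[k]]
          rows <- acc[L$id]
          resid[[k]][rows] <- resid[[k]][rows] - dfit[[k]][rows]
        }
        if (lw > 0) {
          qacc <- acc[jd$qpid]
          mc$T[acc, ] <- mcT_new[acc, ]; mc$q[qacc, ] <- mcq_new[qacc, ]
          sp$lp_T[acc] <- lpT_new[acc]; sp$lp_q[qacc] <- lpq_new[qacc]
          sp$Lam[acc] <- Lam_new[acc]
          sp$ll <- sum(jd$delta * sp$lp_T) - sum(sp$Lam)
        }
      }
      if (adapting) s_b <- s_b * exp(arate * (as.numeric(acc) - 0.234))
      acc_counts["b"] <- acc_counts["b"] + mean(acc); prop_counts["b"] <- prop_counts["b"] + 1

      ## ---- beta_k: Gaussian-conditional independence proposal --------------
      for (j in seq_len(K)) {
        k <- model$outcomes[j]
        L <- jd$long[[k]]
        p <- ncol(L$X)
        prior_prec <- diag(1 / priors$beta_scale^2, p)
        Vinv <- lw * L$XtX / params$sigma[[k]]^2 + prior_prec
        Rv <- chol(Vinv)
        rhs <- lw * (crossprod(L$X, resid[[k]]) + L$XtX %*% params$beta[[k]]) /
          params$sigma[[k]]^2
        mu <- backsolve(Rv, backsolve(Rv, rhs, transpose = TRUE))
        beta_new <- drop(mu + backsolve(Rv, stats::rnorm(p)))
        dbeta <- beta_new - params$beta[[k]]
        if (lw > 0) {
          dm_T <- drop(jd$X_T[[k]] %*% dbeta)
          dm_q <- drop(jd$X_q[[k]] %*% dbeta)
          lpT_new <- sp$lp_T + params$a[[j]] * dm_T
          lpq_new <- sp$lp_q + params$a[[j]] * dm_q
          Lam_new <- group_sum(jd$qw * exp(lpq_new), jd$qpid, n)
          dsurv <- sum(jd$delta * (lpT_new - sp$lp_T)) - sum(Lam_new - sp$Lam)
          if (is.finite(dsurv) && log(stats::runif(1)) < dsurv) {
            params$beta[[k]][] <- beta_new
            resid[[k]] <- resid[[k]] - drop(L$X %*% dbeta)
            mc$T[, j] <- mc$T[, j] + dm_T; mc$q[, j] <- mc$q[, j] + dm_q
            sp$lp_T <- lpT_new; sp$lp_q <- lpq_new; sp$Lam <- Lam_new
            sp$ll <- sum(jd$delta * sp$lp_T) - sum(sp$Lam)
            acc_counts["beta"] <- acc_counts["beta"] + 1
          }
        } else {
          ## prior-only: the conditional IS the prior, always accepted
          params$beta[[k]][] <- beta_new
          resid[[k]] <- resid[[k]] - drop(L$X %*% dbeta)
          acc_counts["beta"] <- acc_counts["beta"] + 1
        }
        prop_counts["beta"] <- prop_counts["beta"] + 1
      }

      ## ---- residual SDs: random walk on log sigma --------------------------
      for (j in seq_len(K)) {
        k <- model$outcomes[j]
        L <- jd$long[[k]]
        s0 <- params$sigma[[k]]
        s1 <- s0 * exp(s_sig[j] * stats::rnorm(1))
        rss <- sum(resid[[k]]^2)
        dll <- lw * (L$n * (log(s0) - log(s1)) + 0.5 * rss * (1 / s0^2 - 1 / s1^2))
        dpr <- log(1 + (s0 / priors$sigma_scale)^2) -
          log(1 + (s1 / priors$sigma_scale)^2) + (log(s1) - log(s0))
        ok <- log(stats::runif(1)) < dll + dpr
        if (ok) params$sigma[[k]] <- s1
        if (adapting) s_sig[j] <- s_sig[j] * exp(arate * (as.numeric(ok) - 0.44))
        acc_counts["sigma"] <- acc_counts["sigma"] + as.numeric(ok)
        prop_counts["sigma"] <- prop_counts["sigma"] + 1
      }

      ## ---- random-effects covariance: exact inverse-Wishart ----------------
      ## b is latent, so Sigma | b is inverse-Wishart whether or not the data
      ## likelihood is switched on
      S_post <- diag(priors$Sigma_scale, d) + crossprod(b)
      df_post <- d + priors$Sigma_df_add + n
      W <- stats::rWishart(1, df_post, solve(S_post))[, , 1]
      params$Sigma <- solve(W)
      Sinv <- W
      Lprop <- t(chol(params$Sigma))

      ## ---- survival block: adaptive random walk ----------------------------
      phi <- c(params$theta, params$gamma, params$a)
      pr_sd <- c(rep(priors$theta_scale, length(params$theta)),
                 rep(priors$gamma_scale, length(params$gamma)),
                 rep(priors$a_scale, K))
      Ls <- t(chol(C_surv + diag(1e-12, nsp)))
      for (rep_i in seq_len(control$n_survival_inner)) {
        phi_new <- phi + s_surv * drop(Ls %*% stats::rnorm(nsp))
        th <- phi_new[seq_along(params$theta)]
        ga <- phi_new[length(params$theta) + seq_along(params$gamma)]
        aa <- phi_new[nsp - K + seq_len(K)]
        dprior_phi <- sum(-0.5 * (phi_new / pr_sd)^2) - sum(-0.5 * (phi / pr_sd)^2)
        if (lw > 0) {
          spn <- surv_parts(jd, th, ga, aa, mc$T, mc$q)
          dpost <- spn$ll - sp$ll + dprior_phi
        } else dpost <- dprior_phi
        ok <- is.finite(dpost) && log(stats::runif(1)) < dpost
        if (ok) {
          phi <- phi_new
          params$theta[] <- th; if (length(ga)) params$gamma[] <- ga; params$a[] <- aa
          if (lw > 0) sp <- spn
        }
        if (adapting) s_surv <- s_surv * exp(arate * (as.numeric(ok) - 0.234))
        acc_counts["surv"] <- acc_counts["surv"] + as.numeric(ok)
        prop_counts["surv"] <- prop_counts["surv"] + 1
      }
      if (adapting) {
        phi_hist[iter, ] <- phi
        if (iter >= 50 && iter %% 25 == 0) {
          hist_win <- phi_hist[max(1, iter - 299):iter, , drop = FALSE]
          C_surv <- stats::cov(hist_win) * (2.38^2 / nsp) + diag(1e-10, nsp)
        }
      }

      ## ---- store -----------------------------------------------------------
      if (iter > control$n_burn_in) {
        r <- iter - control$n_burn_in
        if (r %% control$thinning == 0L) {
          idx <- r %/% control$thinning
          draws[idx, ] <- params_pack(params, model)
          if (!is.null(b_draws)) b_draws[idx, , ] <- b
        }
      }
    }
  })

  acc_rates <- acc_counts / pmax(prop_counts, 1)
  diag_tab <- data.frame(parameter = colnames(draws),
                         ess = apply(draws, 2, ess_draws),
                         rhat = apply(draws, 2, split_rhat),
                         row.names = NULL)
  structure(list(draws = draws, model = model, control = control, priors = priors,
                 acceptance = acc_rates, diagnostics = diag_tab,
                 b_draws = b_draws, shard_id = NULL, n_patients = n),
            class = "cfj_posterior")
}

#' @export
print.cfj_posterior <- function(x, ...) {
  cat(sprintf("<cfj_posterior> %d retained draws x %d parameters (%d patients%s)\n",
              nrow(x$draws), ncol(x$draws), x$n_patients,
              if (!is.null(x$shard_id)) paste0(", shards ",
                paste(unique(x$shard_id), collapse = "+")) else ""))
  cat(sprintf("  acceptance: b %.2f, beta %.2f, sigma %.2f, survival %.2f; min ESS %.0f\n",
              x$acceptance["b"], x$acceptance["beta"], x$acceptance["sigma"],
              x$acceptance["surv"], min(x$diagnostics$ess, na.rm = TRUE)))
  invisible(x)
}

## effective sample size from the initial positive sequence of autocorrelations
ess_draws <- function(x) {
  n <- length(x)
  if (n < 10 || stats::sd(x) == 0) return(NA_real_)
  ac <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  s <- 0
  for (r in ac) { if (r < 0.05) break; s <- s + r }
  n / (1 + 2 * s)
}

## split-chain convergence statistic (one chain split in halves)
split_rhat <- function(x) {
  n <- length(x) %/% 2
  if (n < 5 || stats::sd(x) == 0) return(NA_real_)
  h1 <- x[seq_len(n)]; h2 <- x[n + seq_len(n)]
  W <- (stats::var(h1) + stats::var(h2)) / 2
  B <- n * (mean(h1) - mean(h2))^2 / 2
  vhat <- (n - 1) / n * W + B / n
  sqrt(vhat / W)
}
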