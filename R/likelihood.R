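## Likelihood machinery. All heavy evaluation runs off a precomputed design
## bundle (`jm_data`): stacked longitudinal designs, event-time designs, and
## Gauss-Legendre nodes for each patient's cumulative hazard, split piecewise
## at covariate switch ages.

#' Precompute the design bundle for a cohort under a model
#'
#' @param model a [joint_model_spec()]; prepared on the cohort if not already.
#' @param cohort a [cohort_data()] object.
#' @param order Gauss-Legendre order per smooth piece of the hazard integral.
#' @return an opaque list of class `cfj_jmdata` reused by the likelihood,
#'   sampler and prediction code.
#' @export
prepare_jm_data <- function(model, cohort, order = 15L) {
  model <- prepare_model(model, cohort)
  pats <- expand_patient_covariates(cohort$patients)
  n <- nrow(pats)
  pid <- pats$patient_id
  obs <- cohort$observations
  obs_idx <- match(obs$patient_id, pid)

  ## encounter history per patient (unique encounter ages, sorted)
  enc_list <- rep(list(numeric(0)), n)
  if (nrow(obs)) {
    sp <- split(obs$age, obs_idx)
    for (nm in names(sp)) enc_list[[as.integer(nm)]] <- sort(unique(sp[[nm]]))
  }
  any_enc <- any(vapply(model$submodels, `[[`, logical(1), "encounter_count"))
  enc_at <- function(idx, ages) {
    out <- numeric(length(ages))
    for (i in unique(idx)) {
      rows <- idx == i
      a <- enc_list[[i]]
      out[rows] <- findInterval(ages[rows], a) -
        findInterval(ages[rows] - 1, a, left.open = TRUE)
    }
    out
  }

  K <- length(model$outcomes)
  long <- list()
  for (k in model$outcomes) {
    rows <- obs$outcome == k
    ages <- obs$age[rows]
    idx <- obs_idx[rows]
    enc <- if (model$submodels[[k]]$encounter_count) enc_at(idx, ages) else NULL
    X <- long_fixed_design(model, k, pats, idx, ages, enc = enc)
    Z <- long_random_design(model, k, ages)
    long[[k]] <- list(y = obs$value[rows], X = X, Z = Z, id = idx,
                      XtX = crossprod(X), n = length(ages))
  }

  delta <- as.numeric(pats$event)
  entry <- pats$entry_age
  exit <- pats$exit_age

  ## designs at the observed exit age (event-density term)
  sidx <- seq_len(n)
  B_T <- baseline_design(model, exit)
  W_T <- event_design(model, pats, sidx, exit)
  X_T <- Z_T <- list()
  for (k in model$outcomes) {
    enc <- if (model$submodels[[k]]$encounter_count) enc_at(sidx, exit) else NULL
    X_T[[k]] <- long_fixed_design(model, k, pats, sidx, exit, enc = enc)
    Z_T[[k]] <- long_random_design(model, k, exit)
  }

  ## quadrature nodes, piecewise between switch ages
  g <- gl_unit(order)
  qage <- qw <- numeric(0); qpid <- integer(0)
  for (i in sidx) {
    br <- quad_pieces(model, pats[i, , drop = FALSE], entry[i], exit[i])
    for (j in seq_len(length(br) - 1L)) {
      a <- br[j]; b <- br[j + 1L]
      qage <- c(qage, a + (b - a) * g$x)
      qw <- c(qw, (b - a) * g$w)
      qpid <- c(qpid, rep.int(i, order))
    }
  }
  B_q <- baseline_design(model, qage)
  W_q <- event_design(model, pats, qpid, qage)
  X_q <- Z_q <- list()
  for (k in model$outcomes) {
    enc <- if (model$submodels[[k]]$encounter_count) enc_at(qpid, qage) else NULL
    X_q[[k]] <- long_fixed_design(model, k, pats, qpid, qage, enc = enc)
    Z_q[[k]] <- long_random_design(model, k, qage)
  }

  structure(list(model = model, n = n, pid = pid, patients = pats,
                 long = long, delta = delta, entry = entry, exit = exit,
                 B_T = B_T, W_T = W_T, X_T = X_T, Z_T = Z_T,
                 qage = qage, qw = qw, qpid = qpid,
                 B_q = B_q, W_q = W_q, X_q = X_q, Z_q = Z_q,
                 enc_list = enc_list, centering = model$centering,
                 pcache = new.env(parent = emptyenv())),
            class = "cfj_jmdata")
}

re_cols <- function(model) {
  off <- re_offsets(model)
  lapply(stats::setNames(model$outcomes, model$outcomes), function(k)
    off[[k]] + seq_len(n_random_k(model$submodels[[k]])))
}

## centred current values m_k - c_k at event times (n x K) and quad nodes (Q x K)
centred_m <- function(jd, params, b) {
  model <- jd$model
  cols <- re_cols(model)
  K <- length(model$outcomes)
  mc_T <- matrix(0, jd$n, K); mc_q <- matrix(0, length(jd$qage), K)
  for (j in seq_len(K)) {
    k <- model$outcomes[j]
    mc_T[, j] <- drop(jd$X_T[[k]] %*% params$beta[[k]]) +
      rowSums(jd$Z_T[[k]] * b[, cols[[k]], drop = FALSE]) - jd$centering[[k]]
    mc_q[, j] <- drop(jd$X_q[[k]] %*% params$beta[[k]]) +
      rowSums(jd$Z_q[[k]] * b[jd$qpid, cols[[k]], drop = FALSE]) - jd$centering[[k]]
  }
  list(T = mc_T, q = mc_q)
}

## per-patient longitudinal log-likelihood (vector length n)
long_ll_by_patient <- function(jd, params, b) {
  model <- jd$model
  cols <- re_cols(model)
  out <- numeric(jd$n)
  for (k in model$outcomes) {
    L <- jd$long[[k]]
    resid <- L$y - drop(L$X %*% params$beta[[k]]) -
      rowSums(L$Z * b[L$id, cols[[k]], drop = FALSE])
    s <- params$sigma[[k]]
    out <- out + group_sum(-0.5 * (resid / s)^2 - log(s) - 0.5 * log(2 * pi), L$id, jd$n)
  }
  out
}

## per-patient survival log-likelihood: delta*log h(T) - Lambda(entry, T)
surv_ll_by_patient <- function(jd, params, b, mc = NULL) {
  if (is.null(mc)) mc <- centred_m(jd, params, b)
  lp_T <- drop(jd$B_T %*% params$theta) + drop(mc$T %*% params$a)
  lp_q <- drop(jd$B_q %*% params$theta) + drop(mc$q %*% params$a)
  if (ncol(jd$W_T)) {
    lp_T <- lp_T + drop(jd$W_T %*% params$gamma)
    lp_q <- lp_q + drop(jd$W_q %*% params$gamma)
  }
  Lam <- group_sum(jd$qw * exp(lp_q), jd$qpid, jd$n)
  jd$delta * lp_T - Lam
}

## per-patient multivariate-normal log-density of the random effects
re_prior_by_patient <- function(params, b) {
  Sinv <- solve(params$Sigma)
  ld <- determinant(params$Sigma, logarithm = TRUE)$modulus
  -0.5 * rowSums((b %*% Sinv) * b) - 0.5 * (ncol(b) * log(2 * pi) + as.numeric(ld))
}

#' Complete-data log-likelihood of the joint model
#'
#' Sum over patients of the longitudinal normal densities around m_k(t), the
#' event term delta * log h(T) - Lambda(entry, T) (delayed entry), and the
#' multivariate-normal density of the random effects.
#'
#' @param model a [joint_model_spec()].
#' @param params parameter list or packed vector.
#' @param b matrix of random effects (patients x total random dimension).
#' @param data a [cohort_data()] object or a [prepare_jm_data()] bundle.
#' @return scalar log-density.
#' @export
complete_data_log_likelihood <- function(model, params, b, data) {
  jd <- if (inherits(data, "cfj_jmdata")) data else prepare_jm_data(model, data)
  if (is.numeric(params) && !is.list(params)) params <- params_unpack(params, jd$model)
  ev <- eigen(params$Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("random-effects covariance is not positive definite")
  sum(long_ll_by_patient(jd, params, b)) +
    sum(surv_ll_by_patient(jd, params, b)) +
    sum(re_prior_by_patient(params, b))
}

## data + survival log-likelihood for one patient as a function of b
## (rows of bmat); include_prior adds the MVN term.
patient_loglik_fn <- function(jd, i, params, include_prior = TRUE) {
  model <- jd$model
  cols <- re_cols(model)
  K <- length(model$outcomes)
  key <- as.character(i)
  static <- jd$pcache[[key]]
  if (is.null(static)) {
    sub_long <- lapply(model$outcomes, function(k) {
      L <- jd$long[[k]]
      rows <- L$id == i
      list(y = L$y[rows], X = L$X[rows, , drop = FALSE], Z = L$Z[rows, , drop = FALSE])
    })
    names(sub_long) <- model$outcomes
    qrows <- jd$qpid == i
    static <- list(
      sub_long = sub_long, nq = sum(qrows),
      Bq = jd$B_q[qrows, , drop = FALSE], Wq = jd$W_q[qrows, , drop = FALSE],
      qw = jd$qw[qrows],
      Xq = lapply(jd$X_q, function(x) x[qrows, , drop = FALSE]),
      Zq = lapply(jd$Z_q, function(z) z[qrows, , drop = FALSE]),
      BT = jd$B_T[i, , drop = FALSE], WT = jd$W_T[i, , drop = FALSE],
      XT = lapply(jd$X_T, function(x) x[i, , drop = FALSE]),
      ZT = lapply(jd$Z_T, function(z) z[i, , drop = FALSE]))
    jd$pcache[[key]] <- static
  }
  sub_long <- static$sub_long
  Bq <- static$Bq; Wq <- static$Wq; qw <- static$qw
  Xq <- static$Xq; Zq <- static$Zq
  BT <- static$BT; WT <- static$WT; XT <- static$XT; ZT <- static$ZT
  delta_i <- jd$delta[i]
  Sinv <- solve(params$Sigma)
  ldS <- as.numeric(determinant(params$Sigma, logarithm = TRUE)$modulus)
  d <- n_random(model)

  function(bmat) {
    if (is.null(dim(bmat))) bmat <- matrix(bmat, nrow = 1)
    G <- nrow(bmat)
    ll <- numeric(G)
    lp_T <- rep(drop(BT %*% params$theta) +
                  (if (ncol(WT)) drop(WT %*% params$gamma) else 0), G)
    lp_q <- matrix(drop(Bq %*% params$theta) +
                     (if (ncol(Wq)) drop(Wq %*% params$gamma) else 0),
                   nrow = static$nq, ncol = G)
    for (j in seq_len(K)) {
      k <- model$outcomes[j]
      bk <- bmat[, cols[[k]], drop = FALSE]
      sl <- sub_long[[k]]
      if (length(sl$y)) {
        fit <- drop(sl$X %*% params$beta[[k]]) + tcrossprod(sl$Z, bk)  # n_i x G
        resid <- sl$y - fit
        s <- params$sigma[[k]]
        ll <- ll + colSums(-0.5 * (resid / s)^2) - length(sl$y) * (log(s) + 0.5 * log(2 * pi))
      }
      mT <- drop(XT[[k]] %*% params$beta[[k]]) + tcrossprod(ZT[[k]], bk) - jd$centering[[k]]
      mq <- drop(Xq[[k]] %*% params$beta[[k]]) + tcrossprod(Zq[[k]], bk) - jd$centering[[k]]
      lp_T <- lp_T + params$a[[j]] * drop(mT)
      lp_q <- lp_q + params$a[[j]] * mq
    }
    Lam <- colSums(qw * exp(lp_q))
    ll <- ll + delta_i * lp_T - Lam
    if (include_prior)
      ll <- ll - 0.5 * rowSums((bmat %*% Sinv) * bmat) - 0.5 * (d * log(2 * pi) + ldS)
    ll
  }
}

## mode and curvature of a patient's complete-data log-density in b
patient_re_mode <- function(fn, d, scale = 1) {
  if (d == 1L) {
    w <- 12 * max(scale)
    opt <- stats::optimize(function(b) -fn(b), interval = c(-w, w), tol = 1e-8)
    x <- opt$minimum
    h <- 1e-4 * max(1, abs(x))
    f0 <- fn(x); hess <- -(fn(x - h) - 2 * f0 + fn(x + h)) / h^2
    if (!is.finite(hess) || hess <= 0) hess <- 1 / max(scale)^2
    return(list(mode = x, hessian = matrix(hess, 1, 1), cov = matrix(1 / hess, 1, 1)))
  }
  opt <- stats::optim(numeric(d), fn = function(b) -fn(b), method = "BFGS",
                      hessian = TRUE, control = list(maxit = 200, reltol = 1e-10))
  if (!is.finite(opt$value)) stop("random-effect mode finding failed")
  H <- (opt$hessian + t(opt$hessian)) / 2
  ev <- eigen(H, symmetric = TRUE)
  ev$values <- pmax(ev$values, 1e-8)
  H <- ev$vectors %*% (ev$values * t(ev$vectors))
  list(mode = opt$par, hessian = H, cov = solve(H))
}

#' Marginal log-likelihood by adaptive Gauss–Hermite quadrature
#'
#' Integrates the random effects out of the complete-data likelihood, patient
#' by patient: the quadrature grid is centred at each patient's conditional
#' mode and scaled by the local curvature. Serves as the slow-but-trusted
#' oracle for the sampler.
#'
#' @param model a [joint_model_spec()].
#' @param params parameter list or packed vector.
#' @param data a [cohort_data()] or [prepare_jm_data()] bundle.
#' @param control list; `order` nodes per dimension (default 9).
#' @return scalar log marginal likelihood.
#' @export
marginal_log_likelihood <- function(model, params, data, control = list()) {
  jd <- if (inherits(data, "cfj_jmdata")) data else prepare_jm_data(model, data)
  if (is.numeric(params) && !is.list(params)) params <- params_unpack(params, jd$model)
  order <- control$order %||% 9L
  d <- n_random(jd$model)
  if (d > 6L) warning("random-effects dimension ", d,
                      " is large for product-rule quadrature")
  gh <- pracma::gaussHermite(order)
  Z <- as.matrix(expand.grid(rep(list(gh$x), d)))
  logW <- rowSums(as.matrix(expand.grid(rep(list(log(gh$w)), d))))
  total <- 0
  sc <- sqrt(diag(params$Sigma))
  for (i in seq_len(jd$n)) {
    fn <- patient_loglik_fn(jd, i, params, include_prior = TRUE)
    md <- patient_re_mode(fn, d, scale = sc)
    Lc <- t(chol(md$cov))
    B <- sweep(sqrt(2) * Z %*% t(Lc), 2, md$mode, `+`)
    lv <- fn(B) + rowSums(Z^2) + logW
    mlv <- max(lv)
    total <- total + (d / 2) * log(2) + sum(log(diag(Lc))) +
      mlv + log(sum(exp(lv - mlv)))
  }
  total
}
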