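# MCMC estimation of the two-level dynamic structural equation model.
#
# Update cycle per iteration:
#   (i)   per-person latent means (mu_pb, mu_ge)      - conjugate bivariate normal
#   (ii)  per-person lag coefficients (phi1, phi3)
#         and (phi2, phi4)                            - conjugate bivariate normal
#   (iii) per-person log residual variances psi       - adaptive random-walk MH
#   (iv)  missing momentary values                    - Gaussian full conditionals
#   (v)   fixed-effect coefficient blocks gamma       - conjugate (SUR) normal
#   (vi)  random-effect covariance Sigma_eta          - conjugate inverse-Wishart /
#                                                       inverse-gamma per block
#   (vii) distal coefficients and residual variances  - conjugate normal /
#                                                       inverse-gamma
#
# Person-level updates are vectorised across persons: sufficient statistics
# are accumulated over the stacked lag pairs with rowsum(), and the 2x2
# conditional Gaussians are drawn with closed-form Cholesky algebra.

#' MCMC configuration
#'
#' @param n_chains Number of chains (default 2; at least 2 for PSR).
#' @param n_iters Post-burn-in iterations per chain (default 10,000).
#' @param n_burnin Burn-in iterations discarded per chain (default 2,000).
#'   The adaptive Metropolis step-size tuning runs during burn-in only and is
#'   frozen afterwards to preserve detailed balance.
#' @param thin Thinning interval applied to the post-burn-in iterations
#'   (default 50, so the defaults retain 200 draws per chain).
#' @param adapt Adapt the random-walk step sizes during burn-in.
#' @param target_accept Target Metropolis acceptance rate (default 0.44).
#' @param init_step Initial random-walk standard deviation for psi updates.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 2L, n_iters = 10000L, n_burnin = 2000L,
                        thin = 50L, adapt = TRUE, target_accept = 0.44,
                        init_step = 0.5) {
  stopifnot(thin >= 1L, n_iters >= thin, n_chains >= 1L, n_burnin >= 0L,
            target_accept > 0, target_accept < 1, init_step > 0)
  structure(list(n_chains = as.integer(n_chains), n_iters = as.integer(n_iters),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin),
                 adapt = isTRUE(adapt), target_accept = target_accept,
                 init_step = init_step),
            class = "mcmc_config")
}

# ---------------------------------------------------------------------------
# Setup: precompute data structures shared by all sweeps of one chain.
# ---------------------------------------------------------------------------
sampler_setup <- function(ds, spec, priors, mcmc) {
  stopifnot(inherits(ds, "analysis_dataset"), inherits(spec, "model_spec"),
            inherits(priors, "prior_set"), inherits(mcmc, "mcmc_config"))
  env <- new.env(parent = emptyenv())
  env$spec <- spec; env$priors <- priors; env$mcmc <- mcmc
  env$persons <- ds$persons
  env$n <- nrow(ds$persons)
  env$M <- nrow(ds$obs)
  env$ypb <- ds$obs$pb
  env$yge <- ds$obs$ge
  env$obs_person <- ds$obs$person
  env$pid <- ds$pairs$person
  env$src <- ds$pairs$src
  env$tgt <- ds$pairs$tgt
  env$np <- tabulate(env$pid, nbins = env$n)

  # Record-level pair lookup for the missing-data updates.
  env$tgt_pair <- integer(env$M); env$tgt_pair[env$tgt] <- seq_along(env$tgt)
  env$src_pair <- integer(env$M); env$src_pair[env$src] <- seq_along(env$src)
  env$miss <- which(is.na(env$ypb) | is.na(env$yge))
  env$miss_pb <- is.na(env$ypb)[env$miss]
  env$miss_ge <- is.na(env$yge)[env$miss]

  # Between-level designs and cached crossproducts per covariance block.
  env$X <- lapply(ETA_NAMES, function(eq) eta_design(spec, ds$persons, eq))
  names(env$X) <- ETA_NAMES
  env$blocks <- lapply(spec$blocks, function(b) match(b, ETA_NAMES))
  env$XtX <- lapply(env$blocks, function(E) {
    m <- length(E)
    out <- vector("list", m * m); dim(out) <- c(m, m)
    for (a in seq_len(m)) for (b in seq_len(m)) {
      out[[a, b]] <- crossprod(env$X[[E[a]]], env$X[[E[b]]])
    }
    out
  })

  # Distal outcomes.
  env$distal_names <- names(spec$distal_eta)
  env$y_distal <- lapply(env$distal_names, function(d) ds$persons[[d]])
  names(env$y_distal) <- env$distal_names
  env$ok_distal <- lapply(env$y_distal, function(y) !is.na(y))
  env
}

# Fitted between-level means for all eta equations (n x 8).
eta_fitted <- function(env) {
  m <- matrix(0, env$n, 8L, dimnames = list(NULL, ETA_NAMES))
  for (e in ETA_NAMES) m[, e] <- drop(env$X[[e]] %*% env$state$gamma[[e]])
  m
}

# ---------------------------------------------------------------------------
# Initialization: crude per-person least-squares starts, jittered per chain.
# ---------------------------------------------------------------------------

#' Per-chain starting values
#'
#' Crude per-person least-squares starts: latent means from observed person
#' means, lag coefficients from per-person OLS on the lag pairs (zero when
#' fewer than 3 complete pairs or the regression is degenerate), log residual
#' variances from the residual (or raw deviation) variance floored at 1e-4.
#' Fixed effects, covariance blocks and distal equations are then initialised
#' by least squares on these person estimates. `jitter_sd` scales the
#' over-dispersion applied per chain.
#'
#' @param ds An `analysis_dataset`.
#' @param spec A [model_spec()].
#' @param jitter_sd Multiplier on the documented per-component jitter scales
#'   (0 gives the raw least-squares start).
#' @return List with `eta`, `gamma`, `Sigma`, `sig2_distal`, `y_fill`
#'   (imputation starts for missing momentary values).
#' @export
dsem_init <- function(ds, spec = model_spec(), jitter_sd = 1) {
  n <- nrow(ds$persons)
  obs <- ds$obs
  eta <- matrix(0, n, 8L, dimnames = list(NULL, ETA_NAMES))
  for (i in seq_len(n)) {
    rows <- which(obs$person == i)
    pb <- obs$pb[rows]; ge <- obs$ge[rows]
    mpb <- mean(pb, na.rm = TRUE); if (!is.finite(mpb)) mpb <- 4
    mge <- mean(ge, na.rm = TRUE); if (!is.finite(mge)) mge <- 4
    eta[i, 1:2] <- c(mpb, mge)
    pr <- ds$pairs[ds$pairs$person == i, , drop = FALSE]
    ok <- !is.na(obs$pb[pr$src]) & !is.na(obs$ge[pr$src]) &
      !is.na(obs$pb[pr$tgt]) & !is.na(obs$ge[pr$tgt])
    pr <- pr[ok, , drop = FALSE]
    vpb <- stats::var(pb, na.rm = TRUE); vge <- stats::var(ge, na.rm = TRUE)
    if (nrow(pr) >= 3L) {
      Xl <- cbind(obs$pb[pr$src] - mpb, obs$ge[pr$src] - mge)
      fit_eq <- function(y) {
        cf <- tryCatch(qr.coef(qr(Xl), y), error = function(e) c(NA, NA))
        cf[!is.finite(cf)] <- 0
        cf
      }
      cpb <- fit_eq(obs$pb[pr$tgt] - mpb)
      cge <- fit_eq(obs$ge[pr$tgt] - mge)
      eta[i, c("phi1", "phi3")] <- cpb
      eta[i, c("phi4", "phi2")] <- cge
      rpb <- (obs$pb[pr$tgt] - mpb) - Xl %*% cpb
      rge <- (obs$ge[pr$tgt] - mge) - Xl %*% cge
      vpb <- sum(rpb^2) / max(1L, nrow(pr) - 2L)
      vge <- sum(rge^2) / max(1L, nrow(pr) - 2L)
    }
    eta[i, "psi_pb"] <- log(max(vpb, 1e-4, na.rm = TRUE))
    eta[i, "psi_ge"] <- log(max(vge, 1e-4, na.rm = TRUE))
  }
  jit <- c(0.10, 0.10, 0.05, 0.05, 0.05, 0.05, 0.20, 0.20) * jitter_sd
  eta <- eta + matrix(stats::rnorm(n * 8L), n, 8L) %*% diag(jit)
  colnames(eta) <- ETA_NAMES

  gamma <- list()
  resid <- matrix(0, n, 8L)
  for (e in seq_along(ETA_NAMES)) {
    X <- eta_design(spec, ds$persons, ETA_NAMES[e])
    cf <- stats::lm.fit(X, eta[, e])$coefficients
    cf[!is.finite(cf)] <- 0
    gamma[[ETA_NAMES[e]]] <- stats::setNames(cf + stats::rnorm(length(cf), 0, 0.02 * jitter_sd),
                                             colnames(X))
    resid[, e] <- eta[, e] - drop(X %*% cf)
  }
  Sigma <- matrix(0, 8L, 8L, dimnames = list(ETA_NAMES, ETA_NAMES))
  for (b in spec$blocks) {
    E <- match(b, ETA_NAMES)
    S <- crossprod(resid[, E, drop = FALSE]) / max(n, 1L)
    S <- S + diag(1e-4, length(E))
    Sigma[E, E] <- S
  }
  sig2 <- c(follow_pb = 1, follow_ge = 1)
  for (d in names(spec$distal_eta)) {
    y <- ds$persons[[d]]
    ok <- !is.na(y)
    D <- distal_design(spec, ds$persons, eta, d)
    cf <- stats::lm.fit(D[ok, , drop = FALSE], y[ok])$coefficients
    cf[!is.finite(cf)] <- 0
    gamma[[d]] <- stats::setNames(cf + stats::rnorm(length(cf), 0, 0.02 * jitter_sd),
                                  colnames(D))
    sig2[d] <- max(stats::var(y[ok] - drop(D[ok, , drop = FALSE] %*% cf)), 1e-4)
  }
  # Imputation starts for missing momentary values: person means.
  y_fill <- list(pb = eta[, 1L], ge = eta[, 2L])
  list(eta = eta, gamma = gamma, Sigma = Sigma, sig2_distal = sig2,
       y_fill = y_fill)
}

sampler_init_state <- function(env, init) {
  env$state <- list(eta = init$eta, gamma = init$gamma, Sigma = init$Sigma,
                    sig2 = init$sig2_distal)
  # Fill missing momentary values with the person-mean starts.
  if (length(env$miss) > 0L) {
    p <- env$obs_person[env$miss]
    env$ypb[env$miss[env$miss_pb]] <- init$y_fill$pb[p[env$miss_pb]]
    env$yge[env$miss[env$miss_ge]] <- init$y_fill$ge[p[env$miss_ge]]
  }
  env$step <- matrix(env$mcmc$init_step, env$n, 2L)
  env$fitted <- eta_fitted(env)
  invisible(env)
}

# ---------------------------------------------------------------------------
# Distal contributions to the full conditional of eta components S:
# common |S| x |S| precision increment and per-person linear terms.
# ---------------------------------------------------------------------------
distal_contrib <- function(env, S) {
  k <- length(S)
  P <- matrix(0, k, k)
  L <- matrix(0, env$n, k)
  st <- env$state
  for (d in env$distal_names) {
    ecols <- match(env$spec$distal_eta[[d]], ETA_NAMES)
    pos <- match(ecols, S)
    sel <- which(!is.na(pos))
    if (length(sel) == 0L) next
    g <- st$gamma[[d]]
    D <- distal_design(env$spec, env$persons, st$eta, d)
    b <- g[1L + sel]                      # coefficients of the S-components
    fit <- drop(D %*% g)
    r <- env$y_distal[[d]] - fit +
      drop(st$eta[, ecols[sel], drop = FALSE] %*% b)
    r[!env$ok_distal[[d]]] <- 0           # persons without a distal outcome
    w <- as.numeric(env$ok_distal[[d]]) / st$sig2[[d]]
    P[pos[sel], pos[sel]] <- P[pos[sel], pos[sel]] + outer(b, b) / st$sig2[[d]]
    L[, pos[sel]] <- L[, pos[sel]] + (r * w) %o% b
  }
  list(P = P, L = L)
}

# ---------------------------------------------------------------------------
# One full Gibbs sweep, updating env$state in place.
# Returns the psi acceptance indicators (n x 2 logical).
# ---------------------------------------------------------------------------
sampler_sweep <- function(env, adapt_now = FALSE, adapt_gain = 0.05) {
  st <- env$state
  n <- env$n; pid <- env$pid; s <- env$src; t <- env$tgt; np <- env$np
  eta <- st$eta

  ## (i) latent means (mu_pb, mu_ge) -------------------------------------
  phi1 <- eta[, 3L]; phi2 <- eta[, 4L]; phi3 <- eta[, 5L]; phi4 <- eta[, 6L]
  vpb <- exp(eta[, 7L]); vge <- exp(eta[, 8L])
  cp <- cond_normal(env$fitted, st$Sigma, c(1L, 2L), eta)
  prec0 <- solve(cp$var)
  rpb <- env$ypb[t] - phi1[pid] * env$ypb[s] - phi3[pid] * env$yge[s]
  rge <- env$yge[t] - phi4[pid] * env$ypb[s] - phi2[pid] * env$yge[s]
  S2 <- person_sum(cbind(rpb, rge), pid, n)
  a1 <- 1 - phi1; a2 <- -phi3; b1 <- -phi4; b2 <- 1 - phi2
  dc <- distal_contrib(env, c(1L, 2L))
  P11 <- np * (a1^2 / vpb + b1^2 / vge) + prec0[1L, 1L] + dc$P[1L, 1L]
  P12 <- np * (a1 * a2 / vpb + b1 * b2 / vge) + prec0[1L, 2L] + dc$P[1L, 2L]
  P22 <- np * (a2^2 / vpb + b2^2 / vge) + prec0[2L, 2L] + dc$P[2L, 2L]
  prior_lin <- cp$mean %*% prec0
  L1 <- a1 * S2[, 1L] / vpb + b1 * S2[, 2L] / vge + prior_lin[, 1L] + dc$L[, 1L]
  L2 <- a2 * S2[, 1L] / vpb + b2 * S2[, 2L] / vge + prior_lin[, 2L] + dc$L[, 2L]
  eta[, 1:2] <- draw_bivariate_gaussian(P11, P12, P22, L1, L2)
  st$eta <- eta

  ## centered deviations under the new means -----------------------------
  wpb_s <- env$ypb[s] - eta[pid, 1L]; wge_s <- env$yge[s] - eta[pid, 2L]
  wpb_t <- env$ypb[t] - eta[pid, 1L]; wge_t <- env$yge[t] - eta[pid, 2L]
  Mw <- person_sum(cbind(wpb_s^2, wpb_s * wge_s, wge_s^2,
                         wpb_s * wpb_t, wge_s * wpb_t,
                         wge_s * wge_t, wpb_s * wge_t), pid, n)

  ## (ii a) pb-equation lag coefficients (phi1, phi3) ---------------------
  env$state <- st
  cp <- cond_normal(eta_fitted_cached(env), st$Sigma, c(3L, 5L), eta)
  prec0 <- solve(cp$var)
  dc <- distal_contrib(env, c(3L, 5L))
  P11 <- Mw[, 1L] / vpb + prec0[1L, 1L] + dc$P[1L, 1L]
  P12 <- Mw[, 2L] / vpb + prec0[1L, 2L] + dc$P[1L, 2L]
  P22 <- Mw[, 3L] / vpb + prec0[2L, 2L] + dc$P[2L, 2L]
  prior_lin <- cp$mean %*% prec0
  L1 <- Mw[, 4L] / vpb + prior_lin[, 1L] + dc$L[, 1L]
  L2 <- Mw[, 5L] / vpb + prior_lin[, 2L] + dc$L[, 2L]
  eta[, c(3L, 5L)] <- draw_bivariate_gaussian(P11, P12, P22, L1, L2)
  st$eta <- eta; env$state <- st

  ## (ii b) ge-equation lag coefficients (phi2, phi4) ---------------------
  cp <- cond_normal(env$fitted, st$Sigma, c(4L, 6L), eta)
  prec0 <- solve(cp$var)
  dc <- distal_contrib(env, c(4L, 6L))
  P11 <- Mw[, 3L] / vge + prec0[1L, 1L] + dc$P[1L, 1L]
  P12 <- Mw[, 2L] / vge + prec0[1L, 2L] + dc$P[1L, 2L]
  P22 <- Mw[, 1L] / vge + prec0[2L, 2L] + dc$P[2L, 2L]
  prior_lin <- cp$mean %*% prec0
  L1 <- Mw[, 6L] / vge + prior_lin[, 1L] + dc$L[, 1L]
  L2 <- Mw[, 7L] / vge + prior_lin[, 2L] + dc$L[, 2L]
  eta[, c(4L, 6L)] <- draw_bivariate_gaussian(P11, P12, P22, L1, L2)
  st$eta <- eta; env$state <- st

  ## (iii) log residual variances: adaptive random-walk MH ---------------
  phi1 <- eta[, 3L]; phi2 <- eta[, 4L]; phi3 <- eta[, 5L]; phi4 <- eta[, 6L]
  ssr_pb <- person_sum((wpb_t - phi1[pid] * wpb_s - phi3[pid] * wge_s)^2, pid, n)[, 1L]
  ssr_ge <- person_sum((wge_t - phi4[pid] * wpb_s - phi2[pid] * wge_s)^2, pid, n)[, 1L]
  accept <- matrix(FALSE, n, 2L)
  for (j in 1:2) {
    comp <- if (j == 1L) 7L else 8L
    ssr <- if (j == 1L) ssr_pb else ssr_ge
    cp <- cond_normal(env$fitted, st$Sigma, comp, eta)
    dc <- distal_contrib(env, comp)
    prec <- 1 / cp$var[1L, 1L] + dc$P[1L, 1L]
    mean_t <- (cp$mean[, 1L] / cp$var[1L, 1L] + dc$L[, 1L]) / prec
    cur <- eta[, comp]
    prop <- cur + env$step[, j] * stats::rnorm(n)
    logr <- -0.5 * (np * prop + ssr * exp(-prop)) -
      0.5 * prec * (prop - mean_t)^2 +
      0.5 * (np * cur + ssr * exp(-cur)) +
      0.5 * prec * (cur - mean_t)^2
    acc <- log(stats::runif(n)) < logr
    acc[!is.finite(logr)] <- FALSE        # overflow in exp(psi): reject
    eta[acc, comp] <- prop[acc]
    accept[, j] <- acc
    if (adapt_now) {
      # adapt on the smooth acceptance probability (lower-variance signal)
      pa <- pmin(1, exp(logr))
      pa[!is.finite(pa)] <- 0
      env$step[, j] <- env$step[, j] *
        exp(adapt_gain * (pa - env$mcmc$target_accept))
    }
    st$eta <- eta; env$state <- st
  }

  ## (iv) missing momentary values ---------------------------------------
  if (length(env$miss) > 0L) update_missing(env)

  ## (v) fixed-effect blocks gamma (SUR per covariance block) ------------
  update_gamma(env)
  ## (vi) covariance blocks ----------------------------------------------
  update_sigma(env)
  ## (vii) distal equations ----------------------------------------------
  update_distal(env)

  env$fitted <- eta_fitted(env)
  accept
}

# env$fitted stays valid within a sweep (gamma only changes in step v).
eta_fitted_cached <- function(env) env$fitted

update_missing <- function(env) {
  st <- env$state
  eta <- st$eta
  for (k in seq_along(env$miss)) {
    r <- env$miss[k]
    i <- env$obs_person[r]
    vpb <- exp(eta[i, 7L]); vge <- exp(eta[i, 8L])
    p_t <- env$tgt_pair[r]  # pair where r is the target
    p_s <- env$src_pair[r]  # pair where r is the source
    if (env$miss_pb[k]) {
      prec <- 0; lin <- 0
      if (p_t > 0L) {
        sr <- env$src[p_t]
        m <- eta[i, 3L] * (env$ypb[sr] - eta[i, 1L]) +
          eta[i, 5L] * (env$yge[sr] - eta[i, 2L])
        prec <- prec + 1 / vpb; lin <- lin + m / vpb
      } else {
        prec <- prec + 1 / vpb  # conditioned-on record: stationary-ish prior
      }
      if (p_s > 0L) {
        tr <- env$tgt[p_s]
        wge_r <- env$yge[r] - eta[i, 2L]
        wpb_t <- env$ypb[tr] - eta[i, 1L]
        wge_t <- env$yge[tr] - eta[i, 2L]
        prec <- prec + eta[i, 3L]^2 / vpb + eta[i, 6L]^2 / vge
        lin <- lin + eta[i, 3L] * (wpb_t - eta[i, 5L] * wge_r) / vpb +
          eta[i, 6L] * (wge_t - eta[i, 4L] * wge_r) / vge
      }
      env$ypb[r] <- eta[i, 1L] + lin / prec + stats::rnorm(1L) / sqrt(prec)
    }
    if (env$miss_ge[k]) {
      prec <- 0; lin <- 0
      if (p_t > 0L) {
        sr <- env$src[p_t]
        m <- eta[i, 6L] * (env$ypb[sr] - eta[i, 1L]) +
          eta[i, 4L] * (env$yge[sr] - eta[i, 2L])
        prec <- prec + 1 / vge; lin <- lin + m / vge
      } else {
        prec <- prec + 1 / vge
      }
      if (p_s > 0L) {
        tr <- env$tgt[p_s]
        wpb_r <- env$ypb[r] - eta[i, 1L]
        wpb_t <- env$ypb[tr] - eta[i, 1L]
        wge_t <- env$yge[tr] - eta[i, 2L]
        prec <- prec + eta[i, 5L]^2 / vpb + eta[i, 4L]^2 / vge
        lin <- lin + eta[i, 5L] * (wpb_t - eta[i, 3L] * wpb_r) / vpb +
          eta[i, 4L] * (wge_t - eta[i, 6L] * wpb_r) / vge
      }
      env$yge[r] <- eta[i, 2L] + lin / prec + stats::rnorm(1L) / sqrt(prec)
    }
  }
  invisible(env)
}

update_gamma <- function(env) {
  st <- env$state
  for (bi in seq_along(env$blocks)) {
    E <- env$blocks[[bi]]
    m <- length(E)
    Om <- solve(symm(st$Sigma[E, E, drop = FALSE]))
    pdim <- vapply(E, function(e) ncol(env$X[[e]]), integer(1L))
    off <- c(0L, cumsum(pdim))
    P <- matrix(0, sum(pdim), sum(pdim))
    L <- numeric(sum(pdim))
    H <- st$eta[, E, drop = FALSE] %*% Om
    for (a in seq_len(m)) {
      ia <- (off[a] + 1L):off[a + 1L]
      pri <- env$priors$gamma[[ETA_NAMES[E[a]]]]
      for (b in seq_len(m)) {
        ib <- (off[b] + 1L):off[b + 1L]
        P[ia, ib] <- P[ia, ib] + Om[a, b] * env$XtX[[bi]][[a, b]]
      }
      P[ia, ia] <- P[ia, ia] + diag(1 / pri$var, pdim[a])
      L[ia] <- crossprod(env$X[[E[a]]], H[, a]) + pri$mean / pri$var
    }
    U <- chol(symm(P))
    mean_g <- backsolve(U, forwardsolve(t(U), L))
    g <- mean_g + backsolve(U, stats::rnorm(length(L)))
    for (a in seq_len(m)) {
      eq <- ETA_NAMES[E[a]]
      st$gamma[[eq]] <- stats::setNames(g[(off[a] + 1L):off[a + 1L]],
                                        colnames(env$X[[eq]]))
    }
  }
  env$state <- st
  env$fitted <- eta_fitted(env)
  invisible(env)
}

update_sigma <- function(env) {
  st <- env$state
  for (bi in seq_along(env$blocks)) {
    E <- env$blocks[[bi]]
    pri <- env$priors$sigma[[bi]]
    U <- st$eta[, E, drop = FALSE] - env$fitted[, E, drop = FALSE]
    if (pri$type == "invgamma") {
      shape <- pri$shape + env$n / 2
      rate <- pri$rate + sum(U^2) / 2
      st$Sigma[E, E] <- 1 / stats::rgamma(1L, shape, rate = rate)
    } else {
      df <- pri$df + env$n
      S <- pri$scale + crossprod(U)
      st$Sigma[E, E] <- rinvwishart(df, S)
    }
  }
  env$state <- st
  invisible(env)
}

update_distal <- function(env) {
  st <- env$state
  for (d in env$distal_names) {
    ok <- env$ok_distal[[d]]
    y <- env$y_distal[[d]][ok]
    D <- distal_design(env$spec, env$persons, st$eta, d)[ok, , drop = FALSE]
    pri <- env$priors$gamma[[d]]
    P <- crossprod(D) / st$sig2[[d]] + diag(1 / pri$var, ncol(D))
    L <- crossprod(D, y) / st$sig2[[d]] + pri$mean / pri$var
    U <- chol(symm(P))
    mean_g <- backsolve(U, forwardsolve(t(U), L))
    g <- drop(mean_g + backsolve(U, stats::rnorm(ncol(D))))
    st$gamma[[d]] <- stats::setNames(g, colnames(D))
    r <- y - drop(D %*% g)
    pv <- env$priors$distal[[d]]
    st$sig2[[d]] <- 1 / stats::rgamma(1L, pv$shape + sum(ok) / 2,
                                      rate = pv$rate + sum(r^2) / 2)
  }
  env$state <- st
  invisible(env)
}

# ---------------------------------------------------------------------------
# Flatten the global state to a named vector (the stored draw).
# ---------------------------------------------------------------------------
global_param_names <- function(env) {
  nm <- character(0)
  for (eq in c(ETA_NAMES, env$distal_names)) {
    cols <- if (eq %in% ETA_NAMES) colnames(env$X[[eq]]) else
      names(env$state$gamma[[eq]])
    nm <- c(nm, paste("gamma", eq, cols, sep = "."))
  }
  for (E in env$blocks) {
    for (a in seq_along(E)) for (b in a:length(E)) {
      nm <- c(nm, paste("Sigma", ETA_NAMES[E[a]], ETA_NAMES[E[b]], sep = "."))
    }
  }
  c(nm, paste0("sigma2.", env$distal_names))
}

state_to_vec <- function(env) {
  st <- env$state
  out <- numeric(0)
  for (eq in c(ETA_NAMES, env$distal_names)) out <- c(out, st$gamma[[eq]])
  for (E in env$blocks) {
    for (a in seq_along(E)) for (b in a:length(E)) {
      out <- c(out, st$Sigma[E[a], E[b]])
    }
  }
  unname(c(out, st$sig2))
}

# ---------------------------------------------------------------------------
# Public fit / diagnostics
# ---------------------------------------------------------------------------

#' Fit the two-level DSEM by MCMC
#'
#' Runs `n_chains` chains of the Gibbs/Metropolis sampler described in the
#' package vignette. Chains are initialised from jittered per-person
#' least-squares starts ([dsem_init()]); each chain consumes an independent
#' random stream derived from the master seed, so results are reproducible
#' and individual chains do not change when `n_chains` changes.
#'
#' @param ds An `analysis_dataset` from [build_analysis_dataset()].
#' @param spec A [model_spec()].
#' @param priors A `prior_set`, e.g. [default_priors()].
#' @param mcmc An [mcmc_config()].
#' @param seed Master integer seed.
#' @param verbose Print progress.
#' @return An object of class `dsem_draws`: list with `chains` (per chain:
#'   `global` draw matrix with named columns, `eta` array draws x persons x 8,
#'   `accept` per-person psi acceptance rates), `param_names`, `person_ids`,
#'   and `meta` (spec, priors, mcmc, seed, equation designs, timing).
#' @export
dsem_fit <- function(ds, spec = model_spec(), priors = default_priors(spec),
                     mcmc = mcmc_config(), seed = 1L, verbose = FALSE) {
  t0 <- Sys.time()
  rep <- validate_dataset(ds)
  chains <- vector("list", mcmc$n_chains)
  keep <- seq(mcmc$thin, mcmc$n_iters, by = mcmc$thin)
  for (ch in seq_len(mcmc$n_chains)) {
    set.seed(sub_seed(seed, 100L + ch))
    env <- sampler_setup(ds, spec, priors, mcmc)
    init <- dsem_init(ds, spec, jitter_sd = 1)
    sampler_init_state(env, init)
    pn <- global_param_names(env)
    for (it in seq_len(mcmc$n_burnin)) {
      # Robbins-Monro step-size tuning with decaying gain, frozen after burn-in
      sampler_sweep(env, adapt_now = mcmc$adapt,
                    adapt_gain = min(0.2, it^(-0.6)))
    }
    global <- matrix(NA_real_, length(keep), length(pn),
                     dimnames = list(NULL, pn))
    eta_draws <- array(NA_real_, c(length(keep), env$n, 8L),
                       dimnames = list(NULL, NULL, ETA_NAMES))
    acc_tot <- matrix(0, env$n, 2L)
    kslot <- 1L
    for (it in seq_len(mcmc$n_iters)) {
      acc <- sampler_sweep(env, adapt_now = FALSE)
      acc_tot <- acc_tot + acc
      if (kslot <= length(keep) && it == keep[kslot]) {
        global[kslot, ] <- state_to_vec(env)
        eta_draws[kslot, , ] <- env$state$eta
        kslot <- kslot + 1L
      }
    }
    chains[[ch]] <- list(global = global, eta = eta_draws,
                         accept = acc_tot / mcmc$n_iters)
    if (verbose) message("chain ", ch, " done (", length(keep), " draws)")
  }
  structure(list(
    chains = chains,
    param_names = colnames(chains[[1L]]$global),
    person_ids = ds$persons$person_id,
    meta = list(spec = spec, priors = priors, mcmc = mcmc, seed = seed,
                lag_policy = ds$lag_policy, centering = ds$centering,
                eq_columns = lapply(stats::setNames(ETA_NAMES, ETA_NAMES),
                                    function(e) colnames(eta_design(spec, ds$persons, e))),
                distal_columns = lapply(spec$distal_eta, function(ec)
                  c("(Intercept)", ec, spec$distal_fixed)),
                validation = rep,
                elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  ), class = "dsem_draws")
}

#' @export
print.dsem_draws <- function(x, ...) {
  cat("<dsem_draws>\n")
  cat("  chains:", length(x$chains), " draws/chain:", nrow(x$chains[[1L]]$global), "\n")
  cat("  parameters:", length(x$param_names), "global +",
      dim(x$chains[[1L]]$eta)[2L], "x 8 person effects\n")
  cat("  elapsed:", round(x$meta$elapsed_s, 1), "s\n")
  invisible(x)
}

#' Split-chain potential scale reduction diagnostics
#'
#' Gelman-Rubin statistic computed on split chains (each retained chain cut
#' in half), covering every stored global parameter (all fixed-effect
#' coefficients, covariance entries and distal variances).
#'
#' @param draws A [dsem_fit()] result.
#' @param threshold Convergence threshold on the maximum PSR (default 1.10).
#' @return Object of class `convergence_report`: data frame `psr` (parameter,
#'   value), `max_psr`, `converged`.
#' @export
psr <- function(draws, threshold = 1.10) {
  stopifnot(inherits(draws, "dsem_draws"))
  if (length(draws$chains) < 2L) stop("PSR requires at least 2 chains")
  K <- nrow(draws$chains[[1L]]$global)
  half <- K %/% 2L
  if (half < 4L) stop("diagnostic error: fewer than 4 draws per split chain")
  splits <- list()
  for (ch in draws$chains) {
    splits <- c(splits, list(ch$global[seq_len(half), , drop = FALSE],
                             ch$global[(K - half + 1L):K, , drop = FALSE]))
  }
  vals <- vapply(seq_along(draws$param_names), function(j) {
    split_rhat(lapply(splits, function(s) s[, j]))
  }, numeric(1L))
  rep <- data.frame(parameter = draws$param_names, psr = vals)
  structure(list(psr = rep, max_psr = max(vals),
                 converged = max(vals) < threshold, threshold = threshold),
            class = "convergence_report")
}

# Classic split-chain Gelman-Rubin on a list of equal-length sequences.
split_rhat <- function(seqs) {
  k <- length(seqs[[1L]])
  means <- vapply(seqs, mean, numeric(1L))
  vars <- vapply(seqs, stats::var, numeric(1L))
  W <- mean(vars)
  B_over_k <- stats::var(means)
  if (!is.finite(W) || W <= .Machine$double.eps) {
    return(if (B_over_k <= .Machine$double.eps) 1 else Inf)
  }
  sqrt((k - 1) / k + B_over_k / W)
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("<convergence_report>\n")
  cat("  parameters:", nrow(x$psr), "\n")
  cat("  max PSR:", round(x$max_psr, 4), "\n")
  cat("  converged (<", x$threshold, "):", x$converged, "\n")
  invisible(x)
}

#' Persist posterior draws to disk
#'
#' Writes one CSV of global draws per chain plus a JSON manifest (parameter
#' names, chain count, iteration bookkeeping, seed). Person-level draws are
#' optional (they are large).
#'
#' @param draws A `dsem_draws`.
#' @param dir Output directory.
#' @param include_eta Also write per-person random-effect draws.
#' @return Vector of written paths, invisibly.
#' @export
write_draws <- function(draws, dir, include_eta = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (ch in seq_along(draws$chains)) {
    p <- file.path(dir, sprintf("draws_chain%d.csv", ch))
    utils::write.csv(as.data.frame(draws$chains[[ch]]$global), p, row.names = FALSE)
    paths <- c(paths, p)
    if (include_eta) {
      e <- draws$chains[[ch]]$eta
      flat <- matrix(e, nrow = dim(e)[1L])
      colnames(flat) <- paste0(rep(draws$person_ids, times = 8L), ".",
                               rep(ETA_NAMES, each = dim(e)[2L]))
      pe <- file.path(dir, sprintf("eta_chain%d.csv", ch))
      utils::write.csv(as.data.frame(flat), pe, row.names = FALSE)
      paths <- c(paths, pe)
    }
  }
  man <- file.path(dir, "draws_manifest.json")
  jsonlite::write_json(list(
    param_names = draws$param_names,
    n_chains = length(draws$chains),
    n_draws = nrow(draws$chains[[1L]]$global),
    person_ids = draws$person_ids,
    mcmc = unclass(draws$meta$mcmc),
    seed = draws$meta$seed,
    lag_policy = draws$meta$lag_policy,
    eq_columns = draws$meta$eq_columns,
    distal_columns = draws$meta$distal_columns
  ), man, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, man))
}

#' @rdname write_draws
#' @export
read_draws <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "draws_manifest.json"),
                             simplifyVector = TRUE)
  chains <- lapply(seq_len(man$n_chains), function(ch) {
    g <- as.matrix(utils::read.csv(file.path(dir, sprintf("draws_chain%d.csv", ch)),
                                   check.names = FALSE))
    list(global = g, eta = NULL, accept = NULL)
  })
  structure(list(chains = chains, param_names = man$param_names,
                 person_ids = man$person_ids,
                 meta = list(mcmc = man$mcmc, seed = man$seed,
                             lag_policy = man$lag_policy,
                             eq_columns = man$eq_columns,
                             distal_columns = man$distal_columns)),
            class = "dsem_draws")
}

# ---------------------------------------------------------------------------
# Successive-conditional data redraw (Geweke-style sampler validation).
# Redraws every momentary value that is the target of some lag pair from the
# within-person model (records that are never a target are conditioned upon
# and stay fixed), then redraws the distal outcomes. Used by the joint
# distribution test; exported for reproducibility of that check.
# ---------------------------------------------------------------------------
sc_redraw_data <- function(env) {
  st <- env$state
  eta <- st$eta
  # pairs are ordered by person and time, so a single forward pass suffices
  for (p in seq_along(env$src)) {
    i <- env$pid[p]; s <- env$src[p]; t <- env$tgt[p]
    wpb <- env$ypb[s] - eta[i, 1L]; wge <- env$yge[s] - eta[i, 2L]
    env$ypb[t] <- eta[i, 1L] + eta[i, 3L] * wpb + eta[i, 5L] * wge +
      stats::rnorm(1L, 0, sqrt(exp(eta[i, 7L])))
    env$yge[t] <- eta[i, 2L] + eta[i, 6L] * wpb + eta[i, 4L] * wge +
      stats::rnorm(1L, 0, sqrt(exp(eta[i, 8L])))
  }
  for (d in env$distal_names) {
    D <- distal_design(env$spec, env$persons, eta, d)
    env$y_distal[[d]] <- drop(D %*% st$gamma[[d]]) +
      stats::rnorm(env$n, 0, sqrt(st$sig2[[d]]))
  }
  invisible(env)
}
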