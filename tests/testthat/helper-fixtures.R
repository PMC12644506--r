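# Shared fixtures and independent oracles, all built in code at test time.

eta_names <- c("mu_pb", "mu_ge", "phi1", "phi2", "phi3", "phi4",
               "psi_pb", "psi_ge")

# Write a toy ESM CSV; rows is a data frame in the file dialect.
write_toy_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  write.csv(rows, path, row.names = FALSE, na = "")
  path
}

toy_panel_rows <- function() {
  data.frame(person_id = "a", day = 1:3, prompt = 1L,
             time_min = c(500, 510, 520), pb = c(2, 3, 2.5), ge = c(5, 6, 5.5))
}

# Small complete synthetic study for fast end-to-end tests.
small_study <- function(seed = 1, n = 25, days = 6, compliance = 1) {
  design <- design_config(n_persons = n, n_days = days, prompts_per_day = 3,
                          compliance = compliance)
  simulate_study(true_params(), design, seed = seed)
}

# A minimal dsem_draws-shaped object for summary-level tests.
fake_draws <- function(chain_mats) {
  structure(list(
    chains = lapply(chain_mats, function(m) list(global = m, eta = NULL,
                                                 accept = NULL)),
    param_names = colnames(chain_mats[[1]]),
    person_ids = character(0),
    meta = list()
  ), class = "dsem_draws")
}

# Independent within-person oracle: conditional joint normal of y_2..y_T
# given y_1, covariance built by VAR(1) recursion, evaluated with mvtnorm.
oracle_within <- function(y, eta) {
  Tn <- nrow(y)
  mu <- eta[1:2]
  Phi <- matrix(c(eta[3], eta[6], eta[5], eta[4]), 2, 2)
  Q <- diag(exp(eta[7:8]))
  d <- 2 * (Tn - 1)
  mean_vec <- numeric(d)
  V <- matrix(0, d, d)
  m <- y[1, ] - mu
  C <- matrix(0, 2, 2)
  means <- list(); covs <- list()
  for (t in 2:Tn) {
    m <- Phi %*% m
    C <- Phi %*% C %*% t(Phi) + Q
    means[[t]] <- m; covs[[t]] <- C
  }
  for (t in 2:Tn) {
    it <- (2 * (t - 2) + 1):(2 * (t - 1))
    mean_vec[it] <- means[[t]]
    V[it, it] <- covs[[t]]
    if (t < Tn) {
      P <- diag(2)
      for (s in (t + 1):Tn) {
        P <- Phi %*% P
        is <- (2 * (s - 2) + 1):(2 * (s - 1))
        V[it, is] <- covs[[t]] %*% t(P)
        V[is, it] <- t(V[it, is])
      }
    }
  }
  w <- as.vector(t(sweep(y[-1, , drop = FALSE], 2, mu)))
  mvtnorm::dmvnorm(w, mean_vec, V, log = TRUE)
}

# Independent between-level oracle: direct joint-normal evaluation.
oracle_between <- function(eta, distals, predictors, params, spec) {
  n <- nrow(eta)
  ll <- 0
  for (i in seq_len(n)) {
    m <- vapply(eta_names, function(e) {
      X <- dynesm:::eta_design(spec, predictors[i, , drop = FALSE], e)
      drop(X %*% params$gamma[[e]])
    }, numeric(1))
    ll <- ll + mvtnorm::dmvnorm(eta[i, ], m, params$Sigma, log = TRUE)
    for (d in names(spec$distal_eta)) {
      y <- distals[[d]][i]
      if (is.na(y)) next
      D <- dynesm:::distal_design(spec, predictors[i, , drop = FALSE],
                                  eta[i, , drop = FALSE], d)
      ll <- ll + dnorm(y, drop(D %*% params$gamma[[d]]),
                       sqrt(params$sig2_distal[[d]]), log = TRUE)
    }
  }
  ll
}

# Finite-moment priors for the successive-conditional sampler check.
geweke_priors <- function(spec) {
  priors <- default_priors(spec, gamma_mean = 0, gamma_var = 0.25,
                           ig_shape = 5, ig_rate = 0.2)
  for (b in seq_along(priors$sigma)) {
    if (priors$sigma[[b]]$type == "invwishart") {
      p <- length(priors$sigma[[b]]$block)
      priors$sigma[[b]]$df <- p + 6L
      priors$sigma[[b]]$scale <- diag(0.25, p)
    }
  }
  priors$distal <- list(follow_pb = list(shape = 5, rate = 0.2),
                        follow_ge = list(shape = 5, rate = 0.2))
  priors
}

# Draw the sampler state from the prior (used by the Geweke-style check).
draw_prior_state <- function(env, mcmc) {
  pr <- env$priors
  gamma <- list()
  for (eq in c(eta_names, env$distal_names)) {
    p <- length(pr$gamma[[eq]]$mean)
    nm <- if (eq %in% eta_names) colnames(env$X[[eq]]) else
      c("(Intercept)", env$spec$distal_eta[[eq]], env$spec$distal_fixed)
    gamma[[eq]] <- stats::setNames(
      rnorm(p, pr$gamma[[eq]]$mean, sqrt(pr$gamma[[eq]]$var)), nm)
  }
  Sigma <- matrix(0, 8, 8, dimnames = list(eta_names, eta_names))
  for (bi in seq_along(env$blocks)) {
    E <- env$blocks[[bi]]
    pb <- pr$sigma[[bi]]
    Sigma[E, E] <- if (pb$type == "invgamma") {
      1 / rgamma(1, pb$shape, rate = pb$rate)
    } else {
      dynesm:::rinvwishart(pb$df, pb$scale)
    }
  }
  sig2 <- c(follow_pb = 1 / rgamma(1, pr$distal$follow_pb$shape,
                                   rate = pr$distal$follow_pb$rate),
            follow_ge = 1 / rgamma(1, pr$distal$follow_ge$shape,
                                   rate = pr$distal$follow_ge$rate))
  env$state <- list(eta = matrix(0, env$n, 8), gamma = gamma, Sigma = Sigma,
                    sig2 = sig2)
  env$fitted <- dynesm:::eta_fitted(env)
  eta <- env$fitted + dynesm:::rmvnorm_chol(env$n, rep(0, 8), Sigma)
  colnames(eta) <- eta_names
  env$state$eta <- eta
  env$step <- matrix(mcmc$init_step, env$n, 2)
  invisible(env)
}
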