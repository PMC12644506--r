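# Probabilistic model definition: within-person bivariate lag-1 process with
# person-specific location and log-scale parameters, between-person
# structural regressions, distal follow-up outcomes, and priors.
#
# Person-specific random effects, in fixed order:
#   eta_i = (mu_pb, mu_ge, phi1, phi2, phi3, phi4, psi_pb, psi_ge)
# where mu_* are latent means (score units), phi1/phi2 autoregressive
# coefficients, phi3 the lagged ge -> pb cross-effect, phi4 the lagged
# pb -> ge cross-effect, and psi_* log residual variances.
#
# Within level, for each lag pair (t-1, t) of person i, with
# w_t = y_t - mu_i:
#   w_t = Phi_i w_{t-1} + e_t,  e_t ~ N(0, diag(exp psi_pb, exp psi_ge)),
#   Phi_i = [[phi1, phi3], [phi4, phi2]].
# The first observation of each chain segment is conditioned upon and
# contributes no likelihood term.
#
# Between level:
#   eta_i = Gamma' x_i + u_i,  u_i ~ N(0, Sigma_eta)
#   follow_i = delta' (eta-components, baselines, covariates) + e,
# with the predictor map held in the model_spec.

#' Model specification
#'
#' Defines which between-person predictors enter each random-effect equation
#' and each distal-outcome equation, and the structure imposed on the
#' random-effect residual covariance.
#'
#' The default predictor map mirrors the substantive model: each construct's
#' latent mean, autoregression and log residual variance are regressed on the
#' construct's own (centered) baseline plus the four sociodemographic
#' covariates; the two cross-lagged coefficients are regressed on the
#' covariates only; each follow-up outcome is regressed on its construct's
#' latent mean, log variance and autoregression, both centered baselines, and
#' the covariates. `predictors = "intercept_only"` drops all between-person
#' predictors (useful for small validation runs), keeping only own-construct
#' dynamic parameters in the distal equations.
#'
#' @param sigma_structure Structure of the random-effect residual covariance:
#'   `"blocks"` (default: mu, phi_AR and psi correlated within construct,
#'   cross-lag coefficients independent), `"diagonal"`, or `"full"`.
#' @param predictors `"default"` or `"intercept_only"`.
#' @param resid_cor Within-level residual correlation of the two processes;
#'   only `0` (default) is currently supported for estimation.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(sigma_structure = c("blocks", "diagonal", "full"),
                       predictors = c("default", "intercept_only"),
                       resid_cor = 0) {
  sigma_structure <- match.arg(sigma_structure)
  predictors <- match.arg(predictors)
  if (resid_cor != 0) {
    stop("only resid_cor = 0 is supported in this version")
  }
  covs <- c("gender_female", "single", "income_c", "needs")
  if (predictors == "default") {
    eta_predictors <- list(
      mu_pb = c("base_pb_c", covs), mu_ge = c("base_ge_c", covs),
      phi1 = c("base_pb_c", covs), phi2 = c("base_ge_c", covs),
      phi3 = covs, phi4 = covs,
      psi_pb = c("base_pb_c", covs), psi_ge = c("base_ge_c", covs)
    )
    distal_fixed <- c("base_pb_c", "base_ge_c", covs)
  } else {
    eta_predictors <- stats::setNames(rep(list(character(0)), 8L), ETA_NAMES)
    distal_fixed <- character(0)
  }
  distal_eta <- list(
    follow_pb = c("mu_pb", "psi_pb", "phi1"),
    follow_ge = c("mu_ge", "psi_ge", "phi2")
  )
  blocks <- switch(sigma_structure,
    blocks = list(c("mu_pb", "phi1", "psi_pb"), c("mu_ge", "phi2", "psi_ge"),
                  "phi3", "phi4"),
    diagonal = as.list(ETA_NAMES),
    full = list(ETA_NAMES)
  )
  structure(list(sigma_structure = sigma_structure,
                 predictors = predictors,
                 eta_predictors = eta_predictors,
                 distal_eta = distal_eta,
                 distal_fixed = distal_fixed,
                 resid_cor = resid_cor,
                 blocks = blocks),
            class = "model_spec")
}

# Design matrix (with intercept) for one eta equation, from the centered
# person table of an analysis_dataset.
eta_design <- function(spec, persons, eq) {
  preds <- spec$eta_predictors[[eq]]
  X <- cbind(`(Intercept)` = rep(1, nrow(persons)))
  if (length(preds) > 0L) {
    X <- cbind(X, as.matrix(persons[preds]))
    colnames(X) <- c("(Intercept)", preds)
  }
  X
}

# Distal design: intercept, own-construct eta components (current values),
# then the fixed between-person predictors.
distal_design <- function(spec, persons, eta, outcome) {
  ecols <- spec$distal_eta[[outcome]]
  X <- cbind(1, eta[, match(ecols, ETA_NAMES), drop = FALSE])
  colnames(X) <- c("(Intercept)", ecols)
  if (length(spec$distal_fixed) > 0L) {
    F <- as.matrix(persons[spec$distal_fixed])
    X <- cbind(X, F)
  }
  X
}

#' Model parameter container
#'
#' @param gamma Named list of coefficient vectors, one per random-effect
#'   equation (`mu_pb`, ..., `psi_ge`) and per distal equation (`follow_pb`,
#'   `follow_ge`), each named by predictor (intercept first).
#' @param Sigma 8 x 8 residual covariance of the random effects (row/column
#'   order as `eta` components); entries outside the spec's blocks must be 0.
#' @param sig2_distal Length-2 named vector of distal residual variances.
#' @return An object of class `model_params`.
#' @export
model_params <- function(gamma, Sigma, sig2_distal) {
  stopifnot(is.list(gamma), is.matrix(Sigma), nrow(Sigma) == 8L, ncol(Sigma) == 8L)
  ev <- eigen(symm(Sigma), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("numerical error: Sigma_eta is not positive definite")
  if (any(sig2_distal <= 0)) stop("distal residual variances must be positive")
  dimnames(Sigma) <- list(ETA_NAMES, ETA_NAMES)
  structure(list(gamma = gamma, Sigma = Sigma,
                 sig2_distal = stats::setNames(as.numeric(sig2_distal),
                                               c("follow_pb", "follow_ge"))),
            class = "model_params")
}

#' Within-person log-likelihood of one person's series
#'
#' Sum over lag pairs of the conditional Gaussian density
#' `log N(w_t; Phi w_{t-1}, diag(exp psi_pb, exp psi_ge))` with
#' `w = y - mu`. The first observation of each chain segment is conditioned
#' upon and contributes nothing.
#'
#' @param y Numeric matrix (T x 2) of observed scores, columns `pb`, `ge`.
#' @param eta Numeric vector of length 8 in [ETA_NAMES] order (names optional).
#' @param pairs Two-column integer matrix of (src, tgt) row indices into `y`;
#'   defaults to consecutive rows.
#' @return Log-density (scalar) with attribute `n_pairs`. An empty pair set
#'   returns 0 with a warning.
#' @export
within_loglik <- function(y, eta, pairs = NULL) {
  y <- as.matrix(y)
  stopifnot(ncol(y) == 2L, length(eta) == 8L)
  eta <- as.numeric(eta)
  if (any(!is.finite(eta[7:8]))) stop("psi must be finite")
  if (is.null(pairs)) {
    pairs <- if (nrow(y) >= 2L) cbind(seq_len(nrow(y) - 1L), 2:nrow(y)) else
      matrix(integer(0), 0L, 2L)
  }
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  if (nrow(pairs) == 0L) {
    warning("empty lag-pair set: within_loglik is 0")
    return(structure(0, n_pairs = 0L))
  }
  mu <- eta[1:2]
  w_s <- sweep(y[pairs[, 1L], , drop = FALSE], 2L, mu)
  w_t <- sweep(y[pairs[, 2L], , drop = FALSE], 2L, mu)
  v <- exp(eta[7:8])
  m_pb <- eta[3L] * w_s[, 1L] + eta[5L] * w_s[, 2L]
  m_ge <- eta[6L] * w_s[, 1L] + eta[4L] * w_s[, 2L]
  ll <- sum(lognorm(w_t[, 1L], m_pb, v[1L])) + sum(lognorm(w_t[, 2L], m_ge, v[2L]))
  structure(ll, n_pairs = nrow(pairs))
}

#' Between-person log-density of random effects and distal outcomes
#'
#' Log multivariate-normal density of the random-effect residuals
#' `eta_i - Gamma' x_i` under `Sigma_eta`, plus Gaussian log-densities of the
#' two follow-up outcomes given their linear predictors. Rows with a missing
#' distal outcome contribute no distal term.
#'
#' @param eta Numeric matrix (n x 8) of random effects (or a length-8 vector).
#' @param distals Data frame or matrix with columns `follow_pb`, `follow_ge`.
#' @param predictors Centered person predictor table (the `persons` element
#'   of an `analysis_dataset`).
#' @param params A [model_params()].
#' @param spec A [model_spec()].
#' @return Total log-density (scalar).
#' @export
between_loglik <- function(eta, distals, predictors, params,
                           spec = model_spec()) {
  if (is.null(dim(eta))) eta <- matrix(eta, nrow = 1L)
  stopifnot(ncol(eta) == 8L)
  n <- nrow(eta)
  distals <- as.data.frame(distals)
  m <- matrix(0, n, 8L)
  for (e in seq_along(ETA_NAMES)) {
    X <- eta_design(spec, predictors, ETA_NAMES[e])
    m[, e] <- drop(X %*% params$gamma[[ETA_NAMES[e]]])
  }
  U <- eta - m
  Sig <- symm(params$Sigma)
  L <- tryCatch(chol(Sig),
                error = function(e) stop("numerical error: Sigma_eta is not positive definite"))
  z <- U %*% backsolve(L, diag(8L))
  ll <- -n * (4 * log(2 * pi) + sum(log(diag(L)))) - 0.5 * sum(z^2)
  for (d in names(spec$distal_eta)) {
    D <- distal_design(spec, predictors, eta, d)
    fit <- drop(D %*% params$gamma[[d]])
    obsy <- distals[[d]]
    ok <- !is.na(obsy)
    ll <- ll + sum(lognorm(obsy[ok], fit[ok], params$sig2_distal[[d]]))
  }
  ll
}

#' Stationarity check for a lag coefficient vector
#'
#' Computes the spectral radius of the person-specific lag matrix
#' `Phi = [[phi1, phi3], [phi4, phi2]]`.
#'
#' @param phi Numeric vector `(phi1, phi2, phi3, phi4)`.
#' @return List with `stationary` (radius < 1) and `radius`.
#' @export
check_stationarity <- function(phi) {
  stopifnot(length(phi) == 4L)
  Phi <- matrix(c(phi[1L], phi[4L], phi[3L], phi[2L]), 2L, 2L)
  radius <- max(Mod(eigen(Phi, only.values = TRUE)$values))
  list(stationary = radius < 1, radius = radius)
}

# Spectral radii for an n x 4 matrix of (phi1, phi2, phi3, phi4) rows,
# using the closed form for 2x2 eigenvalues.
spectral_radius2 <- function(phi) {
  tr <- phi[, 1L] + phi[, 2L]
  det <- phi[, 1L] * phi[, 2L] - phi[, 3L] * phi[, 4L]
  disc <- tr^2 - 4 * det
  out <- numeric(nrow(phi))
  pos <- disc >= 0
  out[pos] <- pmax(abs((tr[pos] + sqrt(disc[pos])) / 2),
                   abs((tr[pos] - sqrt(disc[pos])) / 2))
  out[!pos] <- sqrt(det[!pos])  # complex pair: modulus = sqrt(det)
  out
}

#' Default diffuse priors
#'
#' Serialized prior set matching common "software default" diffuse choices:
#' independent normal(0, 1e6) priors on every regression coefficient,
#' inverse-Wishart priors with degrees of freedom `dim + 2` and scale
#' `0.01 * I` on each random-effect covariance block (inverse-gamma
#' `(0.001, 0.001)` when a block is scalar or the structure is diagonal),
#' and inverse-gamma `(0.001, 0.001)` priors on the distal residual
#' variances.
#'
#' @param spec A [model_spec()].
#' @param gamma_mean,gamma_var Normal prior mean and variance applied to
#'   every coefficient.
#' @param iw_scale_diag Diagonal value of each inverse-Wishart scale matrix.
#' @param ig_shape,ig_rate Inverse-gamma shape/rate for scalar variances.
#' @return An object of class `prior_set`: per-equation normal prior means
#'   and variances, per-block covariance priors, and distal variance priors.
#' @export
default_priors <- function(spec = model_spec(), gamma_mean = 0,
                           gamma_var = 1e6, iw_scale_diag = 0.01,
                           ig_shape = 0.001, ig_rate = 0.001) {
  stopifnot(gamma_var > 0, iw_scale_diag > 0, ig_shape > 0, ig_rate > 0)
  eqs <- c(ETA_NAMES, "follow_pb", "follow_ge")
  gamma <- list()
  for (eq in eqs) {
    p <- if (eq %in% ETA_NAMES) length(spec$eta_predictors[[eq]]) + 1L
         else length(spec$distal_eta[[eq]]) + length(spec$distal_fixed) + 1L
    gamma[[eq]] <- list(mean = rep(gamma_mean, p), var = rep(gamma_var, p))
  }
  sigma <- lapply(spec$blocks, function(b) {
    if (length(b) == 1L) {
      list(type = "invgamma", shape = ig_shape, rate = ig_rate, block = b)
    } else {
      list(type = "invwishart", df = length(b) + 2L,
           scale = diag(iw_scale_diag, length(b)), block = b)
    }
  })
  distal <- list(follow_pb = list(shape = ig_shape, rate = ig_rate),
                 follow_ge = list(shape = ig_shape, rate = ig_rate))
  structure(list(gamma = gamma, sigma = sigma, distal = distal),
            class = "prior_set")
}

#' Serialize / deserialize specs and priors
#'
#' `spec_to_config()` renders a [model_spec()], [default_priors()] result and
#' [mcmc_config()] into a plain list suitable for YAML/JSON serialization;
#' `config_to_spec()` inverts it. The serialized keys are part of the public
#' contract (version field `config_version = 1`).
#'
#' @param spec A `model_spec`.
#' @param priors A `prior_set`.
#' @param mcmc An `mcmc_config`.
#' @return A plain nested list (`spec_to_config`), or the rebuilt objects
#'   (`config_to_spec`).
#' @export
spec_to_config <- function(spec = model_spec(), priors = default_priors(spec),
                           mcmc = mcmc_config()) {
  list(config_version = 1L,
       model = list(sigma_structure = spec$sigma_structure,
                    predictors = spec$predictors,
                    resid_cor = spec$resid_cor),
       priors = list(gamma_mean = priors$gamma[[1L]]$mean[1L],
                     gamma_var = priors$gamma[[1L]]$var[1L],
                     iw_scale_diag = if (priors$sigma[[1L]]$type == "invwishart")
                       priors$sigma[[1L]]$scale[1L, 1L] else 0.01,
                     ig_shape = priors$distal$follow_pb$shape,
                     ig_rate = priors$distal$follow_pb$rate),
       mcmc = unclass(mcmc))
}

#' @rdname spec_to_config
#' @param config A list as produced by `spec_to_config()` (for example read
#'   back from YAML).
#' @export
config_to_spec <- function(config) {
  stopifnot(identical(as.integer(config$config_version), 1L))
  spec <- model_spec(sigma_structure = config$model$sigma_structure,
                     predictors = config$model$predictors,
                     resid_cor = config$model$resid_cor %||% 0)
  priors <- default_priors(spec,
                           gamma_mean = config$priors$gamma_mean %||% 0,
                           gamma_var = config$priors$gamma_var %||% 1e6,
                           iw_scale_diag = config$priors$iw_scale_diag %||% 0.01,
                           ig_shape = config$priors$ig_shape %||% 0.001,
                           ig_rate = config$priors$ig_rate %||% 0.001)
  mcmc <- do.call(mcmc_config, config$mcmc[intersect(names(config$mcmc),
    names(formals(mcmc_config)))])
  list(spec = spec, priors = priors, mcmc = mcmc)
}
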