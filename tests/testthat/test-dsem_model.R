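# Density kernels, stationarity check, priors, config round-trip.

test_that("within_loglik handles trivial cases", {
  # zero lag pairs: 0 with a warning
  y <- matrix(c(2, 5), 1, 2)
  expect_warning(ll <- within_loglik(y, rep(0, 8)), "empty lag-pair")
  expect_equal(as.numeric(ll), 0)

  # single pair, Phi = 0, mu = 0, psi = 0, w_t = 0: two standard normals at 0
  y <- rbind(c(1.3, -0.4), c(0, 0))
  ll <- within_loglik(y, c(0, 0, 0, 0, 0, 0, 0, 0))
  expect_equal(as.numeric(ll), -log(2 * pi), tolerance = 1e-12)

  expect_error(within_loglik(y, c(0, 0, 0, 0, 0, 0, Inf, 0)), "psi")
})

test_that("within_loglik matches the frozen hand-computed 3-occasion value", {
  # pb = (1, .5, -.2), ge = (0, 0, 0); phi1 = .5, psi_pb = log .25, rest 0.
  # Expected value computed independently as a sum of univariate normal
  # log-densities before the implementation was written.
  y <- cbind(c(1, 0.5, -0.2), c(0, 0, 0))
  eta <- c(0, 0, 0.5, 0, 0, 0, log(0.25), 0)
  expect_equal(as.numeric(within_loglik(y, eta)), -2.694459771699,
               tolerance = 1e-10)
})

test_that("within + between densities agree with the independent joint-normal oracle", {
  set.seed(31)
  spec <- model_spec()
  for (rep in 1:6) {
    n <- sample(1:3, 1)
    Tn <- sample(2:4, 1)
    predictors <- data.frame(base_pb_c = rnorm(n), base_ge_c = rnorm(n),
                             income_c = rnorm(n), gender_female = rbinom(n, 1, .5),
                             single = rbinom(n, 1, .2), needs = rbinom(n, 1, .2))
    gamma <- default_truth <- true_params(spec = spec)$params$gamma
    Sigma <- true_params()$params$Sigma
    params <- model_params(gamma, Sigma, c(0.4, 0.5))
    eta <- matrix(rnorm(n * 8, 0, 0.5), n, 8)
    eta[, 1] <- eta[, 1] + 2; eta[, 2] <- eta[, 2] + 5.5
    colnames(eta) <- eta_names
    distals <- data.frame(follow_pb = rnorm(n, 2.5), follow_ge = rnorm(n, 5.5))
    ll_w <- 0
    ll_w_oracle <- 0
    for (i in seq_len(n)) {
      y <- matrix(rnorm(Tn * 2, c(2, 5.5), 1), Tn, 2, byrow = TRUE)
      ll_w <- ll_w + as.numeric(within_loglik(y, eta[i, ]))
      ll_w_oracle <- ll_w_oracle + oracle_within(y, eta[i, ])
    }
    ll_b <- between_loglik(eta, distals, predictors, params, spec)
    ll_b_oracle <- oracle_between(eta, distals, predictors, params, spec)
    expect_equal(ll_w, ll_w_oracle, tolerance = 1e-8)
    expect_equal(ll_b, ll_b_oracle, tolerance = 1e-8)
  }
})

test_that("between_loglik trivial values", {
  spec <- model_spec(predictors = "intercept_only")
  n <- 1L
  predictors <- data.frame(base_pb_c = 0, base_ge_c = 0, income_c = 0,
                           gender_female = 0, single = 0, needs = 0)
  gamma <- lapply(true_params(spec = spec)$params$gamma, function(v) v)
  eta <- matrix(vapply(eta_names, function(e) gamma[[e]][["(Intercept)"]],
                       numeric(1)), 1, 8)
  colnames(eta) <- eta_names
  params <- model_params(gamma, diag(8), c(1, 1))
  # eta at its conditional mean, Sigma = I, no distals: -4 log(2 pi)
  ll0 <- between_loglik(eta, data.frame(follow_pb = NA, follow_ge = NA),
                        predictors, params, spec)
  expect_equal(ll0, -4 * log(2 * pi), tolerance = 1e-12)
  # each distal at its conditional mean with unit variance adds -log(2 pi)/2
  D <- dynesm:::distal_design(spec, predictors, eta, "follow_pb")
  fpb <- drop(D %*% gamma$follow_pb)
  ll1 <- between_loglik(eta, data.frame(follow_pb = fpb, follow_ge = NA),
                        predictors, params, spec)
  expect_equal(ll1 - ll0, -0.5 * log(2 * pi), tolerance = 1e-12)
  # non-PD Sigma is a named numerical error
  expect_error(model_params(gamma, matrix(0, 8, 8), c(1, 1)), "positive definite")
})

test_that("within_loglik is translation-equivariant in each construct", {
  set.seed(7)
  y <- matrix(rnorm(8, 3, 1), 4, 2)
  eta <- c(3, 3, 0.4, 0.2, -0.1, 0.1, log(0.3), log(0.5))
  for (c_shift in c(-2, 0.7, 10)) {
    y2 <- y; y2[, 1] <- y2[, 1] + c_shift
    eta2 <- eta; eta2[1] <- eta2[1] + c_shift
    expect_equal(as.numeric(within_loglik(y2, eta2)),
                 as.numeric(within_loglik(y, eta)), tolerance = 1e-10)
  }
})

test_that("with Phi = 0 the Gaussian MLE of psi_pb maximises within_loglik", {
  set.seed(8)
  y <- matrix(rnorm(40, 0, 1.3), 20, 2)
  base <- c(0, 0, 0, 0, 0, 0, 0, 0)
  # lag pairs condition on the first observation: the MLE uses targets only
  msd <- mean(y[-1, 1]^2)
  at <- function(psi) {
    e <- base; e[7] <- psi
    as.numeric(within_loglik(y, e))
  }
  opt <- optimize(at, c(-3, 3), maximum = TRUE)$maximum
  expect_equal(opt, log(msd), tolerance = 1e-4)
})

test_that("check_stationarity computes the spectral radius", {
  z <- check_stationarity(c(0, 0, 0, 0))
  expect_true(z$stationary)
  expect_equal(z$radius, 0)
  # published point estimates are comfortably stationary
  z2 <- check_stationarity(c(0.338, 0.205, -0.004, -0.099))
  expect_true(z2$stationary)
  expect_lt(z2$radius, 0.4)
  z3 <- check_stationarity(c(1.2, 0, 0, 0))
  expect_false(z3$stationary)
  expect_equal(z3$radius, 1.2)
  # closed form agrees with eigen for complex and real spectra
  set.seed(9)
  phis <- matrix(runif(40, -0.9, 0.9), 10, 4)
  r1 <- dynesm:::spectral_radius2(phis)
  r2 <- apply(phis, 1, function(x) check_stationarity(x)$radius)
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("default_priors serialize the documented diffuse defaults", {
  spec <- model_spec()
  pr <- default_priors(spec)
  expect_true(all(vapply(pr$gamma, function(g) all(g$var == 1e6), logical(1))))
  types <- vapply(pr$sigma, `[[`, "", "type")
  expect_equal(types, c("invwishart", "invwishart", "invgamma", "invgamma"))
  expect_equal(pr$sigma[[1]]$df, 5L)  # dim 3 + 2

  pr_d <- default_priors(model_spec(sigma_structure = "diagonal"))
  expect_length(pr_d$sigma, 8L)
  expect_true(all(vapply(pr_d$sigma, `[[`, "", "type") == "invgamma"))

  pr_f <- default_priors(model_spec(sigma_structure = "full"))
  expect_length(pr_f$sigma, 1L)
  expect_equal(pr_f$sigma[[1]]$df, 10L)  # dim 8 + 2
})

test_that("spec/prior/mcmc configs round-trip through the serialized form", {
  spec <- model_spec(sigma_structure = "diagonal")
  mc <- mcmc_config(n_chains = 3, n_iters = 400, n_burnin = 100, thin = 4)
  cfg <- spec_to_config(spec, default_priors(spec, gamma_var = 100), mc)
  # through YAML text, as the CLI consumes it
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, path)
  back <- config_to_spec(yaml::read_yaml(path))
  expect_equal(back$spec$sigma_structure, "diagonal")
  expect_equal(back$priors$gamma$mu_pb$var[1], 100)
  expect_equal(back$mcmc$n_iters, 400L)
  expect_equal(back$mcmc$thin, 4L)
})
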