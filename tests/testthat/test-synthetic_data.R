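# Synthetic study generator: schedules, compliance, dynamics, between-person
# structure, follow-ups, reproducibility.

test_that("schedule respects the design and compliance", {
  d1 <- design_config(n_persons = 4, compliance = 1)
  s1 <- simulate_schedule(d1, seed = 1)
  expect_equal(sum(s1$answered), 4 * 105)
  expect_true(all(s1$time_min >= 480 & s1$time_min < 1200))
  # times sorted within person-day
  expect_true(all(tapply(s1$time_min, paste(s1$person, s1$day),
                         function(x) !is.unsorted(x))))
  # determinism
  expect_identical(simulate_schedule(d1, seed = 1), s1)
  expect_false(identical(simulate_schedule(d1, seed = 2), s1))
})

test_that("mean responses per person matches the binomial expectation", {
  d <- design_config(n_persons = 600)
  s <- simulate_schedule(d, seed = 5)
  m <- sum(s$answered) / 600
  se <- sqrt(105 * 0.47 * 0.53 / 600)
  expect_lt(abs(m - 105 * 0.47), 4 * se)
})

test_that("degenerate truth collapses eta to the fixed means", {
  tp <- true_params(Sigma = diag(1e-12, 8))
  # zero out all non-intercept coefficients
  g <- tp$params$gamma
  for (eq in names(g)) g[[eq]][-1] <- 0
  tp2 <- true_params(gamma = g, Sigma = diag(1e-12, 8))
  p <- simulate_persons(tp2, design_config(n_persons = 50, n_days = 2), seed = 2)
  expect_equal(unname(colMeans(p$eta)),
               c(2.022, 5.799, 0.338, 0.205, -0.004, -0.099,
                 log(0.179), log(0.401)), tolerance = 1e-4)
  expect_lt(max(apply(p$eta, 2, sd)), 1e-5)
})

test_that("baseline shift of +1 scales the burnout residual variance by exp(0.675)", {
  p <- simulate_persons(true_params(Sigma = diag(1e-12, 8)),
                        design_config(n_persons = 400, n_days = 2), seed = 3)
  fit <- lm(p$eta[, "psi_pb"] ~ base_pb_c + gender_female + single +
              income_c + needs, data = p$predictors)
  expect_equal(unname(coef(fit)["base_pb_c"]), 0.675, tolerance = 1e-6)
  expect_equal(exp(unname(coef(fit)["(Intercept)"])), 0.179, tolerance = 1e-6)
  # one unit above the sample average: 0.179 -> 0.352
  expect_equal(round(exp(coef(fit)["(Intercept)"] + coef(fit)["base_pb_c"]), 3),
               0.352, ignore_attr = TRUE)
})

test_that("eta means over many persons match the stated truth", {
  p <- simulate_persons(true_params(), design_config(n_persons = 2000), seed = 7)
  truth <- c(2.022, 5.799, 0.338, 0.205, -0.004, -0.099,
             log(0.179), log(0.401))
  se <- apply(p$eta, 2, sd) / sqrt(2000)
  expect_true(all(abs(colMeans(p$eta) - truth) < 4 * se))
  # stationarity guard holds for all accepted persons
  rad <- apply(p$eta[, 3:6], 1, function(x) check_stationarity(x)$radius)
  expect_true(all(rad < 0.98))
})

test_that("panel dynamics follow the person AR(1) law", {
  # phi1 = 0.5, everything else off: lag-1 autocorrelation ~ 0.5 and
  # stationary variance exp(psi)/(1 - phi1^2)
  eta <- matrix(c(0, 0, 0.5, 0, 0, 0, log(1), log(1)), 1, 8)
  d <- design_config(n_persons = 1, n_days = 5000, prompts_per_day = 3,
                     compliance = 1)
  panel <- simulate_panel(eta, simulate_schedule(d, seed = 3), d, seed = 3)
  x <- panel$pb
  expect_equal(cor(x[-1], x[-length(x)]), 0.5, tolerance = 0.03)
  expect_equal(var(x), 1 / (1 - 0.25), tolerance = 0.06)
  # Phi = 0: white noise, lag-1 autocorrelation ~ 0
  eta0 <- matrix(c(0, 0, 0, 0, 0, 0, 0, 0), 1, 8)
  p0 <- simulate_panel(eta0, simulate_schedule(d, seed = 4), d, seed = 4)
  expect_lt(abs(cor(p0$pb[-1], p0$pb[-nrow(p0)])), 0.03)
})

test_that("follow-ups follow the distal equations", {
  # all coefficients zero, zero residual: follow-ups equal the intercepts
  tp <- true_params(sig2_distal = c(follow_pb = 1e-12, follow_ge = 1e-12))
  g <- tp$params$gamma
  g$follow_pb[-1] <- 0; g$follow_ge[-1] <- 0
  tp0 <- true_params(gamma = g, sig2_distal = c(1e-12, 1e-12))
  st <- simulate_study(tp0, design_config(n_persons = 20, n_days = 2), seed = 5)
  expect_equal(st$persons$follow_pb, rep(1.272, 20), tolerance = 1e-5)
  expect_equal(st$persons$follow_ge, rep(4.292, 20), tolerance = 1e-5)

  # OLS on the true eta recovers the 0.571 path at large N
  st2 <- simulate_study(true_params(),
                        design_config(n_persons = 4000, n_days = 2,
                                      compliance = 1), seed = 6)
  d <- cbind(as.data.frame(st2$truth$eta), st2$truth$predictors)
  f <- lm(st2$persons$follow_pb ~ mu_pb + psi_pb + phi1 + base_pb_c +
            base_ge_c + gender_female + single + income_c + needs, data = d)
  expect_equal(unname(coef(f)["mu_pb"]), 0.571, tolerance = 0.05)
})

test_that("simulate_study composes reproducibly", {
  st <- simulate_study(true_params(),
                       design_config(n_persons = 40, n_days = 10), seed = 11)
  # same seed: byte-identical CSV exports
  d1 <- tempfile(); d2 <- tempfile()
  write_study(st, d1)
  st2 <- simulate_study(true_params(),
                        design_config(n_persons = 40, n_days = 10), seed = 11)
  write_study(st2, d2)
  for (f in c("esm_panel.csv", "persons.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # truth manifest re-simulation reproduces the stored panel exactly
  expect_identical(as.data.frame(st2$panel), as.data.frame(st$panel))
  # emitted studies pass structural validation
  ds <- build_analysis_dataset(st$panel, st$persons)
  rep <- validate_dataset(ds)
  expect_length(rep$degenerate, 0L)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("clipping is available but off by default", {
  eta <- matrix(c(1.2, 6.8, 0, 0, 0, 0, log(4), log(4)), 1, 8)
  d <- design_config(n_persons = 1, n_days = 200, prompts_per_day = 3,
                     compliance = 1)
  sched <- simulate_schedule(d, seed = 9)
  unclipped <- simulate_panel(eta, sched, d, seed = 9)
  clipped <- simulate_panel(eta, sched, d, seed = 9, clip = TRUE)
  expect_true(any(unclipped$pb < 1 | unclipped$pb > 7))
  expect_true(all(clipped$pb >= 1 & clipped$pb <= 7))
})
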