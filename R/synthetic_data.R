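# Synthetic ESM study generator: prompt schedules with partial compliance,
# between-person structure (covariates, baselines, random effects), the
# within-person bivariate lag-1 process, and distal follow-up outcomes.
# Defaults reproduce the design of a 35-day, three-prompts-per-day study of
# 293 parents with roughly 49 answered prompts per person, and population
# parameter values near the published between/within-person estimates.

#' Study design configuration
#'
#' @param n_persons Number of persons (default 293).
#' @param n_days Number of sampling days (default 35).
#' @param prompts_per_day Prompts per day (default 3), randomly timed.
#' @param window Sampling window in minutes since midnight (default
#'   `c(480, 1200)`, i.e. 08:00-20:00).
#' @param compliance Per-prompt response probability (default 0.47, tuned so
#'   the expected number of answered prompts is about 49 of 105).
#' @return An object of class `design_config`.
#' @export
design_config <- function(n_persons = 293L, n_days = 35L, prompts_per_day = 3L,
                          window = c(480, 1200), compliance = 0.47) {
  stopifnot(n_persons >= 1L, n_days >= 1L, prompts_per_day >= 1L,
            compliance > 0, compliance <= 1,
            length(window) == 2L, window[1L] < window[2L],
            window[1L] >= 0, window[2L] <= 1440)
  structure(list(n_persons = as.integer(n_persons), n_days = as.integer(n_days),
                 prompts_per_day = as.integer(prompts_per_day),
                 window = as.numeric(window), compliance = compliance),
            class = "design_config")
}

#' Ground-truth population parameters
#'
#' Returns a [model_params()]-based truth object whose defaults sit at the
#' published point estimates: fixed means of the dynamic parameters
#' (autoregressions 0.338 and 0.205, cross-lags -0.004 and -0.099, latent
#' means 2.022 and 5.799, log residual variances log(0.179) and log(0.401)),
#' the baseline-to-dynamics coefficients (e.g. 0.507 on the burnout mean,
#' 0.675 on the burnout log variance, -0.291 on the expression log
#' variance), and the dynamics-to-follow-up paths (0.571 and 0.233 on the
#' latent means). Unreported coefficients default to zero. The population
#' side adds covariate distributions (gender Bernoulli 0.64, single
#' parenthood 0.08, special needs 0.21, ordinal income), correlated
#' truncated-normal baselines, the random-effect residual covariance, and
#' distal residual standard deviations.
#'
#' @param gamma Optional named list overriding individual coefficient vectors.
#' @param Sigma Optional 8 x 8 random-effect residual covariance.
#' @param sig2_distal Optional distal residual variances.
#' @param pop Optional overrides for the population generators (see the
#'   element list in the returned object).
#' @param resid_cor Within-level residual correlation of the two processes
#'   used by the generator (default 0).
#' @param spec The [model_spec()] the truth is expressed in.
#' @return Object of class `true_params`: list with `params`
#'   ([model_params()]), `pop`, `resid_cor`, `spec`.
#' @export
true_params <- function(gamma = list(), Sigma = NULL, sig2_distal = NULL,
                        pop = list(), resid_cor = 0, spec = model_spec()) {
  g <- default_truth_gamma(spec)
  for (nm in names(gamma)) {
    if (!nm %in% names(g)) stop("unknown equation in gamma override: ", nm)
    stopifnot(length(gamma[[nm]]) == length(g[[nm]]))
    g[[nm]] <- stats::setNames(as.numeric(gamma[[nm]]), names(g[[nm]]))
  }
  if (is.null(Sigma)) Sigma <- default_truth_sigma()
  if (is.null(sig2_distal)) sig2_distal <- c(follow_pb = 0.36, follow_ge = 0.49)
  params <- model_params(g, Sigma, sig2_distal)
  pop_defaults <- list(
    p_female = 0.64, p_single = 0.08, p_needs = 0.21,
    income_mean = 6, income_sd = 2.5,
    base_mean = c(pb = 2.70, ge = 5.76), base_sd = c(pb = 1.28, ge = 1.12),
    base_cor = -0.39, base_range = c(1, 7)
  )
  pop_defaults[names(pop)] <- pop
  structure(list(params = params, pop = pop_defaults, resid_cor = resid_cor,
                 spec = spec),
            class = "true_params")
}

# Published point estimates; coefficients the results do not report are 0.
# Distal intercepts are set so population follow-up means sit near the
# observed follow-up means (2.55 and 5.64).
default_truth_gamma <- function(spec) {
  g <- list()
  ints <- c(mu_pb = 2.022, mu_ge = 5.799, phi1 = 0.338, phi2 = 0.205,
            phi3 = -0.004, phi4 = -0.099,
            psi_pb = log(0.179), psi_ge = log(0.401))
  own_slope <- c(mu_pb = 0.507, mu_ge = 0.363, phi1 = 0.049, phi2 = -0.024,
                 psi_pb = 0.675, psi_ge = -0.291)
  for (eq in ETA_NAMES) {
    preds <- spec$eta_predictors[[eq]]
    v <- stats::setNames(rep(0, length(preds) + 1L), c("(Intercept)", preds))
    v["(Intercept)"] <- ints[[eq]]
    own <- if (grepl("pb$|1$|3$", eq)) "base_pb_c" else "base_ge_c"
    if (eq %in% names(own_slope) && own %in% preds) v[own] <- own_slope[[eq]]
    g[[eq]] <- v
  }
  for (d in c("follow_pb", "follow_ge")) {
    nm <- c("(Intercept)", spec$distal_eta[[d]], spec$distal_fixed)
    v <- stats::setNames(rep(0, length(nm)), nm)
    if (d == "follow_pb") {
      v[intersect(c("mu_pb", "psi_pb", "phi1"), nm)] <- c(0.571, 0.011, 0.133)
      if ("base_pb_c" %in% nm) v["base_pb_c"] <- 0.371
      if ("base_ge_c" %in% nm) v["base_ge_c"] <- -0.039
      if ("gender_female" %in% nm) v["gender_female"] <- 0.152
      v["(Intercept)"] <- 1.272
    } else {
      v[intersect(c("mu_ge", "psi_ge", "phi2"), nm)] <- c(0.233, -0.034, -0.166)
      if ("base_pb_c" %in% nm) v["base_pb_c"] <- -0.066
      if ("base_ge_c" %in% nm) v["base_ge_c"] <- 0.515
      v["(Intercept)"] <- 4.292
    }
    g[[d]] <- v
  }
  g
}

# Random-effect residual covariance: standard deviations chosen so total
# between-person spread matches the published descriptive table after the
# baseline regressions are accounted for, with the published mean-variability
# correlations (0.369 for burnout, -0.677 for expression) inside the blocks.
default_truth_sigma <- function() {
  sd <- c(mu_pb = 0.70, mu_ge = 0.80, phi1 = 0.12, phi2 = 0.12,
          phi3 = 0.05, phi4 = 0.08, psi_pb = 0.60, psi_ge = 0.50)
  R <- diag(8L)
  dimnames(R) <- list(ETA_NAMES, ETA_NAMES)
  set_cor <- function(R, a, b, r) { R[a, b] <- r; R[b, a] <- r; R }
  R <- set_cor(R, "mu_pb", "phi1", 0.20)
  R <- set_cor(R, "mu_pb", "psi_pb", 0.369)
  R <- set_cor(R, "phi1", "psi_pb", 0.10)
  R <- set_cor(R, "mu_ge", "phi2", -0.10)
  R <- set_cor(R, "mu_ge", "psi_ge", -0.677)
  R <- set_cor(R, "phi2", "psi_ge", 0.10)
  diag(sd) %*% R %*% diag(sd)
}

#' Simulate a prompt schedule with compliance
#'
#' Per person-day, draws `prompts_per_day` times uniformly in the sampling
#' window and sorts them; each prompt is answered independently with
#' probability `compliance`.
#'
#' @param design A [design_config()].
#' @param seed Integer seed.
#' @return Data frame with columns `person`, `day`, `prompt`, `time_min`,
#'   `answered` (logical), ordered by person, day, time.
#' @export
simulate_schedule <- function(design = design_config(), seed = 1L) {
  set.seed(sub_seed(seed, 1L))
  n <- design$n_persons; D <- design$n_days; P <- design$prompts_per_day
  total <- n * D * P
  times <- stats::runif(total, design$window[1L], design$window[2L])
  sched <- data.frame(
    person = rep(seq_len(n), each = D * P),
    day = rep(rep(seq_len(D), each = P), times = n),
    time_min = times
  )
  ord <- order(sched$person, sched$day, sched$time_min)
  sched <- sched[ord, , drop = FALSE]
  sched$prompt <- rep(seq_len(P), times = n * D)
  sched$answered <- stats::runif(total) < design$compliance
  rownames(sched) <- NULL
  sched[c("person", "day", "prompt", "time_min", "answered")]
}

#' Simulate persons: covariates, baselines and true random effects
#'
#' Draws the four covariates and the two (correlated, truncated to the score
#' range) baseline traits, then the person random effects
#' `eta_i = Gamma' x_i + u_i` with `u_i ~ N(0, Sigma_eta)`. Draws of `u_i`
#' are rejected and redrawn until the person's 2 x 2 lag matrix has spectral
#' radius below `max_radius` (stationarity guard).
#'
#' @param truth A [true_params()].
#' @param design A [design_config()].
#' @param seed Integer seed.
#' @param max_radius Stationarity bound for accepted persons (default 0.98).
#' @param max_reject Error after this many consecutive rejections.
#' @return List with `persons` (a `person_table` with `NA` follow-ups),
#'   `eta` (n x 8 matrix of true random effects), and `predictors` (the
#'   centered design table used by the generator).
#' @export
simulate_persons <- function(truth = true_params(), design = design_config(),
                             seed = 1L, max_radius = 0.98, max_reject = 10000L) {
  set.seed(sub_seed(seed, 2L))
  n <- design$n_persons
  pop <- truth$pop
  gender <- stats::rbinom(n, 1L, pop$p_female)
  single <- stats::rbinom(n, 1L, pop$p_single)
  needs <- stats::rbinom(n, 1L, pop$p_needs)
  income <- pmin(pmax(round(stats::rnorm(n, pop$income_mean, pop$income_sd)), 1), 13)
  # Correlated baselines, truncated to the instrument range by rejection.
  Sb <- matrix(c(pop$base_sd["pb"]^2,
                 pop$base_cor * pop$base_sd["pb"] * pop$base_sd["ge"],
                 pop$base_cor * pop$base_sd["pb"] * pop$base_sd["ge"],
                 pop$base_sd["ge"]^2), 2L, 2L)
  base <- matrix(NA_real_, n, 2L)
  todo <- seq_len(n)
  tries <- 0L
  while (length(todo) > 0L) {
    cand <- rmvnorm_chol(length(todo), c(pop$base_mean["pb"], pop$base_mean["ge"]), Sb)
    ok <- cand[, 1L] >= pop$base_range[1L] & cand[, 1L] <= pop$base_range[2L] &
      cand[, 2L] >= pop$base_range[1L] & cand[, 2L] <= pop$base_range[2L]
    base[todo[ok], ] <- cand[ok, , drop = FALSE]
    todo <- todo[!ok]
    tries <- tries + 1L
    if (tries > max_reject) stop("baseline truncation rejection limit exceeded")
  }
  persons <- person_table(data.frame(
    person_id = sprintf("p%04d", seq_len(n)),
    base_pb = base[, 1L], base_ge = base[, 2L],
    follow_pb = NA_real_, follow_ge = NA_real_,
    gender_female = gender, single = single, income = income, needs = needs
  ))
  predictors <- data.frame(
    base_pb_c = base[, 1L] - mean(base[, 1L]),
    base_ge_c = base[, 2L] - mean(base[, 2L]),
    income_c = income - mean(income),
    gender_female = gender, single = single, needs = needs
  )
  spec <- truth$spec
  m <- matrix(0, n, 8L, dimnames = list(NULL, ETA_NAMES))
  for (eq in ETA_NAMES) {
    m[, eq] <- drop(eta_design(spec, predictors, eq) %*% truth$params$gamma[[eq]])
  }
  Sigma <- truth$params$Sigma
  eta <- m + rmvnorm_chol(n, rep(0, 8L), Sigma)
  reject_run <- 0L
  repeat {
    bad <- which(spectral_radius2(eta[, 3:6, drop = FALSE]) >= max_radius)
    if (length(bad) == 0L) break
    reject_run <- reject_run + length(bad)
    if (reject_run > max_reject) {
      stop("configuration error: stationarity guard rejected > ", max_reject,
           " draws; Sigma_eta is too wide")
    }
    eta[bad, ] <- m[bad, , drop = FALSE] +
      rmvnorm_chol(length(bad), rep(0, 8L), Sigma)
  }
  colnames(eta) <- ETA_NAMES
  list(persons = persons, eta = eta, predictors = predictors)
}

#' Simulate the momentary panel from true random effects
#'
#' Latent centered states evolve across *all* scheduled prompts (answered or
#' not) as `w_t = Phi_i w_{t-1} + e_t` with diagonal innovation variances
#' `exp(psi_i)`; the initial state is drawn from the person's stationary
#' distribution. Observed scores `mu_i + w_t` are emitted at answered
#' prompts only and are left continuous (no clipping) by default.
#'
#' @param eta n x 8 matrix of true person random effects.
#' @param schedule Schedule from [simulate_schedule()].
#' @param design A [design_config()].
#' @param seed Integer seed.
#' @param resid_cor Innovation correlation between the two processes.
#' @param clip Clip observed scores to `[1, 7]` (off by default: clipping
#'   breaks the linear-Gaussian assumptions of the analysis model).
#' @return An [esm_panel()] of answered prompts.
#' @export
simulate_panel <- function(eta, schedule, design = design_config(), seed = 1L,
                           resid_cor = 0, clip = FALSE) {
  set.seed(sub_seed(seed, 3L))
  n <- nrow(eta)
  stopifnot(max(schedule$person) <= n)
  total <- nrow(schedule)
  z <- matrix(stats::rnorm(2L * total), total, 2L)
  if (resid_cor != 0) {
    z <- z %*% chol(matrix(c(1, resid_cor, resid_cor, 1), 2L, 2L))
  }
  w <- matrix(NA_real_, total, 2L)
  # schedule is ordered by person; iterate persons, vector ops within person.
  idx_by_person <- split(seq_len(total), schedule$person)
  for (i in seq_len(n)) {
    rows <- idx_by_person[[as.character(i)]]
    if (is.null(rows)) next
    Phi <- matrix(c(eta[i, 3L], eta[i, 6L], eta[i, 5L], eta[i, 4L]), 2L, 2L)
    sdv <- sqrt(exp(eta[i, 7:8]))
    Q <- diag(sdv) %*% matrix(c(1, resid_cor, resid_cor, 1), 2L, 2L) %*% diag(sdv)
    V <- stationary_var(Phi, Q)
    wi <- matrix(0, length(rows), 2L)
    wi[1L, ] <- drop(rmvnorm_chol(1L, c(0, 0), V))
    eps <- z[rows, , drop = FALSE] %*% diag(sdv)
    for (t in seq_along(rows)[-1L]) {
      wi[t, ] <- Phi %*% wi[t - 1L, ] + eps[t, ]
    }
    w[rows, ] <- wi
  }
  y <- w + eta[schedule$person, 1:2, drop = FALSE]
  if (clip) y <- pmin(pmax(y, 1), 7)
  ans <- schedule$answered
  records <- data.frame(
    person_id = sprintf("p%04d", schedule$person[ans]),
    day = schedule$day[ans], prompt = schedule$prompt[ans],
    time_min = schedule$time_min[ans],
    pb = y[ans, 1L], ge = y[ans, 2L]
  )
  esm_panel(records,
            design = list(n_days = design$n_days,
                          prompts_per_day = design$prompts_per_day,
                          window_start_min = design$window[1L],
                          window_end_min = design$window[2L]),
            range = if (clip) c(1, 7) else NULL)
}

# Stationary covariance of a bivariate VAR(1): vec(V) = (I - Phi (x) Phi)^-1 vec(Q).
stationary_var <- function(Phi, Q) {
  V <- solve(diag(4L) - kronecker(Phi, Phi), as.vector(Q))
  symm(matrix(V, 2L, 2L))
}

#' Simulate distal follow-up outcomes
#'
#' Completes a person table with follow-up scores drawn from the distal
#' equations: linear in the person's own-construct dynamic parameters,
#' centered baselines and covariates, plus normal residual. Follow-ups are
#' left continuous (unclipped) to preserve the linear-Gaussian model.
#'
#' @param truth A [true_params()].
#' @param persons `person_table` from [simulate_persons()].
#' @param eta n x 8 matrix of true random effects.
#' @param predictors Centered predictor table from [simulate_persons()].
#' @param seed Integer seed.
#' @return The completed `person_table`.
#' @export
simulate_followups <- function(truth, persons, eta, predictors, seed = 1L) {
  set.seed(sub_seed(seed, 4L))
  spec <- truth$spec
  out <- as.data.frame(persons)
  for (d in c("follow_pb", "follow_ge")) {
    D <- distal_design(spec, predictors, eta, d)
    mu <- drop(D %*% truth$params$gamma[[d]])
    out[[d]] <- mu + stats::rnorm(nrow(out), 0, sqrt(truth$params$sig2_distal[[d]]))
  }
  person_table(out, range = NULL)
}

#' Simulate a complete synthetic ESM study
#'
#' Composes [simulate_schedule()], [simulate_persons()], [simulate_panel()]
#' and [simulate_followups()] under documented sub-seeding from one master
#' seed, and returns the panel, the completed person table, and a
#' ground-truth manifest sufficient to reproduce the study exactly.
#'
#' @param truth A [true_params()].
#' @param design A [design_config()].
#' @param seed Master integer seed; all stages derive sub-seeds from it.
#' @param clip Clip momentary scores to the instrument range (default off).
#' @return Object of class `synthetic_study`: list with `panel`, `persons`,
#'   `truth` (list: `params` ([true_params()]), `eta`, `predictors`,
#'   `design`, `seed`).
#' @export
simulate_study <- function(truth = true_params(), design = design_config(),
                           seed = 1L, clip = FALSE) {
  sched <- simulate_schedule(design, seed)
  pers <- simulate_persons(truth, design, seed)
  panel <- simulate_panel(pers$eta, sched, design, seed,
                          resid_cor = truth$resid_cor, clip = clip)
  persons <- simulate_followups(truth, pers$persons, pers$eta,
                                pers$predictors, seed)
  structure(list(panel = panel, persons = persons,
                 truth = list(params = truth, eta = pers$eta,
                              predictors = pers$predictors,
                              design = design, seed = seed, clip = clip)),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("<synthetic_study>\n")
  cat("  persons:", nrow(x$persons), "\n")
  cat("  records:", nrow(x$panel), "\n")
  cat("  mean obs/person:", round(nrow(x$panel) / nrow(x$persons), 2), "\n")
  cat("  seed:", x$truth$seed, "\n")
  invisible(x)
}

#' Export a synthetic study to CSV + JSON manifest
#'
#' Writes the ESM panel and person table in the dialects [read_esm_panel()]
#' and [read_person_table()] consume, plus a truth manifest (JSON) holding
#' the population parameters, per-person random effects and seed.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(panel = file.path(dir, "esm_panel.csv"),
             persons = file.path(dir, "persons.csv"),
             truth = file.path(dir, "truth_manifest.json"))
  write_esm_panel(study$panel, paths["panel"])
  write_person_table(study$persons, paths["persons"])
  tr <- study$truth
  manifest <- list(
    seed = tr$seed, clip = tr$clip,
    design = unclass(tr$design),
    gamma = tr$params$params$gamma,
    Sigma = tr$params$params$Sigma,
    sig2_distal = as.list(tr$params$params$sig2_distal),
    pop = tr$params$pop,
    eta = as.data.frame(tr$eta)
  )
  jsonlite::write_json(manifest, paths["truth"], digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(paths)
}
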