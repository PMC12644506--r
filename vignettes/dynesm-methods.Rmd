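---
title: "Two-level dynamic structural equation models for experience-sampling data: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dynesm methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model `dynesm` implements, the
estimation algorithm, the synthetic-data generator and what it does and does
not emulate, the numerical choices, and the places where the design was
genuinely open and a decision had to be made. It states no empirical result
that the package's test suite or acceptance script does not itself compute.

## 1. The model

### Within level

Each person $i$ contributes a short bivariate time series of momentary
scores — here labelled PB (parental burnout) and GE (genuine expression),
both on 1–7 response scales. Scores decompose into a person-specific latent
mean and a centered deviation, $y_{it} = \mu_i + w_{it}$, and deviations
follow a lag-1 vector autoregression over *observation occasions*:

$$
w_{it} = \Phi_i\, w_{i,t-1} + \varepsilon_{it},\qquad
\Phi_i = \begin{pmatrix} \varphi_{1i} & \varphi_{3i}\\
                          \varphi_{4i} & \varphi_{2i} \end{pmatrix},\qquad
\varepsilon_{it} \sim N\!\left(0,\ \mathrm{diag}(e^{\psi_{PB,i}},
e^{\psi_{GE,i}})\right).
$$

$\varphi_{1i},\varphi_{2i}$ are the autoregressions (inertia),
$\varphi_{3i}$ the lagged GE$\to$PB and $\varphi_{4i}$ the lagged PB$\to$GE
cross-effects, and $\psi_i$ the person's log residual variances
(variability). Modelling the residual variance on the log scale keeps the
person-level variance positive and makes between-person coefficients on
$\psi$ *multiplicative* on the raw variance: a coefficient $b$ multiplies the
variance by $e^b$ per predictor unit (`var_factor()`).

The first observation of each chain segment is **conditioned upon**: it
contributes no likelihood term. The alternative — a stationary initial-state
term — couples $\varphi$ and $\psi$ through the implied marginal variance and
requires stationarity of every posterior draw; conditioning matches common
latent-autoregression practice and lets the posterior put (vanishing) mass
outside the stationary region without pathology. Stationarity is therefore
*monitored* (`check_stationarity()`, spectral radius of $\Phi_i$), never
enforced by truncation, which would distort diffuse-prior posteriors.

### Between level

The eight random effects
$\eta_i = (\mu_{PB}, \mu_{GE}, \varphi_1, \varphi_2, \varphi_3, \varphi_4,
\psi_{PB}, \psi_{GE})_i$ are regressed on person-level predictors:

$$\eta_i = \Gamma' x_i + u_i, \qquad u_i \sim N(0, \Sigma_\eta),$$

and two distal (follow-up) outcomes are regressed on the person's
own-construct dynamic parameters plus baselines and covariates:

$$\mathrm{follow}_i = \delta_0 + \delta' (\mu_i, \psi_i, \varphi_{AR,i},
\text{baselines}_i, \text{covariates}_i) + e_i .$$

The default predictor map regresses each construct's $\mu$, $\varphi_{AR}$
and $\psi$ on the construct's *own* centered baseline plus the four
covariates (gender, single parenthood, centered income, special needs); the
cross-lagged coefficients $\varphi_3,\varphi_4$ on covariates only. This
mirrors the reported between-level structure, which presents own-baseline
paths for means, inertia and variability and no baseline paths for the
cross-lags; whether the original model also regressed cross-lags on
baselines is not stated, so the map is configuration, not hard-coded.
Continuous predictors are grand-mean centered over the persons in the
analysis set (constants recorded for back-transformation); binaries enter
uncentered.

$\Sigma_\eta$ defaults to **within-construct blocks** —
$(\mu, \varphi_{AR}, \psi)$ correlated within PB and within GE, cross-lags
independent — because construct-wise mean–variability correlations are the
quantities of substantive interest (e.g. `random_effect_correlations()`),
while a full 8×8 covariance is available by configuration and a diagonal
structure for degenerate checks. The within-level residual correlation of
the two processes defaults to zero in the generator (`resid_cor` hook) and
is fixed at zero in estimation: with person-varying scales a person-varying
residual covariance is ill-identified.

### What "a×b" means here

Indirect effects are computed per posterior draw: for paths $a$
(baseline $\to$ dynamic parameter) and $b$ (dynamic parameter $\to$
follow-up), `mediation()` forms $a^{(s)} b^{(s)}$ at every stored draw $s$
and summarises those products. This preserves the posterior dependence
between $a$ and $b$; the product of the two marginal medians is *not* the
median of the product, and the package never reports the latter as the
former. The same transform-then-summarise discipline applies to raw-scale
variances: `raw_scale_variance()` exponentiates the $\psi$ linear predictor
draw-wise at a covariate profile (default: centered continuous predictors at
0, binaries at 0) and then takes median and 2.5/97.5 percentiles (linear
interpolation, equal-tailed — the convention behind bracketed credible
intervals in mainstream DSEM software; highest-density intervals are not
used).

## 2. Estimation

`dsem_fit()` runs a blocked Gibbs sampler with one Metropolis ingredient:

1. **Latent means** $(\mu_{PB},\mu_{GE})_i$ — bivariate conjugate normal.
   Conditional on $\Phi_i$ the observation equation is linear in $\mu_i$ with
   design rows $(1-\varphi_1, -\varphi_3)$ and $(-\varphi_4, 1-\varphi_2)$.
2. **Lag coefficients** $(\varphi_1,\varphi_3)_i$ and
   $(\varphi_2,\varphi_4)_i$ — bivariate conjugate normal regressions of the
   target deviations on the source deviations.
3. **Log variances** $\psi_i$ — scalar random-walk Metropolis on the log
   scale. The Gaussian part of the conditional (between-level conditional
   prior plus the distal equations' contribution, which are linear in
   $\psi$) is folded into the target exactly; only the within-level term
   $-\tfrac12(n_i\psi + \mathrm{SSR}_i e^{-\psi})$ is non-conjugate.
4. **Missing momentary values** — Gaussian full conditionals combining the
   record's role as lag-pair target and as lag-pair source in both
   equations.
5. **Fixed effects** $\Gamma$ — per covariance block, a seemingly-unrelated
   -regressions conjugate normal draw (equations in a block share the
   person-level error covariance).
6. **$\Sigma_\eta$** — inverse-Wishart per block (inverse-gamma for scalar
   blocks / diagonal structure).
7. **Distal equations** — conjugate normal coefficients and inverse-gamma
   residual variances. Because the distal design contains current draws of
   $\eta$, the $\eta$ updates in (1)–(3) include the distal likelihood
   terms, making the mediation structure a genuine joint model.

All person-level updates are vectorised across persons (sufficient
statistics by `rowsum` over the stacked lag pairs; closed-form 2×2 Cholesky
algebra), which keeps a full sweep at a few milliseconds for hundreds of
persons — the practical reason the package can run interval-coverage studies
inside its test suite.

**Every eta sub-block conditions on the others through the full
$\Sigma_\eta$** (generic Schur complement), so the block updates remain
valid Gibbs steps under any covariance structure.

### Tunables that matter

| parameter | default | meaning |
|---|---|---|
| `n_chains` | 2 | chains; 2+ needed for PSR |
| `n_iters` | 10,000 | post-burn-in iterations/chain |
| `n_burnin` | 2,000 | discarded; MH adaptation happens here |
| `thin` | 50 | retained every `thin`-th iteration |
| `target_accept` | 0.44 | scalar-MH optimum |
| `init_step` | 0.5 | initial RW sd on the log-variance scale |
| `lag_policy` | consecutive | see below |

The reported protocol this mirrors is "2 chains × 10,000 iterations, thin
50"; it does not state a burn-in, so 2,000 discarded iterations per chain is
this package's default (an explicit choice, recorded in every run manifest).
Thinning at 50 is retained for protocol fidelity even though it discards
information an unthinned estimator would keep. Step-size adaptation is
Robbins–Monro with decaying gain $\min(0.2, t^{-0.6})$ on the smooth
acceptance probability, frozen after burn-in to preserve detailed balance.
Priors default to the "software default diffuse" family: $N(0, 10^6)$ on
every coefficient, inverse-Wishart$(\mathrm{dim}+2,\ 0.01 I)$ per covariance
block (the scale is not pinned by any reported value; $0.01 I$ adds roughly
one pseudo-observation at the scale of the random effects), inverse-gamma
$(0.001, 0.001)$ for scalar variances.

### Initialization

Chains start from per-person least squares: observed person means for
$\mu_i$; per-person OLS of target on source deviations for $\Phi_i$ when at
least 3 complete lag pairs exist (zero otherwise); log residual variance
floored at $10^{-4}$ (so a constant series starts at $\psi = \log 10^{-4}$);
between-level coefficients by OLS on these person estimates. Each chain
jitters the start (documented scales), giving over-dispersed but sane
initial states.

### Lag policy: the single most consequential unstated choice

ESM prompts are unequally spaced and nights intervene. Nothing in the
two-level lag-1 formulation says what "$t-1$" means for an 11-hour overnight
gap. `dynesm` makes the choice explicit configuration:

* `consecutive` (default): adjacent *observed* records within a person form
  a lag pair regardless of clock gaps — the common DSEM practice when no
  interval grid is imposed;
* `same_day_only`: pairs must share a calendar day (the conservative
  alternative; overnight pairs are dropped and each day's first record is
  conditioned upon).

No interval-grid re-discretisation (insertion of phantom missing occasions
on a fixed time grid) is implemented in this version. Consequence, fully
deliberate: when compliance is partial, "consecutive" observed pairs span
multi-step gaps of the underlying process, so lag-1 coefficients estimated
from partial-compliance data are attenuated relative to the one-step truth
(a geometric mixture of powers of $\Phi$). The package's recovery and
coverage tests therefore run at full compliance, where observed adjacency
equals process adjacency; the partial-compliance default exists to exercise
exactly this mismatch, not to hide it.

## 3. The synthetic-data generator

`simulate_study()` composes four stages under one master seed with
documented per-stage sub-seeding: prompt schedules (per person-day,
`prompts_per_day` draws uniform in the 08:00–20:00 window, sorted; each
answered independently with probability `compliance = 0.47`, tuned so the
expected number of answered prompts is ≈ 49 of 105); persons (covariates:
gender Bernoulli(0.64), single parenthood 0.08, special needs 0.21, income
rounded $N(6, 2.5^2)$ clamped to 1..13; baselines bivariate normal with
means 2.70/5.76, SDs 1.28/1.12, correlation −0.39, truncated to the 1–7
instrument range by rejection; random effects $\eta_i$ from the between
model with a spectral-radius < 0.98 stationarity guard via rejection — 0.98,
not 1.0, to avoid near-unit-root numerics); the momentary panel (latent
states advance through *all* scheduled prompts, answered or not, from a
stationary initial state so short series are unbiased; observations emitted
at answered prompts only); and follow-ups from the distal equations.

Fixed-effect means and the reported between-level coefficients sit at the
published point estimates (autoregressions 0.338/0.205, cross-lags
−0.004/−0.099, latent means 2.022/5.799, log variances log 0.179 /
log 0.401, baseline paths 0.507, 0.675, 0.049, 0.363, −0.291, −0.024,
distal paths 0.571, 0.011, 0.133, 0.233, −0.034, −0.166, controls 0.371,
−0.039, 0.152, 0.515, −0.066); coefficients the source does not report
default to zero. Quantities no report pins down were chosen once, from the
descriptive tables and interval widths, and not revisited: random-effect SDs
(0.70/0.80 for means, 0.12 for autoregressions, 0.05/0.08 for cross-lags,
0.60/0.50 for log variances), within-block correlations (the published
0.369 and −0.677 mean–variability correlations, plus small 0.1–0.2
nuisance correlations), distal residual SDs 0.6/0.7, and distal intercepts
1.272/4.292 (set so the population follow-up means match the observed
2.55/5.64).

**What the generator does not emulate** — and hence what a green test does
not establish: ordinal 7-point measurement (scores are continuous Gaussian;
an optional `clip` flag exists for realism experiments and is off in every
acceptance test, because clipping breaks the linear-Gaussian model);
time-of-day or weekday structure; reactive compliance (missingness is
independent of the state); item-level psychometrics. Recovery tests on this
generator validate the *estimator under its own assumptions*, not robustness
to ordinal measurement or informative missingness.

A boundary consequence worth noting: baselines are truncated to the 1–7
range (they are exogenous predictors; truncation costs nothing), but
follow-ups and momentary scores are left continuous and may exceed the
instrument range — a clipped *outcome* would bias every linear-recovery
check. File-reading validation is therefore strict for baselines and
optional (`range = NULL`, `strict`) for scores and follow-ups.

## 4. Numerical choices and degenerate inputs

* Percentiles: type-7 linear interpolation, equal-tailed 2.5/50/97.5.
* 2×2 conditional draws: closed-form precision Cholesky with a
  machine-epsilon floor on the trailing pivot.
* Metropolis overflow: a proposal whose target evaluates non-finite
  (e.g. $e^{-\psi}$ overflow) is rejected and the rejection is counted.
* Missing momentary values on records that are never a lag-pair target (the
  conditioned-upon first record of a segment) have no model-implied full
  conditional; they are imputed from $N(\mu_i, e^{\psi_i})$ — a stationary
  -like pragmatic prior that only affects records carrying no likelihood
  information.
* Persons with no lag pairs (single observation) contribute only
  between-level information; their $\eta$ updates reduce to prior + distal
  terms. Constant series floor the initial residual variance at $10^{-4}$.
* PSR: split-chain Gelman–Rubin over every stored global parameter; a
  parameter with zero within- and between-variance reports 1, zero within-
  but positive between-variance reports Inf; fewer than 4 draws per split
  is an error, not a silent NA.
* Seeds: one master seed; stage/chain streams derived as
  $(48271\,s + 16807\,k) \bmod (2^{31}-1)$, so chain $c$'s stream does not
  depend on how many chains run.

## 5. Validation strategy

Three layers, in increasing strength:

1. **Exact oracles** — the within/between density kernels are checked to
   $10^{-8}$ against an independently constructed joint-normal evaluation
   (covariance built by VAR recursion, evaluated with `mvtnorm`), on up to 3
   persons × 4 occasions; closed-form cases (standard-normal pairs,
   translation equivariance, the Gaussian MLE of $\psi$) are asserted
   directly.
2. **Joint-distribution (Geweke-style successive-conditional) check** — on
   an 8-person × 6-occasion configuration with finite-moment test priors,
   alternating full posterior sweeps with data redraws from the model must
   leave the prior invariant; 34 marginal moments are compared with analytic
   prior moments via batch-means z-scores. This is the strongest available
   correctness check for the full set of conditional distributions,
   including the Metropolis step and the distal coupling.
3. **Frequentist operating characteristics** — parameter recovery at the
   stated truth (N = 150 persons, 39 complete occasions: every fixed-effect
   mean recovered within 0.05–0.10, PSR < 1.10) and 95%-interval coverage
   over 20 replicates (N = 100, T = 30; per-parameter coverage ≥ 80%).

## 6. Known limitations

* Lag-1 only, two constructs only, no time-varying coefficients, no interval
  -grid discretisation — scope choices, not oversights.
* Distal-equation coefficients (and hence mediation paths) are weakly
  identified in small samples and mix more slowly than the within-person
  parameters; at partial compliance with a few dozen persons, expect to need
  longer chains for PSR < 1.10 on those blocks.
* The descriptive module's between-level correlations use observed person
  means, which are noisy proxies for latent means; they differ modestly from
  a latent decomposition by design.
* Estimation assumes a zero within-level residual correlation; the generator
  can produce correlated innovations (`resid_cor`) for sensitivity
  experiments, but the estimator will attribute such correlation to the
  cross-lags.
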