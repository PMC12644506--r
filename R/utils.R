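# Internal numerical utilities shared across modules.

# Component order of the person-specific random-effect vector eta.
ETA_NAMES <- c("mu_pb", "mu_ge", "phi1", "phi2", "phi3", "phi4",
               "psi_pb", "psi_ge")

# Between-person predictor columns available to the model (centered
# continuous variables carry the "_c" suffix; binaries are raw 0/1).
BETWEEN_PREDICTORS <- c("base_pb_c", "base_ge_c", "gender_female", "single",
                        "income_c", "needs")

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a reproducible 31-bit sub-seed from a master seed and a stage index.
# Doubles hold the intermediate product exactly (< 2^53), so the result is
# platform-stable.
sub_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(seed) * 48271 + stage * 16807) %% 2147483647) + 1L
}

# Draw n samples from N(mean, sigma) via Cholesky. `mean` may be a single
# vector or an n x d matrix of per-row means.
rmvnorm_chol <- function(n, mean, sigma) {
  d <- ncol(sigma)
  L <- chol(sigma)  # upper triangular, sigma = t(L) %*% L
  z <- matrix(stats::rnorm(n * d), n, d) %*% L
  if (is.matrix(mean)) z + mean else sweep(z, 2, mean, "+")
}

# Inverse-Wishart draw: if W ~ Wishart(df, solve(S)) then solve(W) ~ IW(df, S).
rinvwishart <- function(df, S) {
  W <- stats::rWishart(1L, df, solve(S))[, , 1L]
  out <- solve(W)
  (out + t(out)) / 2
}

# Symmetrize a nearly-symmetric matrix (guards against drift in chol()).
symm <- function(M) (M + t(M)) / 2

# log N(x; mean, var) without constructing distribution objects in hot loops.
lognorm <- function(x, mean, var) {
  -0.5 * (log(2 * pi) + log(var) + (x - mean)^2 / var)
}

# Conditional distribution of components S of a joint normal N(m, Sigma)
# given the remaining components fixed at their current values.
# `m` and `current` are n x d matrices (per-person means / states).
# Returns list(mean = n x |S| matrix, var = |S| x |S| matrix).
cond_normal <- function(m, Sigma, S, current) {
  d <- ncol(Sigma)
  R <- setdiff(seq_len(d), S)
  if (length(R) == 0L) {
    return(list(mean = m[, S, drop = FALSE], var = symm(Sigma[S, S, drop = FALSE])))
  }
  A <- Sigma[S, R, drop = FALSE] %*% solve(Sigma[R, R, drop = FALSE])
  cvar <- Sigma[S, S, drop = FALSE] - A %*% Sigma[R, S, drop = FALSE]
  cmean <- m[, S, drop = FALSE] +
    (current[, R, drop = FALSE] - m[, R, drop = FALSE]) %*% t(A)
  list(mean = cmean, var = symm(cvar))
}

# Sum pair-level vectors/matrices into per-person totals. `x` is a vector or
# matrix with one row per lag pair, `pid` the integer person index of each
# pair, `n` the number of persons. Persons without pairs get zero rows.
person_sum <- function(x, pid, n) {
  x <- as.matrix(x)
  out <- matrix(0, n, ncol(x))
  if (nrow(x) > 0L) {
    s <- rowsum(x, group = pid, reorder = TRUE)
    out[as.integer(rownames(s)), ] <- s
  }
  out
}

# Vectorised draw from n bivariate normals parameterised by precision
# elements (P11, P12, P22 vectors) and linear terms (L1, L2): the target is
# N(P^{-1} L, P^{-1}).
draw_bivariate_gaussian <- function(P11, P12, P22, L1, L2) {
  det <- P11 * P22 - P12^2
  m1 <- (P22 * L1 - P12 * L2) / det
  m2 <- (P11 * L2 - P12 * L1) / det
  # Upper Cholesky of the precision: P = U'U.
  u11 <- sqrt(P11)
  u12 <- P12 / u11
  u22 <- sqrt(pmax(P22 - u12^2, .Machine$double.eps))
  n <- length(P11)
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  # x = mean + U^{-1} z
  x2 <- z2 / u22
  x1 <- (z1 - u12 * x2) / u11
  cbind(m1 + x1, m2 + x2)
}
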