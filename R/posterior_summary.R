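# Posterior summaries: medians and equal-tailed 95% credible intervals,
# raw-scale variance transforms of the log-scale coefficients, draw-wise
# indirect (a x b) effects, and random-effect correlation summaries.
#
# Discipline throughout: transform each draw first, then summarise. Reported
# raw-scale variances are medians of exp(linear predictor), not exp of
# medians (the two coincide for the median because exp is monotone, but
# interval endpoints differ).

# Pool retained draws of the named global parameters across chains.
pooled_draws <- function(draws, pars = NULL) {
  stopifnot(inherits(draws, "dsem_draws"))
  g <- do.call(rbind, lapply(draws$chains, function(ch) ch$global))
  if (is.null(pars)) return(g)
  bad <- setdiff(pars, colnames(g))
  if (length(bad) > 0L) {
    stop("selector error: unknown parameter(s): ", paste(bad, collapse = ", "))
  }
  g[, pars, drop = FALSE]
}

summarise_vector <- function(x, name) {
  q <- stats::quantile(x, c(0.025, 0.5, 0.975), names = FALSE, type = 7L)
  data.frame(parameter = name, median = q[2L], ci_low = q[1L], ci_high = q[3L],
             non_null = q[1L] > 0 | q[3L] < 0, row.names = NULL)
}

#' Summarize posterior draws
#'
#' Pools draws across chains and reports, per parameter, the posterior median,
#' the equal-tailed 95% credible interval (2.5 and 97.5 percentiles, linear
#' interpolation), and a non-null flag (interval excludes zero).
#'
#' @param draws A [dsem_fit()] result.
#' @param pars Character vector of parameter names (default: all global
#'   parameters). Unknown names raise a selector error.
#' @return Data frame with columns `parameter`, `median`, `ci_low`,
#'   `ci_high`, `non_null`.
#' @export
summarize_posterior <- function(draws, pars = NULL) {
  g <- pooled_draws(draws, pars)
  if (nrow(g) < 2L) stop("need at least 2 retained draws")
  out <- do.call(rbind, lapply(colnames(g), function(p) summarise_vector(g[, p], p)))
  rownames(out) <- NULL
  out
}

#' Raw-scale variance factor of a log-scale coefficient
#'
#' A between-person coefficient `b` on a log residual variance multiplies the
#' raw-scale variance by `exp(b)` per unit of the predictor.
#'
#' @param coef Log-scale coefficient(s).
#' @return `exp(coef)`.
#' @export
var_factor <- function(coef) {
  stopifnot(all(is.finite(coef)))
  exp(coef)
}

#' Raw-scale residual variance at a covariate profile
#'
#' Per draw, evaluates the linear predictor of a construct's log residual
#' variance at the given covariate profile and exponentiates; the resulting
#' draws of the raw-scale variance are then summarised (median and 95%
#' equal-tailed interval). The default profile sets every centered continuous
#' predictor to 0 and every binary predictor to 0, i.e. the "average person"
#' convention under which the model's average residual variances are
#' reported.
#'
#' @param draws A [dsem_fit()] result, or a numeric matrix of psi-equation
#'   coefficient draws whose columns are named by predictor (intercept column
#'   `"(Intercept)"`).
#' @param construct `"pb"` or `"ge"` (ignored when `draws` is a matrix).
#' @param profile Named numeric vector assigning a value to every non-intercept
#'   predictor of the psi equation. Defaults to all zeros. An incomplete
#'   profile is an error.
#' @return One-row summary data frame (as [summarize_posterior()]), with the
#'   per-draw variances in attribute `"draws"`.
#' @export
raw_scale_variance <- function(draws, construct = c("pb", "ge"), profile = NULL) {
  if (inherits(draws, "dsem_draws")) {
    construct <- match.arg(construct)
    eq <- paste0("psi_", construct)
    cols <- draws$meta$eq_columns[[eq]]
    g <- pooled_draws(draws, paste("gamma", eq, cols, sep = "."))
    colnames(g) <- cols
  } else {
    g <- as.matrix(draws)
    eq <- "psi"
    cols <- colnames(g)
    if (is.null(cols) || !"(Intercept)" %in% cols) {
      stop("coefficient matrix must have named columns including \"(Intercept)\"")
    }
  }
  preds <- setdiff(cols, "(Intercept)")
  if (is.null(profile)) profile <- stats::setNames(rep(0, length(preds)), preds)
  missing_preds <- setdiff(preds, names(profile))
  if (length(missing_preds) > 0L) {
    stop("profile error: no value for predictor(s): ",
         paste(missing_preds, collapse = ", "))
  }
  x <- c(1, profile[preds])
  v <- var_factor(drop(g[, c("(Intercept)", preds), drop = FALSE] %*% x))
  out <- summarise_vector(v, paste0("raw_variance.", eq))
  attr(out, "draws") <- v
  out
}

#' Indirect effect from draw-wise products
#'
#' Computes the a x b indirect effect as the per-draw product of the
#' baseline-to-mediator path (a) and the mediator-to-outcome path (b),
#' preserving their posterior dependence, and summarises the product draws.
#' The product summary is never formed from the two path summaries.
#'
#' @param draws A [dsem_fit()] result, or a list/data frame with numeric
#'   vectors `a` and `b` of equal length (raw path draws).
#' @param a,b Parameter names of the two paths (when `draws` is a
#'   `dsem_draws`), e.g. `a = "gamma.mu_pb.base_pb_c"`,
#'   `b = "gamma.follow_pb.mu_pb"`.
#' @return Object of class `mediation_summary`: list with `product` (one-row
#'   summary of the a x b draws), `paths` (summaries of a and b), names, and
#'   the product draws.
#' @export
mediation <- function(draws, a = "gamma.mu_pb.base_pb_c",
                      b = "gamma.follow_pb.mu_pb") {
  if (inherits(draws, "dsem_draws")) {
    g <- pooled_draws(draws, c(a, b))
    av <- g[, 1L]; bv <- g[, 2L]
  } else {
    av <- draws$a; bv <- draws$b
    a <- "a"; b <- "b"
  }
  if (length(av) != length(bv)) {
    stop("alignment error: path draws have different lengths")
  }
  prod <- av * bv
  structure(list(
    a_name = a, b_name = b,
    product = summarise_vector(prod, paste0(a, " x ", b)),
    paths = rbind(summarise_vector(av, a), summarise_vector(bv, b)),
    draws = prod
  ), class = "mediation_summary")
}

#' @export
print.mediation_summary <- function(x, ...) {
  cat("<mediation_summary> ", x$a_name, " x ", x$b_name, "\n", sep = "")
  print(x$product, row.names = FALSE)
  invisible(x)
}

#' Random-effect correlation summaries
#'
#' Converts each stored draw of the random-effect residual covariance to a
#' correlation matrix and summarises every off-diagonal entry that the model
#' allows to be non-zero (entries within the spec's covariance blocks).
#'
#' @param draws A [dsem_fit()] result.
#' @return Data frame of summaries, one row per free off-diagonal pair (e.g.
#'   `cor.mu_pb.psi_pb`).
#' @export
random_effect_correlations <- function(draws) {
  stopifnot(inherits(draws, "dsem_draws"))
  g <- pooled_draws(draws)
  sig_cols <- grep("^Sigma\\.", colnames(g), value = TRUE)
  parts <- strsplit(sub("^Sigma\\.", "", sig_cols), ".", fixed = TRUE)
  out <- list()
  for (k in seq_along(sig_cols)) {
    a <- parts[[k]][1L]; b <- parts[[k]][2L]
    if (a == b) next
    va <- g[, paste("Sigma", a, a, sep = ".")]
    vb <- g[, paste("Sigma", b, b, sep = ".")]
    r <- g[, sig_cols[k]] / sqrt(va * vb)
    out[[length(out) + 1L]] <- summarise_vector(r, paste("cor", a, b, sep = "."))
  }
  if (length(out) == 0L) return(data.frame())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Tidy export of posterior summaries
#'
#' Writes the [summarize_posterior()] table as CSV (parameter, median,
#' ci_low, ci_high, non_null) and, optionally, a JSON mediation report.
#'
#' @param draws A `dsem_draws`.
#' @param path Output CSV path.
#' @param mediation_paths Optional named list of `c(a, b)` parameter pairs.
#' @param mediation_path Output JSON path for the mediation report.
#' @return `path`, invisibly.
#' @export
write_summary <- function(draws, path, mediation_paths = NULL,
                          mediation_path = NULL) {
  utils::write.csv(summarize_posterior(draws), path, row.names = FALSE)
  if (!is.null(mediation_paths)) {
    med <- lapply(mediation_paths, function(ab) {
      m <- mediation(draws, ab[1L], ab[2L])
      list(a = m$a_name, b = m$b_name,
           median = m$product$median,
           ci_low = m$product$ci_low, ci_high = m$product$ci_high,
           non_null = m$product$non_null)
    })
    jsonlite::write_json(med, mediation_path %||% sub("\\.csv$", "_mediation.json", path),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
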