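# Model-free two-level descriptives: intraclass correlations, within/between
# correlation decomposition, person-mean tables and compliance statistics.
# These use observed person means (the sample analogue of the model's latent
# decomposition) and serve as a fast sanity layer next to the fitted model.

#' Intraclass correlation of a momentary variable
#'
#' One-way random-effects ANOVA estimator of the proportion of total variance
#' attributable to between-person differences, with the standard unbalanced
#' `n0` correction; a negative between-person variance component is truncated
#' at zero.
#'
#' @param panel An [esm_panel()].
#' @param variable `"pb"` or `"ge"`.
#' @return The ICC (scalar), with attribute `components` holding the
#'   between/within variance estimates.
#' @export
icc <- function(panel, variable = c("pb", "ge")) {
  variable <- match.arg(variable)
  x <- panel[[variable]]
  id <- panel$person_id[!is.na(x)]
  x <- x[!is.na(x)]
  counts <- table(id)
  counts <- counts[counts >= 1L]
  k <- length(counts)
  if (k < 2L || sum(counts >= 2L) < 2L) {
    stop("ICC requires at least 2 persons with at least 2 observations")
  }
  N <- length(x)
  gm <- mean(x)
  means <- tapply(x, id, mean)
  ssb <- sum(counts * (means[names(counts)] - gm)^2)
  ssw <- sum((x - means[id])^2)
  if (ssw == 0 && ssb == 0) stop("ICC undefined: all observations constant")
  msb <- ssb / (k - 1)
  msw <- ssw / (N - k)
  n0 <- (N - sum(counts^2) / N) / (k - 1)
  sb <- max((msb - msw) / n0, 0)
  out <- sb / (sb + msw)
  attr(out, "components") <- c(between = sb, within = msw)
  out
}

#' Two-level decomposition table
#'
#' Splits each momentary variable into observed person means and
#' person-mean-centered deviations, and reports per-variable grand means,
#' between/within variance components, and ICCs, plus the within-level
#' correlation of the deviations and between-level correlations of the person
#' means with each other and with the person-level trait variables. Observed
#' person means are noisy proxies for latent means, so between-level values
#' differ modestly from a latent decomposition; this is expected.
#'
#' @param panel An [esm_panel()].
#' @param persons Optional `person_table` supplying trait variables for the
#'   between-level correlations.
#' @return Object of class `decomposition_table`: list with `variables`
#'   (per-variable summary), `within_cor` (pb-ge deviation correlation),
#'   `between_cor` (correlation matrix of person means and traits), and
#'   `flags` (pairs with degenerate variance).
#' @export
two_level_correlations <- function(panel, persons = NULL) {
  df <- as.data.frame(panel)
  vars <- c("pb", "ge")
  per_var <- lapply(vars, function(v) {
    i <- icc(panel, v)
    comp <- attr(i, "components")
    data.frame(variable = v, grand_mean = mean(df[[v]], na.rm = TRUE),
               between_var = comp["between"], within_var = comp["within"],
               icc = as.numeric(i), row.names = NULL)
  })
  variables <- do.call(rbind, per_var)

  pm <- lapply(vars, function(v) tapply(df[[v]], df$person_id, mean, na.rm = TRUE))
  names(pm) <- vars
  dev <- lapply(vars, function(v) df[[v]] - pm[[v]][df$person_id])
  names(dev) <- vars
  flags <- character(0)
  ok <- stats::complete.cases(dev$pb, dev$ge)
  within_cor <- if (stats::sd(dev$pb[ok]) == 0 || stats::sd(dev$ge[ok]) == 0) {
    flags <- c(flags, "within:pb-ge")
    NA_real_
  } else {
    stats::cor(dev$pb[ok], dev$ge[ok])
  }

  ids <- names(pm$pb)
  bt <- data.frame(pb_mean = as.numeric(pm$pb[ids]),
                   ge_mean = as.numeric(pm$ge[ids]))
  if (!is.null(persons)) {
    persons <- as.data.frame(persons)
    m <- match(ids, persons$person_id)
    for (v in c("base_pb", "base_ge", "follow_pb", "follow_ge")) {
      if (v %in% names(persons)) bt[[v]] <- persons[[v]][m]
    }
  }
  keep <- vapply(bt, function(x) stats::sd(x, na.rm = TRUE) > 0, logical(1L))
  flags <- c(flags, paste0("between:", names(bt)[!keep & !is.na(keep)]))
  between_cor <- stats::cor(bt[keep], use = "pairwise.complete.obs")

  structure(list(variables = variables, within_cor = within_cor,
                 between_cor = between_cor,
                 flags = flags[flags != "between:"]),
            class = "decomposition_table")
}

#' @export
print.decomposition_table <- function(x, ...) {
  cat("<decomposition_table>\n")
  print(x$variables, row.names = FALSE)
  cat("  within-level pb-ge correlation:", round(x$within_cor, 3), "\n")
  cat("  between-level correlations:\n")
  print(round(x$between_cor, 3))
  invisible(x)
}

#' Compliance summary of an ESM panel
#'
#' Per-person and overall counts of answered prompts, the share of possible
#' prompts answered, and per-variable missingness among answered prompts.
#'
#' @param panel An [esm_panel()].
#' @return Object of class `compliance_summary`: list with `per_person`
#'   (data frame of counts), `mean_responses`, `sd_responses`, `total`,
#'   `possible_per_person`, `missing` (per-variable counts).
#' @export
compliance_summary <- function(panel) {
  design <- attr(panel, "design")
  counts <- table(factor(panel$person_id, levels = unique(panel$person_id)))
  per_person <- data.frame(person_id = names(counts),
                           n_responses = as.integer(counts), row.names = NULL)
  possible <- design$n_days * design$prompts_per_day
  structure(list(
    per_person = per_person,
    mean_responses = mean(per_person$n_responses),
    sd_responses = stats::sd(per_person$n_responses),
    total = nrow(panel),
    possible_per_person = possible,
    compliance_rate = mean(per_person$n_responses) / possible,
    missing = c(pb = sum(is.na(panel$pb)), ge = sum(is.na(panel$ge)))
  ), class = "compliance_summary")
}

#' @export
print.compliance_summary <- function(x, ...) {
  cat("<compliance_summary>\n")
  cat("  persons:", nrow(x$per_person), "\n")
  cat(sprintf("  responses/person: mean %.2f (SD %.2f) of %d possible\n",
              x$mean_responses, x$sd_responses, x$possible_per_person))
  cat("  total records:", x$total, "\n")
  invisible(x)
}

#' Write the decomposition table as CSV
#'
#' @param decomp A [two_level_correlations()] result.
#' @param path Output path (two CSVs are written: `<path>` for the variable
#'   table and `<path>` with suffix `_cor` for the between-level matrix).
#' @return `path`, invisibly.
#' @export
write_decomposition <- function(decomp, path) {
  utils::write.csv(decomp$variables, path, row.names = FALSE)
  cp <- sub("(\\.[a-zA-Z]+)?$", "_cor\\1", path)
  utils::write.csv(as.data.frame(decomp$between_cor), cp, row.names = TRUE)
  invisible(path)
}
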