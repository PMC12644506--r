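# Reading, validation and preparation of ESM panel and person-level tables.
#
# File dialects (UTF-8 CSV, empty cell = missing):
#   ESM panel:    person_id, day, prompt, time_min, pb, ge
#   person table: person_id, base_pb, base_ge, follow_pb, follow_ge,
#                 gender_female, single, income, needs
# Days and prompts are 1-based in files; internally persons are indexed
# 1..n in first-appearance order.

#' Default column mapping for ESM panel files
#'
#' @param person_id,day,prompt,time_min,pb,ge Column names in the file for
#'   each canonical field.
#' @return Named character vector mapping canonical names to file columns.
#' @export
esm_schema <- function(person_id = "person_id", day = "day", prompt = "prompt",
                       time_min = "time_min", pb = "pb", ge = "ge") {
  c(person_id = person_id, day = day, prompt = prompt,
    time_min = time_min, pb = pb, ge = ge)
}

#' Construct an ESM panel object
#'
#' An `esm_panel` is a long-format table of momentary records (one row per
#' answered prompt) carrying the two momentary scores, ordered within person
#' by day and timestamp, together with the sampling design metadata.
#'
#' @param records Data frame with columns `person_id`, `day`, `prompt`,
#'   `time_min`, `pb`, `ge`. Scores may be `NA` (missing).
#' @param design List with `n_days`, `prompts_per_day`, `window_start_min`,
#'   `window_end_min`.
#' @param range Permitted closed range for the momentary scores, or `NULL`
#'   to skip range validation (synthetic scores are continuous and may
#'   exceed the instrument bounds).
#' @return An object of class `esm_panel` (a data frame with a `design`
#'   attribute).
#' @export
esm_panel <- function(records,
                      design = list(n_days = max(records$day),
                                    prompts_per_day = max(records$prompt),
                                    window_start_min = 480, window_end_min = 1200),
                      range = c(1, 7)) {
  need <- c("person_id", "day", "prompt", "time_min", "pb", "ge")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0L) {
    stop("records is missing column(s): ", paste(miss, collapse = ", "))
  }
  records <- as.data.frame(records)[need]
  records$person_id <- as.character(records$person_id)
  for (v in c("day", "prompt", "time_min", "pb", "ge")) {
    records[[v]] <- as.numeric(records[[v]])
  }
  validate_records(records, range = range)
  # Order within person by (day, timestamp); persons keep first appearance order.
  pidx <- match(records$person_id, unique(records$person_id))
  ord <- order(pidx, records$day, records$time_min)
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  dup <- duplicated(records[c("person_id", "day", "prompt")])
  if (any(dup)) {
    stop("duplicate (person, day, prompt) records at rows: ",
         paste(utils::head(which(dup), 5L), collapse = ", "))
  }
  structure(records, design = design, class = c("esm_panel", "data.frame"))
}

validate_records <- function(records, range = c(1, 7)) {
  bad_day <- which(!is.na(records$day) & records$day < 1)
  if (length(bad_day) > 0L) {
    stop("day < 1 at row(s): ", paste(utils::head(bad_day, 5L), collapse = ", "))
  }
  bad_t <- which(!is.na(records$time_min) &
                   (records$time_min < 0 | records$time_min >= 1440))
  if (length(bad_t) > 0L) {
    stop("timestamp outside [0, 1440) at row(s): ",
         paste(utils::head(bad_t, 5L), collapse = ", "))
  }
  if (!is.null(range)) {
    for (v in c("pb", "ge")) {
      x <- records[[v]]
      bad <- which(!is.na(x) & (x < range[1] | x > range[2]))
      if (length(bad) > 0L) {
        stop("validation error: ", v, " outside [", range[1], ", ", range[2],
             "] at row(s): ", paste(utils::head(bad, 5L), collapse = ", "))
      }
    }
  }
  invisible(TRUE)
}

#' Read an ESM panel from CSV
#'
#' Parses and validates a long-format ESM file. Empty cells become explicit
#' missing values. A parse report (persons, records, missing counts) is
#' attached as attribute `parse_report` and available via [parse_report()].
#'
#' @param path Path to the CSV file.
#' @param schema Column mapping from [esm_schema()].
#' @param design Optional design metadata (inferred from the data otherwise).
#' @param range Permitted score range, or `NULL` to skip the range check.
#' @return An [esm_panel()].
#' @export
read_esm_panel <- function(path, schema = esm_schema(), design = NULL,
                           range = c(1, 7)) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"), fileEncoding = "UTF-8")
  miss <- setdiff(unname(schema), names(raw))
  if (length(miss) > 0L) {
    stop("schema error: mapped column(s) not in file: ",
         paste(miss, collapse = ", "))
  }
  records <- stats::setNames(raw[unname(schema)], names(schema))
  if (is.null(design)) {
    design <- list(n_days = max(records$day, na.rm = TRUE),
                   prompts_per_day = max(records$prompt, na.rm = TRUE),
                   window_start_min = 480, window_end_min = 1200)
  }
  panel <- esm_panel(records, design = design, range = range)
  report <- list(
    n_persons = length(unique(panel$person_id)),
    n_records = nrow(panel),
    n_missing = c(pb = sum(is.na(panel$pb)), ge = sum(is.na(panel$ge)))
  )
  attr(panel, "parse_report") <- report
  panel
}

#' @rdname read_esm_panel
#' @param x An object with a parse report attribute.
#' @export
parse_report <- function(x) attr(x, "parse_report")

#' Write an ESM panel to CSV
#'
#' Round-trip companion of [read_esm_panel()]: missing values are written as
#' empty cells, and reading the file back reproduces records and missing
#' flags exactly (timestamps and scores are serialized at full precision).
#'
#' @param panel An [esm_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_esm_panel <- function(panel, path) {
  df <- as.data.frame(panel)
  for (v in c("time_min", "pb", "ge")) {
    df[[v]] <- ifelse(is.na(df[[v]]), "", format(df[[v]], digits = 17L,
                                                 scientific = FALSE, trim = TRUE))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a person-level table from CSV
#'
#' One row per person: baseline and follow-up trait scores, plus four
#' sociodemographic covariates (gender, single parenthood, household income
#' on a 1-13 ordinal scale, special-needs flag).
#'
#' @param path Path to the CSV file.
#' @param range Permitted range for baseline trait scores, or `NULL` to skip.
#'   Follow-up scores are checked only when `strict = TRUE`, since simulated
#'   follow-ups are continuous and unclipped by default.
#' @param strict Also range-check follow-up scores.
#' @return A `person_table` data frame.
#' @export
read_person_table <- function(path, range = c(1, 7), strict = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"), fileEncoding = "UTF-8")
  person_table(df, range = range, strict = strict)
}

#' @rdname read_person_table
#' @param df Data frame with the person-table columns.
#' @export
person_table <- function(df, range = c(1, 7), strict = FALSE) {
  need <- c("person_id", "base_pb", "base_ge", "follow_pb", "follow_ge",
            "gender_female", "single", "income", "needs")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("person table is missing column(s): ", paste(miss, collapse = ", "))
  }
  df <- as.data.frame(df)[need]
  df$person_id <- as.character(df$person_id)
  if (anyDuplicated(df$person_id)) stop("duplicate person_id in person table")
  if (!is.null(range)) {
    vars <- c("base_pb", "base_ge", if (strict) c("follow_pb", "follow_ge"))
    for (v in vars) {
      x <- df[[v]]
      bad <- which(!is.na(x) & (x < range[1] | x > range[2]))
      if (length(bad) > 0L) {
        stop("validation error: ", v, " outside [", range[1], ", ", range[2],
             "] at row(s): ", paste(utils::head(bad, 5L), collapse = ", "))
      }
    }
  }
  for (v in c("gender_female", "single", "needs")) {
    if (!all(df[[v]] %in% c(0, 1, NA))) stop(v, " must be 0/1")
  }
  if (!all(is.na(df$income) | (df$income >= 1 & df$income <= 13))) {
    stop("income must lie in 1..13")
  }
  structure(df, class = c("person_table", "data.frame"))
}

#' Write a person table to CSV
#' @param persons A `person_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_person_table <- function(persons, path) {
  df <- as.data.frame(persons)
  num <- vapply(df, is.numeric, logical(1))
  for (v in names(df)[num]) {
    df[[v]] <- ifelse(is.na(df[[v]]), "", format(df[[v]], digits = 17L,
                                                 scientific = FALSE, trim = TRUE))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Enumerate lag pairs and centre between-person predictors
#'
#' Builds the analysis dataset consumed by [dsem_fit()]: per-person
#' observation sequences with an explicit lag-pair index set under the
#' chosen lag policy, plus the centered between-person predictor matrix.
#'
#' Lag policies: `"consecutive"` treats adjacent observed records within a
#' person as a (t-1, t) pair regardless of clock gaps (including overnight);
#' `"same_day_only"` restricts pairs to records on the same calendar day.
#' Continuous predictors (`base_pb`, `base_ge`, `income`) are grand-mean
#' centered over the persons present in the analysis set; binary covariates
#' enter uncentered. Centering constants are stored for back-transformation.
#'
#' @param panel An [esm_panel()].
#' @param persons A `person_table` covering every person in the panel.
#' @param lag_policy `"consecutive"` (default) or `"same_day_only"`.
#' @return An object of class `analysis_dataset`: list with `obs` (ordered
#'   records with integer person index), `pairs` (src/tgt row indices into
#'   `obs`), `persons` (centered predictor table), `centering` (named
#'   constants), `lag_policy`, `design`.
#' @export
build_analysis_dataset <- function(panel, persons,
                                   lag_policy = c("consecutive", "same_day_only")) {
  lag_policy <- match.arg(lag_policy)
  stopifnot(inherits(panel, "esm_panel"))
  persons <- if (inherits(persons, "person_table")) persons else person_table(persons)
  panel_ids <- unique(panel$person_id)
  absent <- setdiff(panel_ids, persons$person_id)
  if (length(absent) > 0L) {
    stop("join error: person(s) in panel absent from person table: ",
         paste(utils::head(absent, 10L), collapse = ", "))
  }
  persons <- persons[match(panel_ids, persons$person_id), , drop = FALSE]
  rownames(persons) <- NULL

  obs <- as.data.frame(panel)
  obs$person <- match(obs$person_id, panel_ids)

  # Lag pairs: rows are already ordered by (person, day, time).
  same_person <- obs$person[-1L] == obs$person[-nrow(obs)]
  keep <- same_person
  if (lag_policy == "same_day_only") {
    keep <- keep & (obs$day[-1L] == obs$day[-nrow(obs)])
  }
  src <- which(keep)
  pairs <- data.frame(person = obs$person[src], src = src, tgt = src + 1L)

  centering <- c(base_pb = mean(persons$base_pb, na.rm = TRUE),
                 base_ge = mean(persons$base_ge, na.rm = TRUE),
                 income = mean(persons$income, na.rm = TRUE))
  ptab <- data.frame(
    person_id = persons$person_id,
    base_pb_c = persons$base_pb - centering["base_pb"],
    base_ge_c = persons$base_ge - centering["base_ge"],
    income_c = persons$income - centering["income"],
    gender_female = persons$gender_female,
    single = persons$single,
    needs = persons$needs,
    follow_pb = persons$follow_pb,
    follow_ge = persons$follow_ge,
    base_pb = persons$base_pb,
    base_ge = persons$base_ge,
    income = persons$income
  )

  structure(list(obs = obs, pairs = pairs, persons = ptab,
                 centering = centering, lag_policy = lag_policy,
                 design = attr(panel, "design")),
            class = "analysis_dataset")
}

#' @export
print.analysis_dataset <- function(x, ...) {
  cat("<analysis_dataset>\n")
  cat("  persons:   ", nrow(x$persons), "\n")
  cat("  records:   ", nrow(x$obs), "\n")
  cat("  lag pairs: ", nrow(x$pairs), " (policy: ", x$lag_policy, ")\n", sep = "")
  invisible(x)
}

#' Report-only validation of an analysis dataset
#'
#' Flags persons with few usable lag pairs or variance-degenerate (constant)
#' observed series, and reports compliance (share of possible prompts
#' answered) and per-variable missingness. Never mutates the data.
#'
#' @param ds An `analysis_dataset`.
#' @param min_pairs Minimum usable lag pairs before a person is flagged.
#' @return A list of class `validation_report`.
#' @export
validate_dataset <- function(ds, min_pairs = 3L) {
  stopifnot(inherits(ds, "analysis_dataset"))
  n <- nrow(ds$persons)
  npairs <- tabulate(ds$pairs$person, nbins = n)
  few <- ds$persons$person_id[npairs < min_pairs]
  degen <- character(0)
  for (i in seq_len(n)) {
    rows <- ds$obs[ds$obs$person == i, c("pb", "ge")]
    for (v in c("pb", "ge")) {
      x <- rows[[v]][!is.na(rows[[v]])]
      if (length(x) >= 2L && stats::var(x) == 0) {
        degen <- c(degen, paste0(ds$persons$person_id[i], ":", v))
      }
    }
  }
  possible <- ds$design$n_days * ds$design$prompts_per_day * n
  missing_rate <- c(pb = mean(is.na(ds$obs$pb)), ge = mean(is.na(ds$obs$ge)))
  structure(list(
    n_persons = n,
    pairs_per_person = npairs,
    few_pairs = few,
    degenerate = degen,
    compliance = if (is.finite(possible) && possible > 0) nrow(ds$obs) / possible else NA_real_,
    observed_rate = 1 - missing_rate,
    missing_rate = missing_rate
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  cat("  persons:", x$n_persons, "\n")
  cat("  compliance:", round(x$compliance, 3), "\n")
  cat("  missing rate: pb", round(x$missing_rate["pb"], 3),
      "ge", round(x$missing_rate["ge"], 3), "\n")
  if (length(x$few_pairs)) {
    cat("  few lag pairs:", paste(utils::head(x$few_pairs, 10), collapse = ", "), "\n")
  }
  if (length(x$degenerate)) {
    cat("  degenerate series:", paste(utils::head(x$degenerate, 10), collapse = ", "), "\n")
  }
  invisible(x)
}
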