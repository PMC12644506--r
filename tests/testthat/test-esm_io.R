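# I/O, lag-pair construction and centering.

test_that("read_esm_panel parses, propagates missing, and validates ranges", {
  rows <- toy_panel_rows()
  p <- read_esm_panel(write_toy_csv(rows))
  expect_s3_class(p, "esm_panel")
  expect_equal(nrow(p), 3L)
  expect_equal(unname(parse_report(p)$n_missing), c(0L, 0L))

  rows2 <- rows
  rows2$pb[2] <- NA
  p2 <- read_esm_panel(write_toy_csv(rows2))
  expect_true(is.na(p2$pb[2]))
  expect_equal(unname(parse_report(p2)$n_missing["pb"]), 1L)

  rows3 <- rows
  rows3$pb[3] <- 9
  expect_error(read_esm_panel(write_toy_csv(rows3)), "validation error.*pb")
  # but permissible when range checking is off (continuous synthetic scores)
  expect_silent(p3 <- read_esm_panel(write_toy_csv(rows3), range = NULL))

  rows4 <- rows
  names(rows4)[names(rows4) == "pb"] <- "burnout"
  expect_error(read_esm_panel(write_toy_csv(rows4)), "schema error.*pb")
  p4 <- read_esm_panel(write_toy_csv(rows4), schema = esm_schema(pb = "burnout"))
  expect_equal(p4$pb, rows$pb)
})

test_that("esm_panel enforces structural invariants", {
  rows <- toy_panel_rows()
  rows$time_min[1] <- 1500
  expect_error(esm_panel(rows), "timestamp")
  rows <- toy_panel_rows()
  rows$day[1] <- 0
  expect_error(esm_panel(rows), "day")
  rows <- toy_panel_rows()
  rows$day <- 1
  rows$prompt <- c(1, 1, 2)
  expect_error(esm_panel(rows), "duplicate")
})

test_that("panel round-trips through CSV exactly, including missing flags", {
  st <- small_study(seed = 4, n = 8, days = 4, compliance = 0.8)
  panel <- st$panel
  panel$pb[c(3, 11)] <- NA
  panel$ge[7] <- NA
  path <- tempfile(fileext = ".csv")
  write_esm_panel(panel, path)
  back <- read_esm_panel(path, range = NULL)
  expect_identical(back$person_id, panel$person_id)
  expect_equal(back$pb, panel$pb, tolerance = 0)
  expect_equal(back$ge, panel$ge, tolerance = 0)
  expect_equal(back$time_min, panel$time_min, tolerance = 0)
  expect_identical(is.na(back$pb), is.na(panel$pb))

  ppath <- tempfile(fileext = ".csv")
  write_person_table(st$persons, ppath)
  pback <- read_person_table(ppath, range = NULL)
  expect_equal(pback$base_pb, st$persons$base_pb, tolerance = 0)
  expect_equal(pback$follow_ge, st$persons$follow_ge, tolerance = 0)
})

make_persons <- function(ids) {
  person_table(data.frame(person_id = ids, base_pb = 2.5, base_ge = 5.5,
                          follow_pb = 3, follow_ge = 5, gender_female = 1,
                          single = 0, income = 6, needs = 0))
}

test_that("lag-pair enumeration follows the lag policy", {
  # person with a single observation: no predecessor, 0 pairs
  p1 <- esm_panel(data.frame(person_id = "a", day = 1, prompt = 1,
                             time_min = 500, pb = 2, ge = 5))
  ds <- build_analysis_dataset(p1, make_persons("a"))
  expect_equal(nrow(ds$pairs), 0L)

  # 5 consecutive same-day prompts: T - 1 = 4 pairs under same_day_only
  p2 <- esm_panel(data.frame(person_id = "a", day = 1, prompt = 1:5,
                             time_min = 500 + 10 * (0:4), pb = 2, ge = 5),
                  design = list(n_days = 1, prompts_per_day = 5,
                                window_start_min = 480, window_end_min = 1200))
  ds2 <- build_analysis_dataset(p2, make_persons("a"), "same_day_only")
  expect_equal(nrow(ds2$pairs), 4L)

  # 2 days x 3 prompts: the night boundary drops one pair under same_day_only
  p3 <- esm_panel(data.frame(person_id = "a", day = rep(1:2, each = 3),
                             prompt = rep(1:3, 2),
                             time_min = rep(c(500, 700, 900), 2),
                             pb = 2, ge = 5))
  expect_equal(nrow(build_analysis_dataset(p3, make_persons("a"),
                                           "same_day_only")$pairs), 4L)
  expect_equal(nrow(build_analysis_dataset(p3, make_persons("a"),
                                           "consecutive")$pairs), 5L)

  # person in panel but not in person table
  expect_error(build_analysis_dataset(p3, make_persons("b")), "join error.*a")
})

test_that("lag-pair counts satisfy the policy identities on random panels", {
  set.seed(42)
  for (rep in 1:5) {
    st <- small_study(seed = rep, n = 10, days = 4, compliance = 0.5)
    ds_c <- build_analysis_dataset(st$panel, st$persons, "consecutive")
    ds_d <- build_analysis_dataset(st$panel, st$persons, "same_day_only")
    obs <- as.data.frame(st$panel)
    n_obs <- table(factor(obs$person_id, levels = unique(obs$person_id)))
    expect_equal(nrow(ds_c$pairs), sum(pmax(n_obs - 1L, 0L)))
    per_day <- aggregate(prompt ~ person_id + day, obs, length)
    expect_equal(nrow(ds_d$pairs), sum(pmax(per_day$prompt - 1L, 0L)))
    # every pair references adjacent records of the same person
    expect_true(all(ds_c$obs$person[ds_c$pairs$src] ==
                      ds_c$obs$person[ds_c$pairs$tgt]))
    expect_true(all(ds_c$pairs$tgt == ds_c$pairs$src + 1L))
  }
})

test_that("centering is grand-mean over analysis persons and idempotent", {
  st <- small_study(seed = 2, n = 20, days = 3)
  ds <- build_analysis_dataset(st$panel, st$persons)
  expect_lt(abs(mean(ds$persons$base_pb_c)), 1e-12)
  expect_lt(abs(mean(ds$persons$base_ge_c)), 1e-12)
  expect_lt(abs(mean(ds$persons$income_c)), 1e-12)
  # binaries untouched
  expect_identical(ds$persons$gender_female, st$persons$gender_female)
  expect_identical(ds$persons$single, st$persons$single)
  # constants recorded and recover the raw values
  expect_equal(ds$persons$base_pb_c + ds$centering["base_pb"],
               st$persons$base_pb, ignore_attr = TRUE)
  # idempotence: predictors already centered at zero stay unchanged
  persons0 <- as.data.frame(st$persons)
  persons0$base_pb <- persons0$base_pb - mean(persons0$base_pb) + 4
  ds0 <- build_analysis_dataset(st$panel, person_table(persons0))
  persons00 <- persons0
  persons00$base_pb <- ds0$persons$base_pb_c + 4
  ds00 <- build_analysis_dataset(st$panel, person_table(persons00))
  expect_equal(ds00$persons$base_pb_c, ds0$persons$base_pb_c, tolerance = 1e-12)
})

test_that("validate_dataset flags sparse and degenerate persons and reports compliance", {
  st <- small_study(seed = 3, n = 10, days = 5)
  ds <- build_analysis_dataset(st$panel, st$persons)
  rep <- validate_dataset(ds)
  expect_length(rep$few_pairs, 0L)
  expect_length(rep$degenerate, 0L)

  # constant pb series -> degenerate flag
  obs <- as.data.frame(st$panel)
  obs$pb[obs$person_id == "p0001"] <- 3
  panel2 <- esm_panel(obs, attr(st$panel, "design"), range = NULL)
  rep2 <- validate_dataset(build_analysis_dataset(panel2, st$persons))
  expect_true("p0001:pb" %in% rep2$degenerate)

  # 50% missing pb -> observed rate 0.5 for pb
  obs3 <- as.data.frame(st$panel)
  obs3$pb[seq(1, nrow(obs3), by = 2)] <- NA
  panel3 <- esm_panel(obs3, attr(st$panel, "design"), range = NULL)
  rep3 <- validate_dataset(build_analysis_dataset(panel3, st$persons))
  expect_equal(unname(rep3$observed_rate["pb"]),
               1 - ceiling(nrow(obs3) / 2) / nrow(obs3), tolerance = 1e-12)
})
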