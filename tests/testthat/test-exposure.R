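test_that("LCT schedule evaluates and clips correctly", {
  expect_equal(lct_for_age(0), 15)
  expect_equal(lct_for_age(10), 10)
  expect_equal(lct_for_age(30), 0)
  expect_error(lct_for_age(-1), "non-negative")
  sched <- age_lct_schedule(floor = 5)
  expect_equal(lct_for_age(30, sched), 5)
  # non-increasing in age
  expect_true(all(diff(lct_for_age(0:40)) <= 0))
})

test_that("physiological LCT evaluates the heat-balance form", {
  expect_equal(physiological_lct(39, 0.1, 0, 0, 0.05), 39)
  expect_equal(physiological_lct(39, external_insulation = 0.1,
                                 min_evaporative_heat_loss = 10,
                                 thermoneutral_heat_production = 60,
                                 tissue_insulation = 0.05), 31)
  # more tissue insulation strictly lowers the LCT
  lcts <- vapply(c(0.02, 0.05, 0.1, 0.2), function(it) {
    physiological_lct(39, 0.1, 10, 60, it)
  }, numeric(1))
  expect_true(all(diff(lcts) < 0))
})

test_that("exposure categories match printed boundaries after rounding", {
  b <- b2g_scheme()
  expect_equal(as.character(categorise_exposure(0.32, b)), "<=0.32")
  expect_equal(as.character(categorise_exposure(0.97, b)), ">=0.97")
  expect_equal(as.character(categorise_exposure(0.585, b)), "0.59-0.96")
  expect_equal(as.character(categorise_exposure(0.325, b)), "0.33-0.58")
  g <- g2e_scheme()
  expect_equal(as.character(categorise_exposure(0, g)), "<=0.01")
  expect_equal(as.character(categorise_exposure(0.015, g)), "0.02-0.06")
  expect_equal(as.character(categorise_exposure(0.28, g)), ">=0.28")
  # every representable proportion maps to exactly one category
  grid <- seq(0, 1, by = 0.001)
  expect_false(anyNA(categorise_exposure(grid, b)))
  expect_false(anyNA(categorise_exposure(grid, g)))
  expect_error(categorise_exposure(1.2, b), "\\[0, 1\\]")
})

test_that("exposure proportion handles the all-above and all-below extremes", {
  birth <- as.POSIXct("2020-01-01 00:00:00", tz = "UTC")
  et_warm <- et_series("2020-01-01 00:00:00", rep(20, 240))
  warm <- exposure_proportion(birth, birth, birth + 240 * 3600, et_warm)
  expect_equal(warm$proportion, 0)
  expect_equal(warm$total_hours, 240)

  et_cold <- et_series("2020-01-01 00:00:00", rep(-10, 240))
  cold <- exposure_proportion(birth, birth, birth + 240 * 3600, et_cold)
  expect_equal(cold$proportion, 1)
})

test_that("a crafted 48-h window straddling the day-1 LCT step scores 12/48", {
  birth <- as.POSIXct("2020-01-01 00:00:00", tz = "UTC")
  # day 0 (LCT 15): hours 0-11 at 14.9 (below), hours 12-23 at 15.0 (not
  # below: strict comparison); day 1 (LCT 14.5): all at 14.7 (not below)
  vals <- c(rep(14.9, 12), rep(15, 12), rep(14.7, 24))
  et <- et_series("2020-01-01 00:00:00", vals)
  res <- exposure_proportion(birth, birth, birth + 48 * 3600, et)
  orc <- oracle_exposure(birth, birth, birth + 48 * 3600, et)
  expect_equal(orc$below, 12L)   # oracle confirms the construction
  expect_equal(res$hours_below, orc$below)
  expect_equal(res$proportion, 0.25)
})

test_that("an hour exactly at the LCT is not counted as below", {
  birth <- as.POSIXct("2020-01-01 00:00:00", tz = "UTC")
  et <- et_series("2020-01-01 00:00:00", rep(15, 24))
  expect_equal(exposure_proportion(birth, birth, birth + 86400, et)$proportion, 0)
})

test_that("exposure proportion agrees with the brute-force oracle", {
  set.seed(101)
  for (rep in 1:20) {
    n_hours <- sample(24:400, 1)
    birth <- as.POSIXct("2020-03-01 00:00:00", tz = "UTC") +
      sample(0:86400, 1)
    et <- et_series("2020-03-01 00:00:00",
                    runif(n_hours, -5, 20))
    start <- birth + sample(0:(3600 * 5), 1)
    end <- start + sample(c(36, 48, 120, 200), 1) * 3600
    end <- min(end, max(et$timestamp) + 3600)
    if (end <= start) next
    res <- exposure_proportion(birth, start, end, et)
    orc <- oracle_exposure(birth, start, end, et)
    expect_equal(res$hours_below, orc$below)
    expect_equal(res$total_hours, orc$total)
    expect_equal(res$proportion, orc$proportion)
  }
})

test_that("exposure counts are conserved under window splitting", {
  set.seed(202)
  birth <- as.POSIXct("2020-02-01 00:00:00", tz = "UTC")
  et <- et_series("2020-02-01 00:00:00", runif(10 * 24, 0, 18))
  whole <- exposure_proportion(birth, birth, birth + 10 * 86400, et)
  mid <- birth + 4 * 86400 + 7 * 3600
  a <- exposure_proportion(birth, birth, mid, et)
  b <- exposure_proportion(birth, mid, birth + 10 * 86400, et)
  expect_equal(a$hours_below + b$hours_below, whole$hours_below)
  expect_equal(a$total_hours + b$total_hours, whole$total_hours)
})

test_that("exposure is monotone in ET shifts and schedule shifts", {
  set.seed(303)
  birth <- as.POSIXct("2020-02-01 00:00:00", tz = "UTC")
  et <- et_series("2020-02-01 00:00:00", runif(8 * 24, 0, 18))
  base <- exposure_proportion(birth, birth, birth + 8 * 86400, et)
  for (delta in c(0.5, 2, 5)) {
    colder <- et
    colder$effective_temp <- et$effective_temp - delta
    shifted <- exposure_proportion(birth, birth, birth + 8 * 86400, colder)
    expect_gte(shifted$proportion, base$proportion)

    sched_up <- age_lct_schedule(lct_at_birth = 15 + delta)
    raised <- exposure_proportion(birth, birth, birth + 8 * 86400, et,
                                  schedule = sched_up)
    expect_gte(raised$proportion, base$proportion)
  }
})

test_that("exposure errors on empty or uncovered windows", {
  birth <- as.POSIXct("2020-01-01 00:00:00", tz = "UTC")
  et <- et_series("2020-01-01 00:00:00", rep(10, 24))
  expect_error(exposure_proportion(birth, birth, birth, et), "empty window")
  expect_error(exposure_proportion(birth, birth - 3600, birth + 3600, et),
               "before birth")
  expect_error(
    exposure_proportion(birth, birth + 5 * 86400, birth + 6 * 86400, et),
    "no climate hours")
})
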