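test_that("season of birth follows the meteorological month grouping", {
  expect_equal(as.character(season_of_birth(as.Date("2020-01-15"))), "winter")
  expect_equal(as.character(season_of_birth(as.Date("2020-03-01"))), "spring")
  expect_equal(as.character(season_of_birth(as.Date("2020-11-30"))), "autumn")
  # every month maps to exactly one season, three months per season
  months <- as.Date(sprintf("2020-%02d-10", 1:12))
  tab <- table(season_of_birth(months))
  expect_equal(unname(as.vector(tab)), rep(3L, 4))
})

test_that("health classification matches the status definitions", {
  expect_equal(as.character(classify_health(2, 3)), "Healthy")
  expect_equal(as.character(classify_health(2, 4)), "Intermediate")
  expect_equal(as.character(classify_health(3, 3)), "Diseased")
  expect_equal(as.character(classify_health(1, 5)), "Diseased")
  expect_error(classify_health(4, 4), "out of range")
  expect_error(classify_health(2, 16), "out of range")
  expect_error(classify_health(3, 2), "cannot be below")
})

test_that("health classification partitions all valid score pairs", {
  pairs <- expand.grid(rectal = 0:3, overall = 0:15)
  pairs <- pairs[pairs$overall >= pairs$rectal, ]
  status <- classify_health(pairs$rectal, pairs$overall)
  expect_false(anyNA(status))
  expect_setequal(levels(status), c("Healthy", "Intermediate", "Diseased"))
  # each rule region maps where it should
  healthy <- pairs$rectal <= 2 & pairs$overall <= 3
  expect_true(all(status[healthy] == "Healthy"))
  inter <- pairs$rectal <= 2 & pairs$overall == 4
  expect_true(all(status[inter] == "Intermediate"))
  dis <- pairs$rectal == 3 | pairs$overall >= 5
  expect_true(all(status[dis] == "Diseased"))
})

test_that("ever-signs-of-disease flags any non-healthy assessment", {
  expect_equal(as.character(signs_of_disease_ever(
    c("Healthy", "Healthy", "Healthy"))), "no")
  expect_equal(as.character(signs_of_disease_ever(
    c("Healthy", "Intermediate"))), "yes")
  expect_equal(as.character(signs_of_disease_ever("Diseased")), "yes")
  expect_error(signs_of_disease_ever(character(0)), "no health assessments")
})

make_roster <- function(n, exit_age = 8) {
  birth <- as.POSIXct("2020-01-01 06:00:00", tz = "UTC") + (seq_len(n) - 1) * 3600
  data.frame(
    calf_id = sprintf("C%03d", seq_len(n)),
    birth_datetime = birth,
    birth_weight = 42,
    hutch_exit_datetime = birth + exit_age * 86400,
    died = FALSE, sold = FALSE, returned_to_hutch = FALSE,
    stringsAsFactors = FALSE
  )
}

test_that("B2G filter reproduces the exclusion arithmetic and precedence", {
  roster <- make_roster(299)
  roster$birth_weight[1] <- NA                         # 1 missing weight
  roster$hutch_exit_datetime[2:28] <-
    roster$birth_datetime[2:28] + 15 * 86400           # 27 over-age
  res <- filter_b2g(roster)
  expect_length(res$eligible, 271)
  expect_equal(sum(res$exclusions$reason == "no birthweight"), 1)
  expect_equal(sum(res$exclusions$reason == "age > 14 d"), 27)

  # a calf failing both rules is logged once, under the first rule
  both <- make_roster(1, exit_age = 20)
  both$birth_weight <- NA
  res2 <- filter_b2g(both)
  expect_equal(res2$exclusions$reason, "no birthweight")

  # exactly 14 days is still eligible
  edge <- make_roster(1, exit_age = 14)
  expect_length(filter_b2g(edge)$eligible, 1)
})

test_that("filters are idempotent and conserve the roster", {
  roster <- make_roster(50)
  roster$birth_weight[7] <- NA
  res <- filter_b2g(roster)
  expect_equal(length(res$eligible) + nrow(res$exclusions), 50)
  again <- filter_b2g(roster[roster$calf_id %in% res$eligible, ])
  expect_equal(sort(again$eligible), sort(res$eligible))
})

test_that("G2E filter applies the fate, milk and weight rules in order", {
  roster <- make_roster(12)
  roster$died[1] <- TRUE
  roster$sold[2] <- TRUE
  roster$returned_to_hutch[3] <- TRUE
  entry <- roster$hutch_exit_datetime
  # two weighings for everyone, 4 and 11 days after entry
  weights <- do.call(rbind, lapply(1:12, function(i) {
    data.frame(calf_id = roster$calf_id[i],
               datetime = entry[i] + c(4, 11) * 86400,
               weight = c(45, 50))
  }))
  # calf 5 has only one weight
  weights <- weights[!(weights$calf_id == "C005" &
                         weights$weight == 50), ]
  milk <- do.call(rbind, lapply(1:12, function(i) {
    days <- seq(as.Date(entry[i]), as.Date(entry[i] + 11 * 86400), by = "day")
    data.frame(calf_id = roster$calf_id[i], date = days, cmr_mass = 900)
  }))
  # calf 4 loses a block of milk days (power failure)
  milk <- milk[!(milk$calf_id == "C004" &
                   milk$date > as.Date(entry[4]) + 5), ]
  res <- filter_g2e(roster$calf_id, roster, weights, milk)
  expect_setequal(res$exclusions$calf_id[res$exclusions$reason == "died or euthanised"], "C001")
  expect_setequal(res$exclusions$calf_id[res$exclusions$reason == "sold"], "C002")
  expect_setequal(res$exclusions$calf_id[res$exclusions$reason == "returned to hutch"], "C003")
  expect_setequal(res$exclusions$calf_id[res$exclusions$reason == "incomplete milk data"], "C004")
  expect_setequal(res$exclusions$calf_id[res$exclusions$reason == "fewer than two group-pen weights"], "C005")
  expect_length(res$eligible, 7)
})
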