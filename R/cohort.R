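#' Season of birth
#'
#' Meteorological seasons: winter (Dec-Feb), spring (Mar-May), summer
#' (Jun-Aug), autumn (Sep-Nov).
#'
#' @param birth_date Date or POSIXct; vectorised.
#' @return factor with levels winter, spring, summer, autumn.
#' @export
season_of_birth <- function(birth_date) {
  m <- as.integer(format(as.Date(birth_date, tz = "UTC"), "%m"))
  s <- c("winter", "winter", "spring", "spring", "spring", "summer",
         "summer", "summer", "autumn", "autumn", "autumn", "winter")[m]
  factor(s, levels = c("winter", "spring", "summer", "autumn"))
}

#' Classify health status from Wisconsin scores
#'
#' Status from the rectal-temperature component score (0-3) and the overall
#' Wisconsin score (sum of the five component scores, 0-15; faecal
#' consistency is not scored in group housing):
#' * Healthy: rectal score <= 2 and overall score <= 3
#' * Intermediate: rectal score <= 2 and overall score = 4
#' * Diseased: rectal score = 3 (regardless of overall), or overall score >= 5
#'
#' Every valid (rectal, overall) pair with overall >= rectal maps to exactly
#' one status.
#'
#' @param rectal_score integer 0-3; vectorised.
#' @param overall_score integer 0-15, at least `rectal_score`.
#' @return factor with levels Healthy, Intermediate, Diseased.
#' @export
classify_health <- function(rectal_score, overall_score) {
  if (any(rectal_score < 0 | rectal_score > 3) ||
      any(overall_score < 0 | overall_score > 15)) {
    stop("classify_health: scores out of range (rectal 0-3, overall 0-15)")
  }
  if (any(overall_score < rectal_score)) {
    stop("classify_health: overall score cannot be below the rectal score")
  }
  status <- ifelse(rectal_score == 3 | overall_score >= 5, "Diseased",
                   ifelse(overall_score == 4, "Intermediate", "Healthy"))
  factor(status, levels = c("Healthy", "Intermediate", "Diseased"))
}

#' Did a calf ever show signs of disease?
#'
#' A calf "ever showed clinical or mild signs of disease" iff any of its
#' health assessments was Intermediate or Diseased.
#'
#' @param statuses non-empty vector of statuses from [classify_health()].
#' @return factor "no"/"yes" (length 1).
#' @export
signs_of_disease_ever <- function(statuses) {
  if (length(statuses) == 0) {
    stop("signs_of_disease_ever: no health assessments supplied")
  }
  yes <- any(as.character(statuses) %in% c("Intermediate", "Diseased"))
  factor(if (yes) "yes" else "no", levels = c("no", "yes"))
}

#' Eligibility filter for the individual-hutch (B2G) dataset
#'
#' A calf enters the B2G analysis iff it has a recorded birth weight and was
#' 14 days of age or less (whole days since birth) when it left the
#' individual hutch. Rules are applied in that order and only the first
#' failing rule is logged per calf, so exclusion counts are disjoint.
#'
#' @param roster data frame of calf records with columns `calf_id`,
#'   `birth_datetime`, `birth_weight`, `hutch_exit_datetime`.
#' @return list with `eligible` (character ids) and `exclusions`
#'   (data frame: calf_id, phase, reason).
#' @export
filter_b2g <- function(roster) {
  stopifnot(all(c("calf_id", "birth_datetime", "birth_weight",
                  "hutch_exit_datetime") %in% names(roster)))
  exit_age <- whole_days(roster$birth_datetime, roster$hutch_exit_datetime)
  reason <- rep(NA_character_, nrow(roster))
  reason[is.na(roster$birth_weight)] <- "no birthweight"
  reason[is.na(reason) & exit_age > 14] <- "age > 14 d"
  list(
    eligible = roster$calf_id[is.na(reason)],
    exclusions = data.frame(
      calf_id = roster$calf_id[!is.na(reason)],
      phase = rep("B2G", sum(!is.na(reason))),
      reason = reason[!is.na(reason)],
      stringsAsFactors = FALSE
    )
  )
}

#' Eligibility filter for the group-pen (G2E) dataset
#'
#' Starting from the B2G-eligible calves, excludes (in order, logging the
#' first failing rule): calves that died or were euthanised, calves sold
#' before the end of the study, calves returned to an individual hutch after
#' entering the group pen, calves without a full set of milk-intake data
#' (a record for every calendar day from pen entry to last weighing;
#' feeder power failures lose whole blocks of days), and calves with fewer
#' than two group-pen weight records (a growth slope needs at least two
#' points).
#'
#' @param b2g_eligible character ids from [filter_b2g()].
#' @param roster calf records with fate flags `died`, `sold`,
#'   `returned_to_hutch` (logical) and `hutch_exit_datetime`.
#' @param weights weight records: `calf_id`, `datetime`, `weight`.
#' @param milk milk records: `calf_id`, `date` (Date), `cmr_mass`.
#' @return list with `eligible` ids and `exclusions` data frame.
#' @export
filter_g2e <- function(b2g_eligible, roster, weights, milk) {
  roster <- roster[roster$calf_id %in% b2g_eligible, , drop = FALSE]
  reason <- rep(NA_character_, nrow(roster))
  reason[roster$died] <- "died or euthanised"
  reason[is.na(reason) & roster$sold] <- "sold"
  reason[is.na(reason) & roster$returned_to_hutch] <- "returned to hutch"

  milk_days <- split(as.Date(milk$date), milk$calf_id)
  wt_times <- split(weights$datetime, weights$calf_id)
  for (i in seq_len(nrow(roster))) {
    if (!is.na(reason[i])) next
    id <- roster$calf_id[i]
    wts <- wt_times[[id]]
    if (length(wts) >= 1) {
      # the milk requirement spans pen entry to last weighing, so it can
      # only be delimited for calves with at least one group-pen weight
      entry_day <- as.Date(roster$hutch_exit_datetime[i], tz = "UTC")
      last_day <- as.Date(max(wts), tz = "UTC")
      required <- seq(entry_day, last_day, by = "day")
      have <- milk_days[[id]]
      if (is.null(have) || !all(required %in% have)) {
        reason[i] <- "incomplete milk data"
        next
      }
    }
    if (is.null(wts) || length(wts) < 2) {
      reason[i] <- "fewer than two group-pen weights"
    }
  }

  list(
    eligible = roster$calf_id[is.na(reason)],
    exclusions = data.frame(
      calf_id = roster$calf_id[!is.na(reason)],
      phase = rep("G2E", sum(!is.na(reason))),
      reason = reason[!is.na(reason)],
      stringsAsFactors = FALSE
    )
  )
}
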