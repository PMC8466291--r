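#' Interval daily liveweight gain
#'
#' DLWG over a phase with exactly two weighings: weight gain divided by the
#' number of days between them. Used for the individual-hutch (B2G) phase,
#' where only a birth weight and a leaving-hutch weight exist.
#'
#' @param weight_start,weight_end weights, kg.
#' @param days elapsed whole days (> 0).
#' @return DLWG in kg/d.
#' @export
dlwg_interval <- function(weight_start, weight_end, days) {
  if (any(days <= 0)) stop("dlwg_interval: days must be positive")
  (weight_end - weight_start) / days
}

#' Slope daily liveweight gain
#'
#' DLWG for a phase with repeated weighings: the ordinary least-squares
#' slope of weight (kg) on age (days), which accommodates a changing rate of
#' gain across the phase. Used for the group-pen (G2E) phase. On exactly two
#' points the slope reduces to the interval rate.
#'
#' @param age_days ages at weighing, days (at least two distinct values).
#' @param weight weights, kg.
#' @return slope in kg/d.
#' @export
dlwg_slope <- function(age_days, weight) {
  if (length(age_days) < 2 || length(weight) != length(age_days)) {
    stop("dlwg_slope: need at least two (age, weight) points")
  }
  if (length(unique(age_days)) < 2) {
    stop("dlwg_slope: all ages identical; slope undefined")
  }
  unname(stats::coef(stats::lm(weight ~ age_days))[2])
}

#' Average daily calf-milk-replacer intake
#'
#' Total CMR mass consumed over the phase divided by the number of days from
#' pen entry to the last measurement day. An empty record set is zero
#' consumption, not missing data (missingness is handled by the eligibility
#' filter).
#'
#' @param cmr_mass daily CMR masses, g.
#' @param n_days phase length in days (> 0).
#' @return mean intake in g/d.
#' @export
avg_daily_cmr <- function(cmr_mass, n_days) {
  if (n_days <= 0) stop("avg_daily_cmr: n_days must be positive")
  sum(cmr_mass) / n_days
}

#' CMR mass from reconstituted milk volume
#'
#' Milk replacer is reconstituted at a weight-per-volume concentration:
#' c% means c * 10 grams of powder per litre of mixed milk, so 6 L/d at 15%
#' is 900 g/d of powder.
#'
#' @param volume_l milk volume, litres/day (>= 0).
#' @param concentration_pct w/v concentration, percent, in (0, 100\].
#' @return CMR mass in g/d.
#' @export
cmr_mass_from_volume <- function(volume_l, concentration_pct) {
  if (any(concentration_pct <= 0 | concentration_pct > 100)) {
    stop("cmr_mass_from_volume: concentration must lie in (0, 100]")
  }
  if (any(volume_l < 0)) stop("cmr_mass_from_volume: volume must be >= 0")
  volume_l * concentration_pct * 10
}
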