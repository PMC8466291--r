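#' Age-dependent lower critical temperature schedule
#'
#' The simplified LCT schedule used for exposure scoring: 15 degrees C at
#' birth (day 0), declining linearly with age. The default decline of
#' 0.5 degrees C per day reflects the rapid early development of
#' thermoregulatory capacity in calves. An optional floor stops the decline;
#' none is applied by default because the study horizon ends around day
#' 30-32, where the schedule is still near 0 degrees C.
#'
#' @param lct_at_birth LCT on day 0, degrees C.
#' @param daily_decline decline per day of age, degrees C/day (>= 0).
#' @param floor optional lower bound, degrees C.
#' @return an object of class `age_lct_schedule`.
#' @export
age_lct_schedule <- function(lct_at_birth = 15, daily_decline = 0.5,
                             floor = NULL) {
  stopifnot(daily_decline >= 0)
  structure(list(lct_at_birth = lct_at_birth, daily_decline = daily_decline,
                 floor = floor),
            class = "age_lct_schedule")
}

#' Lower critical temperature for a given age
#'
#' @param age_days age in whole days (>= 0); vectorised.
#' @param schedule an [age_lct_schedule()].
#' @return LCT in degrees C.
#' @examples
#' lct_for_age(0)   # 15
#' lct_for_age(10)  # 10
#' @export
lct_for_age <- function(age_days, schedule = age_lct_schedule()) {
  if (any(age_days < 0)) stop("lct_for_age: age must be non-negative")
  out <- schedule$lct_at_birth - schedule$daily_decline * age_days
  if (!is.null(schedule$floor)) out <- pmax(out, schedule$floor)
  out
}

#' Physiological lower critical temperature
#'
#' The heat-balance definition of the LCT:
#' \deqn{T_{lc} = (T_r + H'_{e,min} I_e) - H_{min}(I_t + I_e)}
#' with rectal temperature \eqn{T_r} (degrees C), external (coat) insulation
#' \eqn{I_e} and tissue insulation \eqn{I_t} (degrees C m^2/W), minimum
#' evaporative heat loss \eqn{H'_{e,min}} and thermoneutral heat production
#' \eqn{H_{min}} (W/m^2). Better insulation or higher heat production lowers
#' the temperature at which extra metabolic heat is needed.
#'
#' This definition is provided for reference and sensitivity work; the
#' exposure pipeline uses the simplified age schedule, which is the form the
#' study applied per calf-day.
#'
#' @param rectal_temp \eqn{T_r}, degrees C.
#' @param external_insulation \eqn{I_e}, degrees C m^2/W (>= 0).
#' @param min_evaporative_heat_loss \eqn{H'_{e,min}}, W/m^2 (>= 0).
#' @param thermoneutral_heat_production \eqn{H_{min}}, W/m^2 (>= 0).
#' @param tissue_insulation \eqn{I_t}, degrees C m^2/W (>= 0).
#' @return \eqn{T_{lc}} in degrees C.
#' @export
physiological_lct <- function(rectal_temp, external_insulation,
                              min_evaporative_heat_loss,
                              thermoneutral_heat_production,
                              tissue_insulation) {
  stopifnot(external_insulation >= 0, tissue_insulation >= 0,
            min_evaporative_heat_loss >= 0,
            thermoneutral_heat_production >= 0)
  (rectal_temp + min_evaporative_heat_loss * external_insulation) -
    thermoneutral_heat_production * (tissue_insulation + external_insulation)
}

#' Exposure category scheme
#'
#' A set of four ordered, non-overlapping intervals on \[0, 1\] with
#' two-decimal boundaries, used to categorise exposure proportions.
#'
#' @param phase phase label ("B2G" or "G2E").
#' @param lower,upper interval bounds (inclusive), two-decimal values.
#' @param labels category labels, reference level first.
#' @return an object of class `category_scheme`.
#' @seealso [b2g_scheme()], [g2e_scheme()]
#' @export
category_scheme <- function(phase, lower, upper, labels) {
  stopifnot(length(lower) == length(upper), length(labels) == length(lower),
            all(lower <= upper), !is.unsorted(lower))
  if (any(utils::head(upper, -1) >= lower[-1])) {
    stop("category_scheme: intervals must not overlap")
  }
  structure(list(phase = phase, lower = lower, upper = upper,
                 labels = labels),
            class = "category_scheme")
}

#' Individual-hutch (B2G) exposure quartile scheme
#'
#' Quartile boundaries of the proportion of hours below LCT while
#' individually housed: <=0.32, 0.33-0.58, 0.59-0.96, >=0.97.
#' @return a [category_scheme()].
#' @export
b2g_scheme <- function() {
  category_scheme("B2G",
                  lower = c(0, 0.33, 0.59, 0.97),
                  upper = c(0.32, 0.58, 0.96, 1),
                  labels = c("<=0.32", "0.33-0.58", "0.59-0.96", ">=0.97"))
}

#' Group-pen (G2E) exposure quartile scheme
#'
#' Quartile boundaries for the group-housing phase: <=0.01, 0.02-0.06,
#' 0.07-0.27, >=0.28.
#' @return a [category_scheme()].
#' @export
g2e_scheme <- function() {
  category_scheme("G2E",
                  lower = c(0, 0.02, 0.07, 0.28),
                  upper = c(0.01, 0.06, 0.27, 1),
                  labels = c("<=0.01", "0.02-0.06", "0.07-0.27", ">=0.28"))
}

#' Assign an exposure proportion to its category
#'
#' The printed interval boundaries are two-decimal values, so the proportion
#' is rounded half-up to two decimals before matching; this closes the gaps
#' between printed cut-points (0.325 rounds to 0.33 and falls in the second
#' interval).
#'
#' @param proportion numeric in \[0, 1\]; vectorised.
#' @param scheme a [category_scheme()].
#' @return factor with the scheme's labels (reference level first).
#' @export
categorise_exposure <- function(proportion, scheme) {
  if (any(proportion < 0 | proportion > 1)) {
    stop("categorise_exposure: proportion must lie in [0, 1]")
  }
  r <- round_half_up(proportion, 2)
  idx <- vapply(r, function(x) {
    i <- which(x >= scheme$lower & x <= scheme$upper)
    if (length(i) != 1) stop("categorise_exposure: value ", x,
                             " matches ", length(i), " intervals")
    i
  }, integer(1))
  factor(scheme$labels[idx], levels = scheme$labels)
}

#' Proportion of phase hours spent below the age-related LCT
#'
#' For every available climate hour in `[window_start, window_end)` the
#' calf's age in whole days (24-h anniversaries of the birth timestamp) sets
#' its LCT for that hour; the hour counts as exposed iff the effective
#' temperature is strictly below the LCT ("below" is strict: an hour exactly
#' at the LCT is not exposed). The proportion is exposed hours over
#' available hours, so hours missing from the climate series drop out of
#' both numerator and denominator.
#'
#' @param birth calf birth datetime (POSIXct).
#' @param window_start,window_end phase window; `window_start >= birth`,
#'   `window_end > window_start`. Hours are counted by their starting stamp,
#'   half-open on the right.
#' @param et effective-temperature series from [hourly_et_series()].
#' @param schedule an [age_lct_schedule()].
#' @param scheme optional [category_scheme()]; when given, the summary
#'   includes the quartile category.
#' @param calf_id,phase identifiers carried into the summary.
#' @return one-row data frame: calf_id, phase, hours_below, total_hours,
#'   proportion, category.
#' @export
exposure_proportion <- function(birth, window_start, window_end, et,
                                schedule = age_lct_schedule(),
                                scheme = NULL,
                                calf_id = NA_character_,
                                phase = NA_character_) {
  if (window_start < birth) stop("exposure_proportion: window starts before birth")
  if (window_end <= window_start) stop("exposure_proportion: empty window")
  cnt <- exposure_counts(as.numeric(birth), as.numeric(window_start),
                         as.numeric(window_end), as.numeric(et$timestamp),
                         et$effective_temp, schedule)
  n <- cnt[2]
  if (n == 0) {
    stop("exposure_proportion: no climate hours available in window for calf ",
         calf_id)
  }
  prop <- cnt[1] / n
  data.frame(
    calf_id = calf_id,
    phase = phase %||% NA_character_,
    hours_below = cnt[1],
    total_hours = n,
    proportion = prop,
    category = if (is.null(scheme)) NA_character_ else
      as.character(categorise_exposure(prop, scheme)),
    stringsAsFactors = FALSE
  )
}

# Count (exposed, available) hours in [start, end) against the age schedule,
# on numeric (POSIX seconds) inputs. The series must be sorted ascending;
# stamps are whole seconds, so a half-second offset makes findInterval
# honour the half-open window exactly.
exposure_counts <- function(birth_n, start_n, end_n, tsn, etv, schedule) {
  lo <- findInterval(start_n - 0.5, tsn) + 1L
  hi <- findInterval(end_n - 0.5, tsn)
  if (hi < lo) return(c(0L, 0L))
  idx <- lo:hi
  age <- floor((tsn[idx] - birth_n) / 86400)
  below <- etv[idx] < lct_for_age(age, schedule)
  c(sum(below), length(idx))
}

# Vectorised exposure over many calves against one ET series; returns a
# data frame of hours_below, total_hours, proportion (no categories).
exposure_many <- function(birth, start, end, et, schedule) {
  tsn <- as.numeric(et$timestamp)
  etv <- et$effective_temp
  out <- vapply(seq_along(birth), function(i) {
    exposure_counts(as.numeric(birth[i]), as.numeric(start[i]),
                    as.numeric(end[i]), tsn, etv, schedule)
  }, numeric(2))
  if (any(out[2, ] == 0)) {
    stop("exposure: no climate hours available for calf index ",
         paste(which(out[2, ] == 0), collapse = ", "))
  }
  data.frame(hours_below = out[1, ], total_hours = out[2, ],
             proportion = out[1, ] / out[2, ])
}
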