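#' Read a study dataset from a directory of CSV files
#'
#' Expects the five files written by [generate_study()] (climate.csv,
#' roster.csv, weights.csv, health.csv, milk.csv) with ISO-8601 timestamps.
#'
#' @param dir directory containing the study CSVs.
#' @param dialect climate column dialect, see [climate_dialect()].
#' @return list of data frames: climate, roster, weights, health, milk.
#' @export
read_study <- function(dir, dialect = climate_dialect()) {
  need <- c("climate.csv", "roster.csv", "weights.csv", "health.csv",
            "milk.csv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing)) {
    stop("read_study: missing file(s) in ", dir, ": ",
         paste(missing, collapse = ", "))
  }
  ts <- function(x) as.POSIXct(x, tz = "UTC",
                               tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                              "%Y-%m-%d %H:%M:%S"))
  climate <- read_climate(file.path(dir, "climate.csv"), dialect)$records
  roster <- utils::read.csv(file.path(dir, "roster.csv"),
                            stringsAsFactors = FALSE)
  roster$birth_datetime <- ts(roster$birth_datetime)
  roster$hutch_exit_datetime <- ts(roster$hutch_exit_datetime)
  for (col in c("sex", "breed_class", "parity_class", "calving_ease",
                "treated_b2g", "treated_g2e")) {
    roster[[col]] <- factor(roster[[col]])
  }
  weights <- utils::read.csv(file.path(dir, "weights.csv"),
                             stringsAsFactors = FALSE)
  weights$datetime <- ts(weights$datetime)
  health <- utils::read.csv(file.path(dir, "health.csv"),
                            stringsAsFactors = FALSE)
  health$datetime <- ts(health$datetime)
  milk <- utils::read.csv(file.path(dir, "milk.csv"),
                          stringsAsFactors = FALSE)
  milk$date <- as.Date(milk$date)
  list(climate = climate, roster = roster, weights = weights,
       health = health, milk = milk)
}

factor_with <- function(x, levels) factor(as.character(x), levels = levels)

#' Assemble the individual-hutch (B2G) analysis table
#'
#' Applies the B2G eligibility filter, computes each eligible calf's
#' exposure proportion and quartile category over its hutch window (birth
#' to hutch exit) from the climate series, and its interval DLWG.
#'
#' @param study list as returned by [read_study()] (climate, roster, ...)
#'   with roster column `lh_weight` (leaving-hutch weight) either present or
#'   derivable; when absent it is reconstructed from the first group-pen
#'   principle and must be supplied. [generate_cohort()] bundles can be used
#'   directly after [as_study()].
#' @param schedule an [age_lct_schedule()].
#' @param scheme a [category_scheme()] for the hutch phase.
#' @return list with `data` (one row per eligible calf) and `exclusions`.
#' @export
assemble_b2g <- function(study, schedule = age_lct_schedule(),
                         scheme = b2g_scheme()) {
  et <- hourly_et_series(study$climate)
  flt <- filter_b2g(study$roster)
  roster <- study$roster[study$roster$calf_id %in% flt$eligible, ,
                         drop = FALSE]
  if (!"lh_weight" %in% names(roster)) {
    stop("assemble_b2g: roster must carry the leaving-hutch weight ",
         "(column 'lh_weight')")
  }
  exit_age <- whole_days(roster$birth_datetime, roster$hutch_exit_datetime)
  ex <- exposure_many(roster$birth_datetime, roster$birth_datetime,
                      roster$hutch_exit_datetime, et, schedule)
  data <- data.frame(
    calf_id = roster$calf_id,
    dlwg = dlwg_interval(roster$birth_weight, roster$lh_weight, exit_age),
    proportion = ex$proportion,
    category = categorise_exposure(ex$proportion, scheme),
    hours_below = ex$hours_below,
    total_hours = ex$total_hours,
    birth_weight = roster$birth_weight,
    exit_age = exit_age,
    sex = roster$sex, breed_class = roster$breed_class,
    parity_class = roster$parity_class, calving_ease = roster$calving_ease,
    season = season_of_birth(roster$birth_datetime),
    treated_b2g = roster$treated_b2g,
    stringsAsFactors = FALSE
  )
  list(data = data, exclusions = flt$exclusions)
}

#' Assemble the group-pen (G2E) analysis table
#'
#' Applies the G2E eligibility filter on top of the B2G filter, then for
#' each eligible calf computes its growth slope (OLS of weight on age over
#' the group-pen weighings), average daily CMR intake from pen entry to the
#' last weighing, ever-signs-of-disease flag from the Wisconsin
#' assessments, and exposure over the pen-entry-to-last-weighing window.
#'
#' @param study list as returned by [read_study()].
#' @inheritParams assemble_b2g
#' @return list with `data` and `exclusions` (both phases' exclusions).
#' @export
assemble_g2e <- function(study, schedule = age_lct_schedule(),
                         scheme = g2e_scheme()) {
  et <- hourly_et_series(study$climate)
  flt1 <- filter_b2g(study$roster)
  flt2 <- filter_g2e(flt1$eligible, study$roster, study$weights, study$milk)
  roster <- study$roster[study$roster$calf_id %in% flt2$eligible, ,
                         drop = FALSE]
  wt <- split(study$weights, study$weights$calf_id)
  mk <- split(study$milk, study$milk$calf_id)
  he <- split(study$health, study$health$calf_id)
  nr <- nrow(roster)
  dlwg <- numeric(nr); n_weighings <- integer(nr); cmr <- numeric(nr)
  signs <- character(nr); last_weigh_n <- numeric(nr)
  entry_weight <- numeric(nr); end_weight <- numeric(nr)
  for (i in seq_len(nr)) {
    r <- roster[i, ]
    w <- wt[[r$calf_id]]
    w <- w[order(w$datetime), ]
    age_frac <- as.numeric(difftime(w$datetime, r$birth_datetime,
                                    units = "days"))
    last_weigh <- max(w$datetime)
    entry_day <- as.Date(r$hutch_exit_datetime, tz = "UTC")
    n_days <- as.integer(as.Date(last_weigh, tz = "UTC") - entry_day) + 1L
    m <- mk[[r$calf_id]]
    m <- m[m$date >= entry_day & m$date <= as.Date(last_weigh, tz = "UTC"), ]
    h <- he[[r$calf_id]]
    status <- classify_health(h$rectal_score, h$overall_score)
    dlwg[i] <- dlwg_slope(age_frac, w$weight)
    n_weighings[i] <- nrow(w)
    cmr[i] <- avg_daily_cmr(m$cmr_mass, n_days)
    signs[i] <- as.character(signs_of_disease_ever(status))
    last_weigh_n[i] <- as.numeric(last_weigh)
    entry_weight[i] <- w$weight[1]
    end_weight[i] <- w$weight[nrow(w)]
  }
  last_weigh <- as.POSIXct(last_weigh_n, tz = "UTC", origin = "1970-01-01")
  ex <- exposure_many(roster$birth_datetime, roster$hutch_exit_datetime,
                      last_weigh, et, schedule)
  data <- data.frame(
    calf_id = roster$calf_id,
    dlwg = dlwg,
    n_weighings = n_weighings,
    proportion = ex$proportion,
    category = categorise_exposure(ex$proportion, scheme),
    entry_age = whole_days(roster$birth_datetime,
                           roster$hutch_exit_datetime),
    end_age = whole_days(roster$birth_datetime, last_weigh),
    cmr_intake = cmr,
    signs_disease = factor(signs, levels = c("no", "yes")),
    birth_weight = roster$birth_weight,
    sex = roster$sex, breed_class = roster$breed_class,
    parity_class = roster$parity_class, calving_ease = roster$calving_ease,
    season = season_of_birth(roster$birth_datetime),
    treated_b2g = roster$treated_b2g, treated_g2e = roster$treated_g2e,
    group_id = factor(roster$group_id), pen_id = factor(roster$pen_id),
    feeder_system = factor(roster$feeder_system),
    entry_weight = entry_weight, end_weight = end_weight,
    stringsAsFactors = FALSE
  )
  list(data = data,
       exclusions = rbind(flt1$exclusions, flt2$exclusions))
}

#' Turn a generated cohort bundle into a study list
#'
#' @param bundle result of [generate_cohort()].
#' @param climate the climate series the bundle was generated over.
#' @return list shaped like [read_study()] output.
#' @export
as_study <- function(bundle, climate) {
  list(climate = climate, roster = bundle$roster, weights = bundle$weights,
       health = bundle$health, milk = bundle$milk)
}

b2g_terms <- function() {
  c("category", "birth_weight", "exit_age", "sex", "breed_class",
    "parity_class", "calving_ease", "season", "treated_b2g")
}

g2e_terms <- function() {
  c("category", "entry_age", "cmr_intake", "birth_weight", "sex",
    "breed_class", "parity_class", "calving_ease", "season",
    "treated_b2g", "treated_g2e", "signs_disease")
}

#' Run the full B2G analysis
#'
#' Assembles the B2G table, screens all candidate variables univariably at
#' `screen_alpha`, backward-eliminates to the final model at `retain_alpha`,
#' and computes Tukey contrasts for every retained factor with three or
#' more levels.
#'
#' @param study study list (see [read_study()] / [as_study()]).
#' @param schedule,scheme exposure definitions.
#' @param screen_alpha,retain_alpha selection thresholds.
#' @return list: data, exclusions, screening, result ([backward_select()]
#'   output), contrasts (named list of Tukey tables).
#' @export
run_b2g <- function(study, schedule = age_lct_schedule(),
                    scheme = b2g_scheme(),
                    screen_alpha = 0.20, retain_alpha = 0.05) {
  asm <- assemble_b2g(study, schedule, scheme)
  spec <- model_spec("dlwg", b2g_terms(), random = NULL,
                     screen_alpha = screen_alpha,
                     retain_alpha = retain_alpha)
  screening <- univariable_screen(asm$data, spec)
  survivors <- screening$term[screening$kept]
  result <- backward_select(asm$data, survivors, spec)
  contrasts <- posthoc_for_factors(result, asm$data)
  list(data = asm$data, exclusions = asm$exclusions,
       screening = screening, result = result, contrasts = contrasts)
}

#' Run the full G2E analysis
#'
#' As [run_b2g()], with the group-pen candidate set, the slope DLWG, and
#' crossed random intercepts for rearing group, pen and feeder system.
#'
#' @inheritParams run_b2g
#' @return list: data, exclusions, screening, result, contrasts.
#' @export
run_g2e <- function(study, schedule = age_lct_schedule(),
                    scheme = g2e_scheme(),
                    screen_alpha = 0.20, retain_alpha = 0.05) {
  asm <- assemble_g2e(study, schedule, scheme)
  spec <- model_spec("dlwg", g2e_terms(),
                     random = c("group_id", "pen_id", "feeder_system"),
                     screen_alpha = screen_alpha,
                     retain_alpha = retain_alpha)
  screening <- univariable_screen(asm$data, spec)
  survivors <- screening$term[screening$kept]
  result <- backward_select(asm$data, survivors, spec)
  contrasts <- posthoc_for_factors(result, asm$data)
  list(data = asm$data, exclusions = asm$exclusions,
       screening = screening, result = result, contrasts = contrasts)
}

posthoc_for_factors <- function(result, data) {
  fac <- Filter(function(tm) {
    x <- data[[tm]]
    (is.factor(x) || is.character(x)) && nlevels(droplevels(factor(x))) >= 3
  }, result$terms)
  stats::setNames(lapply(fac, function(tm) tukey_posthoc(result, tm)), fac)
}

descriptive_stats <- function(x) {
  x <- x[!is.na(x)]
  data.frame(mean = mean(x), sd = stats::sd(x), median = stats::median(x),
             min = min(x), max = max(x))
}

#' Descriptive summary tables
#'
#' Means, SDs, medians and ranges of the calf-level parameters per phase
#' and of the hourly climate parameters, shaped like the study's
#' descriptive tables.
#'
#' @param b2g_data,g2e_data analysis tables from [assemble_b2g()] /
#'   [assemble_g2e()] (either may be NULL).
#' @param climate hourly climate data frame (optional).
#' @return list of data frames: `calves`, `climate`.
#' @export
report_descriptives <- function(b2g_data = NULL, g2e_data = NULL,
                                climate = NULL) {
  calves <- NULL
  add <- function(tbl, phase, parameter, x) {
    rbind(tbl, cbind(data.frame(phase = phase, parameter = parameter),
                     descriptive_stats(x)))
  }
  if (!is.null(b2g_data)) {
    calves <- add(calves, "B2G", "Birth weight (kg)", b2g_data$birth_weight)
    calves <- add(calves, "B2G", "Age leaving individual hutch (d)",
                  b2g_data$exit_age)
    calves <- add(calves, "B2G", "DLWG (kg/d)", b2g_data$dlwg)
    calves <- add(calves, "B2G", "Proportion of hours below LCT",
                  b2g_data$proportion)
  }
  if (!is.null(g2e_data)) {
    calves <- add(calves, "G2E", "Birth weight (kg)", g2e_data$birth_weight)
    calves <- add(calves, "G2E", "Group pen entry age (d)",
                  g2e_data$entry_age)
    calves <- add(calves, "G2E", "End age (d)", g2e_data$end_age)
    calves <- add(calves, "G2E", "DLWG (kg/d)", g2e_data$dlwg)
    calves <- add(calves, "G2E", "Average CMR intake (g/d)",
                  g2e_data$cmr_intake)
    calves <- add(calves, "G2E", "Proportion of hours below LCT",
                  g2e_data$proportion)
  }
  clim <- NULL
  if (!is.null(climate)) {
    et <- hourly_et_series(climate)
    addc <- function(tbl, parameter, x) {
      rbind(tbl, cbind(data.frame(parameter = parameter),
                       descriptive_stats(x)))
    }
    clim <- addc(clim, "Air temperature (C)", climate$air_temp)
    clim <- addc(clim, "Wind speed (m/s)", climate$wind_speed)
    clim <- addc(clim, "Relative humidity (%)", climate$rel_humidity)
    clim <- addc(clim, "Effective temperature (C)", et$effective_temp)
  }
  list(calves = calves, climate = clim)
}

#' Write analysis outputs to disk
#'
#' Writes the analysis table, the model coefficient table, the elimination
#' trace, Tukey contrasts and the exclusion log as CSV, plus a JSON
#' summary (screening p-values, retained terms, random-effect variances).
#'
#' @param run output of [run_b2g()] or [run_g2e()].
#' @param dir output directory.
#' @param prefix file name prefix (e.g. "b2g").
#' @return invisibly, the paths written.
#' @export
write_run <- function(run, dir, prefix) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(name) file.path(dir, paste0(prefix, "_", name))
  utils::write.csv(run$data, p("data.csv"), row.names = FALSE)
  utils::write.csv(run$result$coef_table, p("model.csv"), row.names = FALSE)
  utils::write.csv(run$result$trace, p("trace.csv"), row.names = FALSE)
  utils::write.csv(run$exclusions, p("exclusions.csv"), row.names = FALSE)
  utils::write.csv(run$screening, p("screening.csv"), row.names = FALSE)
  for (nm in names(run$contrasts)) {
    utils::write.csv(run$contrasts[[nm]],
                     p(paste0("tukey_", nm, ".csv")), row.names = FALSE)
  }
  summary <- list(
    n = run$result$n,
    retained = run$result$terms,
    screening = run$screening,
    random_variances = as.list(run$result$random_variances %||% list()),
    singular = run$result$singular
  )
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}
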