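#' Configuration for the synthetic hourly climate generator
#'
#' Hourly air temperature is an annual sinusoid plus a diurnal sinusoid plus
#' Gaussian noise; relative humidity is Gaussian clipped to the observed
#' range; wind speed is zero-inflated exponential clipped at a maximum. The
#' defaults are calibrated so that a year-long series matches the marginal
#' moments observed inside naturally ventilated Scottish calf housing: air
#' temperature mean 10.3, SD 5.2 degrees C; RH mean 81.1, SD 11.3 %, range
#' 27-99; wind mostly calm (median 0, mean 0.2 m/s, max 3 m/s).
#'
#' @param start first day of the series (Date or string).
#' @param n_days number of days (24 hourly records each).
#' @param mean_temp annual mean air temperature, degrees C.
#' @param seasonal_amplitude amplitude of the annual cycle, degrees C.
#' @param warmest_doy day of year at the seasonal peak.
#' @param diurnal_amplitude amplitude of the within-day cycle, degrees C
#'   (peak at 15:00, trough at 03:00).
#' @param noise_sd SD of hourly temperature noise, degrees C.
#' @param rh_mean,rh_sd,rh_min,rh_max relative humidity parameters, %.
#' @param wind_zero_prob probability of a calm (0 m/s) hour.
#' @param wind_mean mean of the exponential positive part, m/s.
#' @param wind_max clip for wind speed, m/s.
#' @param seed RNG seed for this series.
#' @return an object of class `climate_gen_config`.
#' @export
climate_gen_config <- function(start = "2018-01-01", n_days = 410,
                               mean_temp = 10.3, seasonal_amplitude = 6,
                               warmest_doy = 200, diurnal_amplitude = 3,
                               noise_sd = 2,
                               rh_mean = 81.1, rh_sd = 11.3,
                               rh_min = 27, rh_max = 99,
                               wind_zero_prob = 0.75, wind_mean = 0.8,
                               wind_max = 3, seed = 1) {
  stopifnot(n_days > 0, rh_min < rh_max,
            wind_zero_prob >= 0, wind_zero_prob <= 1)
  structure(as.list(environment()), class = "climate_gen_config")
}

#' Generate a synthetic hourly climate series
#'
#' @param config a [climate_gen_config()].
#' @return data frame of hourly records: timestamp (start of hour, UTC),
#'   air_temp, rel_humidity, wind_speed.
#' @export
generate_climate <- function(config = climate_gen_config()) {
  if (config$n_days <= 0) stop("generate_climate: n_days must be positive")
  start <- as.POSIXct(paste(config$start, "00:00:00"), tz = "UTC")
  n <- config$n_days * 24L
  ts <- start + 3600 * (seq_len(n) - 1L)
  # fractional day-of-year and hour-of-day, arithmetic on the hourly grid
  doy0 <- as.numeric(format(start, "%j"))
  doy <- doy0 + (seq_len(n) - 1L) / 24
  hour <- (seq_len(n) - 1L) %% 24L

  seed_substream(config$seed, "climate-temp")
  temp <- config$mean_temp +
    config$seasonal_amplitude * cos(2 * pi * (doy - config$warmest_doy) / 365.25) +
    config$diurnal_amplitude * cos(2 * pi * (hour - 15) / 24) +
    stats::rnorm(n, 0, config$noise_sd)

  seed_substream(config$seed, "climate-rh")
  rh <- pmin(config$rh_max,
             pmax(config$rh_min, stats::rnorm(n, config$rh_mean, config$rh_sd)))

  seed_substream(config$seed, "climate-wind")
  calm <- stats::runif(n) < config$wind_zero_prob
  wind <- ifelse(calm, 0,
                 pmin(config$wind_max, stats::rexp(n, 1 / config$wind_mean)))

  data.frame(timestamp = ts, air_temp = temp, rel_humidity = rh,
             wind_speed = wind)
}

#' Configuration for the synthetic calf cohort generator
#'
#' Defaults reproduce the statistical structure of the study cohort: birth
#' weights ~ N(43.2, 6.2^2) truncated to \[31, 67\] kg; hutch-exit ages 6-14
#' days with the observed frequency profile; covariate mixes from the
#' observed counts; individual-hutch DLWG generated from the final B2G
#' model's linear predictor (intercept 0.537; exposure-category effects 0,
#' -0.061, -0.157, -0.199; -0.018 per kg birth weight; +0.028 per day of
#' exit age) with residual SD 0.30 kg/d; group-pen growth slopes generated
#' from the final G2E predictor (entry-age effect 0.009/d, CMR effect
#' 0.001 per g/d, near-null category effects) with random intercepts for
#' rearing group, pen and feeder system (SD 0.05 kg/d each); average CMR
#' intake ~ N(890.5, 152.3^2) truncated to \[489.8, 1223.7\] g/d.
#'
#' The B2G exposure category is never drawn directly: it is computed from
#' the supplied climate through the effective-temperature / LCT chain, so
#' recovering the generating coefficients exercises the whole pipeline.
#'
#' The G2E intercept is not estimable from published summaries; the default
#' -0.36 kg/d reproduces the observed mean G2E DLWG of 0.60 kg/d at the
#' cohort means.
#'
#' @param n_calves cohort size.
#' @param birth_start,birth_span_days births are uniform over this window.
#' @param birth_weight_mean,birth_weight_sd,birth_weight_range kg.
#' @param exit_age_probs named probabilities over exit ages 6-14 d.
#' @param p_female,p_dairy,p_multiparous,p_unassisted covariate mixes.
#' @param p_treat_b2g,p_treat_g2e phase treatment incidences.
#' @param status_probs per-assessment probabilities of Healthy,
#'   Intermediate, Diseased health status.
#' @param b2g_coefs named generating coefficients: intercept, cat2, cat3,
#'   cat4 (second to fourth exposure category vs reference), birth_weight,
#'   exit_age.
#' @param b2g_resid_sd calf-level residual SD of B2G DLWG, kg/d.
#' @param g2e_coefs named generating coefficients: intercept, cat2, cat3,
#'   cat4, entry_age, cmr.
#' @param g2e_resid_sd calf-level residual SD of the G2E growth slope, kg/d.
#' @param ranef_sd named SDs of the group/pen/feeder random intercepts, kg/d.
#' @param group_size calves per rearing group (filled in entry order).
#' @param n_pens number of group igloo pens.
#' @param feeder_split fraction of calves (entry order) on the first feeder.
#' @param end_age_mean,end_age_sd,end_age_range age at last weighing, days.
#' @param cmr_mean,cmr_sd,cmr_range per-calf average CMR intake, g/d.
#' @param cmr_daily_sd day-to-day SD around a calf's average intake, g.
#' @param milk_concentration_pct w/v reconstitution concentration.
#' @param weigh_noise_sd weighing measurement error SD, kg.
#' @param schedule the [age_lct_schedule()] used for true exposure.
#' @param exclusion_profile "none" for a fully eligible cohort; "study"
#'   additionally encodes the study's exclusion structure (1 missing birth
#'   weight, 27 late hutch exits; then 5 died, 1 sold, 3 returned to hutch,
#'   41 with incomplete milk data among the remainder).
#' @param seed RNG seed.
#' @return an object of class `cohort_gen_config`.
#' @export
cohort_gen_config <- function(
    n_calves = 271,
    birth_start = "2018-01-01", birth_span_days = 365,
    birth_weight_mean = 43.2, birth_weight_sd = 6.2,
    birth_weight_range = c(31, 67),
    exit_age_probs = c(`6` = 19, `7` = 52, `8` = 45, `9` = 45, `10` = 29,
                       `11` = 28, `12` = 27, `13` = 16, `14` = 10) / 271,
    p_female = 171 / 299, p_dairy = 226 / 299,
    p_multiparous = 190 / 299, p_unassisted = 263 / 299,
    p_treat_b2g = 37 / 271, p_treat_g2e = 95 / 221,
    status_probs = c(Healthy = 0.87, Intermediate = 0.04, Diseased = 0.09),
    b2g_coefs = c(intercept = 0.537, cat2 = -0.061, cat3 = -0.157,
                  cat4 = -0.199, birth_weight = -0.018, exit_age = 0.028),
    b2g_resid_sd = 0.30,
    g2e_coefs = c(intercept = -0.36, cat2 = -0.037, cat3 = -0.008,
                  cat4 = 0.002, entry_age = 0.009, cmr = 0.001),
    g2e_resid_sd = 0.15,
    ranef_sd = c(group = 0.05, pen = 0.05, feeder = 0.05),
    group_size = 12, n_pens = 8, feeder_split = 183 / 299,
    end_age_mean = 29.5, end_age_sd = 1.2, end_age_range = c(25, 32),
    cmr_mean = 890.5, cmr_sd = 152.3, cmr_range = c(489.8, 1223.7),
    cmr_daily_sd = 50, milk_concentration_pct = 15,
    weigh_noise_sd = 0.5,
    schedule = age_lct_schedule(),
    exclusion_profile = c("none", "study"),
    seed = 1) {
  exclusion_profile <- match.arg(exclusion_profile)
  stopifnot(abs(sum(exit_age_probs) - 1) < 1e-8,
            birth_weight_range[1] < birth_weight_range[2],
            all(ranef_sd >= 0), b2g_resid_sd >= 0, g2e_resid_sd >= 0,
            abs(sum(status_probs) - 1) < 1e-8)
  structure(as.list(environment()), class = "cohort_gen_config")
}

# Split (overall - rectal) over the four non-rectal components, each <= 3.
spread_components <- function(rest) {
  rest <- as.integer(rest)
  comp <- integer(4)
  for (j in 1:4) {
    comp[j] <- min(3L, rest)
    rest <- rest - comp[j]
  }
  comp
}

#' Generate a synthetic calf cohort over a climate series
#'
#' Samples births, birth weights, exit ages and covariates; computes each
#' calf's true individual-hutch exposure from the supplied climate through
#' the effective-temperature / LCT chain; draws B2G DLWG from the
#' generating linear predictor and derives the leaving-hutch weight; then
#' builds the group-pen phase (twice-weekly weighings on Mondays and
#' Thursdays, daily milk records, health assessments, random group / pen /
#' feeder intercepts) with weights following the generating growth slope
#' plus measurement noise. Fully reproducible from the config seed.
#'
#' @param config a [cohort_gen_config()].
#' @param climate hourly climate from [generate_climate()] (must cover every
#'   calf's window from birth to last weighing).
#' @param phases "both" (default) for the full record bundle, or "b2g" to
#'   stop after the individual-hutch phase (roster only; weights, health
#'   and milk are NULL). Substream seeding guarantees the B2G draws are
#'   identical either way.
#' @return list with `roster`, `weights`, `health`, `milk` data frames and
#'   `truth` (the generating coefficients, per-calf linear predictors,
#'   random-intercept draws, true exposures and slopes).
#' @export
generate_cohort <- function(config = cohort_gen_config(),
                            climate = generate_climate(),
                            phases = c("both", "b2g")) {
  phases <- match.arg(phases)
  n <- config$n_calves
  et <- hourly_et_series(climate)
  cover_end <- max(climate$timestamp) + 3600

  seed_substream(config$seed, "births")
  birth <- as.POSIXct(paste(config$birth_start, "00:00:00"), tz = "UTC") +
    round(stats::runif(n) * config$birth_span_days * 86400 / 60) * 60

  seed_substream(config$seed, "birthweight")
  bw <- truncnorm::rtruncnorm(n, config$birth_weight_range[1],
                              config$birth_weight_range[2],
                              config$birth_weight_mean, config$birth_weight_sd)

  seed_substream(config$seed, "exitage")
  exit_age <- as.integer(sample(names(config$exit_age_probs), n,
                                replace = TRUE, prob = config$exit_age_probs))

  seed_substream(config$seed, "covariates")
  sex <- factor(ifelse(stats::runif(n) < config$p_female, "female", "male"),
                levels = c("female", "male"))
  breed <- factor(ifelse(stats::runif(n) < config$p_dairy, "dairy",
                         "dairy-beef cross"),
                  levels = c("dairy", "dairy-beef cross"))
  parity <- factor(ifelse(stats::runif(n) < config$p_multiparous,
                          "multiparous", "primiparous"),
                   levels = c("primiparous", "multiparous"))
  ease <- factor(ifelse(stats::runif(n) < config$p_unassisted,
                        "unassisted", "assisted"),
                 levels = c("unassisted", "assisted"))
  treat_b2g <- factor(ifelse(stats::runif(n) < config$p_treat_b2g,
                             "yes", "no"), levels = c("no", "yes"))
  treat_g2e <- factor(ifelse(stats::runif(n) < config$p_treat_g2e,
                             "yes", "no"), levels = c("no", "yes"))

  # study exclusion structure: flags are deterministic given the substream
  missing_bw <- logical(n); died <- logical(n); sold <- logical(n)
  returned <- logical(n); milk_lost <- logical(n)
  if (config$exclusion_profile == "study") {
    stopifnot(n >= 78)
    seed_substream(config$seed, "exclusions")
    late <- sample(n, 28)
    exit_age[late[1:27]] <- sample(15:16, 27, replace = TRUE)
    missing_bw[late[28]] <- TRUE
    rest <- sample(setdiff(seq_len(n), late), 50)
    died[rest[1:5]] <- TRUE
    sold[rest[6]] <- TRUE
    returned[rest[7:9]] <- TRUE
    milk_lost[rest[10:50]] <- TRUE
  }

  exit_dt <- birth + exit_age * 86400
  if (any(exit_dt >= cover_end)) {
    stop("generate_cohort: climate series does not cover all hutch windows")
  }

  # true B2G exposure through the full climate -> ET -> LCT chain
  b2g_exp <- exposure_many(birth, birth, exit_dt, et, config$schedule)
  b2g_cat <- categorise_exposure(b2g_exp$proportion, b2g_scheme())

  cat_eff_b2g <- c(0, config$b2g_coefs[c("cat2", "cat3", "cat4")])
  lp_b2g <- config$b2g_coefs["intercept"] +
    cat_eff_b2g[as.integer(b2g_cat)] +
    config$b2g_coefs["birth_weight"] * bw +
    config$b2g_coefs["exit_age"] * exit_age
  seed_substream(config$seed, "b2g-resid")
  dlwg_b2g <- as.numeric(lp_b2g) + stats::rnorm(n, 0, config$b2g_resid_sd)
  lh_weight <- bw + dlwg_b2g * exit_age

  # group / pen / feeder allocation in entry order
  entry_rank <- rank(exit_dt, ties.method = "first")
  group_id <- ceiling(entry_rank / config$group_size)
  pen_id <- ((group_id - 1L) %% config$n_pens) + 1L
  feeder <- ifelse(entry_rank <= ceiling(config$feeder_split * n),
                   "HL100", "BioControl")
  n_groups <- max(group_id)
  seed_substream(config$seed, "ranef")
  u_group <- stats::rnorm(n_groups, 0, config$ranef_sd["group"])
  u_pen <- stats::rnorm(config$n_pens, 0, config$ranef_sd["pen"])
  u_feeder <- stats::setNames(stats::rnorm(2, 0, config$ranef_sd["feeder"]),
                              c("HL100", "BioControl"))

  roster <- data.frame(
    calf_id = sprintf("C%03d", seq_len(n)),
    birth_datetime = birth,
    sex = sex, breed_class = breed, parity_class = parity,
    calving_ease = ease,
    birth_weight = ifelse(missing_bw, NA_real_, bw),
    lh_weight = lh_weight,
    hutch_exit_datetime = exit_dt,
    pen_id = paste0("P", pen_id),
    group_id = sprintf("G%02d", group_id),
    feeder_system = feeder,
    died = died, sold = sold, returned_to_hutch = returned,
    treated_b2g = treat_b2g, treated_g2e = treat_g2e,
    stringsAsFactors = FALSE
  )
  truth_b2g <- list(
    b2g_coefs = config$b2g_coefs, g2e_coefs = config$g2e_coefs,
    b2g_category = b2g_cat, b2g_proportion = b2g_exp$proportion,
    dlwg_b2g = dlwg_b2g, lh_weight = lh_weight,
    u_group = u_group, u_pen = u_pen, u_feeder = u_feeder
  )
  if (phases == "b2g") {
    return(list(roster = roster, weights = NULL, health = NULL, milk = NULL,
                truth = truth_b2g))
  }

  # end of study: last weighing on or before the 24-h anniversary of end_age
  seed_substream(config$seed, "endage")
  end_age <- round(truncnorm::rtruncnorm(n, config$end_age_range[1],
                                         config$end_age_range[2],
                                         config$end_age_mean,
                                         config$end_age_sd))
  end_dt <- birth + end_age * 86400
  if (any(end_dt >= cover_end)) {
    stop("generate_cohort: climate series does not cover all group-pen windows")
  }

  # global recording days: Mondays and Thursdays, 13:00
  all_days <- seq(as.Date(min(climate$timestamp)),
                  as.Date(max(climate$timestamp)), by = "day")
  rec_days <- all_days[format(all_days, "%u") %in% c("1", "4")]
  rec_times <- as.POSIXct(paste(rec_days, "13:00:00"), tz = "UTC")

  weigh_times <- lapply(seq_len(n), function(i) {
    rec_times[rec_times > exit_dt[i] & rec_times <= end_dt[i]]
  })
  stopifnot(all(vapply(weigh_times, length, integer(1)) >= 2))
  last_weigh <- as.POSIXct(vapply(weigh_times, function(w) max(as.numeric(w)),
                                  numeric(1)), tz = "UTC", origin = "1970-01-01")

  # daily milk records from pen entry to last weighing (inclusive)
  milk_days <- lapply(seq_len(n), function(i) {
    seq(as.Date(exit_dt[i], tz = "UTC"), as.Date(last_weigh[i], tz = "UTC"),
        by = "day")
  })
  n_days_g2e <- vapply(milk_days, length, integer(1))
  seed_substream(config$seed, "cmr-mean")
  cmr_calf <- truncnorm::rtruncnorm(n, config$cmr_range[1],
                                    config$cmr_range[2],
                                    config$cmr_mean, config$cmr_sd)
  seed_substream(config$seed, "cmr-daily")
  daily_cmr <- lapply(seq_len(n), function(i) {
    pmax(0, cmr_calf[i] + stats::rnorm(n_days_g2e[i], 0, config$cmr_daily_sd))
  })
  mass <- unlist(daily_cmr)
  milk <- data.frame(
    calf_id = rep(sprintf("C%03d", seq_len(n)), n_days_g2e),
    date = as.Date(unlist(lapply(milk_days, as.numeric)),
                   origin = "1970-01-01"),
    cmr_mass = mass,
    milk_volume = mass / (config$milk_concentration_pct * 10),
    stringsAsFactors = FALSE)
  avg_cmr <- vapply(seq_len(n), function(i) {
    avg_daily_cmr(daily_cmr[[i]], n_days_g2e[i])
  }, numeric(1))

  # true G2E exposure over pen entry -> last weighing
  g2e_exp <- exposure_many(birth, exit_dt, last_weigh, et, config$schedule)
  g2e_cat <- categorise_exposure(g2e_exp$proportion, g2e_scheme())

  cat_eff_g2e <- c(0, config$g2e_coefs[c("cat2", "cat3", "cat4")])
  lp_g2e <- config$g2e_coefs["intercept"] +
    cat_eff_g2e[as.integer(g2e_cat)] +
    config$g2e_coefs["entry_age"] * exit_age +
    config$g2e_coefs["cmr"] * avg_cmr +
    u_group[group_id] + u_pen[pen_id] + u_feeder[feeder]
  seed_substream(config$seed, "g2e-resid")
  slope <- as.numeric(lp_g2e) + stats::rnorm(n, 0, config$g2e_resid_sd)

  seed_substream(config$seed, "weights")
  n_weigh <- vapply(weigh_times, length, integer(1))
  wt_id <- rep(sprintf("C%03d", seq_len(n)), n_weigh)
  wt_time <- as.POSIXct(unlist(lapply(weigh_times, as.numeric)),
                        tz = "UTC", origin = "1970-01-01")
  wt_age <- as.numeric(difftime(wt_time, rep(birth, n_weigh),
                                units = "days"))
  wt_val <- rep(lh_weight, n_weigh) +
    rep(slope, n_weigh) * (wt_age - rep(exit_age, n_weigh)) +
    stats::rnorm(length(wt_time), 0, config$weigh_noise_sd)
  weights <- data.frame(calf_id = wt_id, datetime = wt_time,
                        weight = wt_val,
                        weighing_number = unlist(lapply(n_weigh, seq_len)),
                        stringsAsFactors = FALSE)

  # health assessments: at hutch exit and on each recording day
  seed_substream(config$seed, "health")
  n_assess <- n_weigh + 1L
  he_id <- rep(sprintf("C%03d", seq_len(n)), n_assess)
  he_time <- as.POSIXct(
    unlist(lapply(seq_len(n), function(i) {
      c(as.numeric(exit_dt[i]), as.numeric(weigh_times[[i]]))
    })), tz = "UTC", origin = "1970-01-01")
  m <- length(he_time)
  st <- sample(names(config$status_probs), m, replace = TRUE,
               prob = config$status_probs)
  rectal <- integer(m); overall <- integer(m)
  healthy <- st == "Healthy"
  rectal[healthy] <- sample(0:2, sum(healthy), replace = TRUE,
                            prob = c(0.6, 0.3, 0.1))
  overall[healthy] <- rectal[healthy] +
    floor(stats::runif(sum(healthy)) * (4 - rectal[healthy]))
  inter <- st == "Intermediate"
  rectal[inter] <- sample(0:2, sum(inter), replace = TRUE)
  overall[inter] <- 4L
  dis <- st == "Diseased"
  febrile <- dis & stats::runif(m) < 0.5
  rectal[febrile] <- 3L
  overall[febrile] <- 3L + sample(0:9, sum(febrile), replace = TRUE)
  rest <- dis & !febrile
  rectal[rest] <- sample(0:2, sum(rest), replace = TRUE)
  overall[rest] <- sample(5:10, sum(rest), replace = TRUE)
  comp <- vapply(overall - rectal, spread_components, integer(4))
  health <- data.frame(calf_id = he_id, datetime = he_time,
                       rectal_score = rectal, ocular_score = comp[1, ],
                       nasal_score = comp[2, ], ear_score = comp[3, ],
                       cough_score = comp[4, ], overall_score = overall,
                       stringsAsFactors = FALSE)

  if (any(milk_lost)) {
    milk <- milk[!milk$calf_id %in% roster$calf_id[milk_lost], , drop = FALSE]
  }

  list(
    roster = roster, weights = weights, health = health, milk = milk,
    truth = c(truth_b2g, list(
      g2e_category = g2e_cat, g2e_proportion = g2e_exp$proportion,
      slope_g2e = slope, avg_cmr = avg_cmr, end_age = end_age
    ))
  )
}

#' Generate a complete on-disk synthetic study
#'
#' Writes the five CSV files the ingestion pipeline reads (climate, roster,
#' weights, health scores, milk intakes) for a seeded synthetic study.
#' Identical seeds and configs produce byte-identical files.
#'
#' @param seed master seed (overrides the seeds inside both configs).
#' @param dir output directory (created if needed).
#' @param climate_config a [climate_gen_config()].
#' @param cohort_config a [cohort_gen_config()].
#' @return invisibly, the list of file paths written.
#' @export
generate_study <- function(seed, dir,
                           climate_config = climate_gen_config(),
                           cohort_config = cohort_gen_config()) {
  climate_config$seed <- seed
  cohort_config$seed <- seed
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  climate <- generate_climate(climate_config)
  bundle <- generate_cohort(cohort_config, climate)

  fmt <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  paths <- list(
    climate = file.path(dir, "climate.csv"),
    roster = file.path(dir, "roster.csv"),
    weights = file.path(dir, "weights.csv"),
    health = file.path(dir, "health.csv"),
    milk = file.path(dir, "milk.csv")
  )
  cl <- climate; cl$timestamp <- fmt(cl$timestamp)
  utils::write.csv(cl, paths$climate, row.names = FALSE)
  ro <- bundle$roster
  ro$birth_datetime <- fmt(ro$birth_datetime)
  ro$hutch_exit_datetime <- fmt(ro$hutch_exit_datetime)
  utils::write.csv(ro, paths$roster, row.names = FALSE)
  wt <- bundle$weights; wt$datetime <- fmt(wt$datetime)
  utils::write.csv(wt, paths$weights, row.names = FALSE)
  he <- bundle$health; he$datetime <- fmt(he$datetime)
  utils::write.csv(he, paths$health, row.names = FALSE)
  mi <- bundle$milk; mi$date <- format(mi$date, "%Y-%m-%d")
  utils::write.csv(mi, paths$milk, row.names = FALSE)
  invisible(paths)
}
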