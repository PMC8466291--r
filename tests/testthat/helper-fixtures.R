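# Shared fixtures built in code: tiny climate series and an independent
# brute-force exposure oracle used by the property tests.

hour_seq <- function(start, n) {
  as.POSIXct(start, tz = "UTC") + 3600 * (seq_len(n) - 1)
}

constant_climate <- function(start = "2020-01-01 00:00:00", n = 24,
                             air_temp = 10, rh = 80, wind = 0) {
  data.frame(timestamp = hour_seq(start, n),
             air_temp = air_temp, rel_humidity = rh, wind_speed = wind)
}

et_series <- function(start, values) {
  data.frame(timestamp = hour_seq(start, length(values)),
             effective_temp = values)
}

write_climate_csv <- function(df, path = tempfile(fileext = ".csv")) {
  out <- df
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  write.csv(out, path, row.names = FALSE)
  path
}

# Hour-by-hour enumeration oracle, independent of exposure_proportion()
# internals: walks every hour stamp, derives the age and LCT explicitly,
# and counts strict below-LCT hours.
oracle_exposure <- function(birth, window_start, window_end, et,
                            lct_at_birth = 15, daily_decline = 0.5) {
  below <- 0L; total <- 0L
  for (k in seq_len(nrow(et))) {
    h <- et$timestamp[k]
    if (h >= window_start && h < window_end) {
      total <- total + 1L
      age <- floor(as.numeric(difftime(h, birth, units = "secs")) / 86400)
      lct <- lct_at_birth - daily_decline * age
      if (et$effective_temp[k] < lct) below <- below + 1L
    }
  }
  list(below = below, total = total,
       proportion = if (total > 0) below / total else NaN)
}

# Closed-form least-squares slope via the normal equations, independent of
# lm(): slope = sum((x - xbar)(y - ybar)) / sum((x - xbar)^2).
oracle_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}
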