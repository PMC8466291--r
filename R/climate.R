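#' Wind- and humidity-adjusted effective temperature
#'
#' Combines air temperature, relative humidity and wind speed into a single
#' perceived-temperature index (degrees C):
#'
#' \deqn{ET = 37 - \frac{37 - t}{0.68 - 0.0014\,ur + 1/(1.76 + 1.4\,v^{0.75})}
#'            - 0.29\,t\,(1 - ur/100)}
#'
#' where \eqn{t} is air temperature (degrees C), \eqn{ur} relative humidity
#' (%) and \eqn{v} wind speed (m/s). At \eqn{t = 37}, \eqn{ur = 100} both
#' correction terms vanish and the index equals 37 for any wind speed. For
#' cold conditions the index decreases with wind and, below freezing, with
#' dryness, which is the regime relevant to calf housing.
#'
#' The function is pure and vectorised; it is the single place the index is
#' defined, so an alternative comfort index can be substituted by passing a
#' different function wherever `et_fun` arguments are accepted.
#'
#' @param air_temp air temperature, degrees C.
#' @param rel_humidity relative humidity, percent, in \[0, 100\].
#' @param wind_speed wind speed, m/s, non-negative.
#' @return effective temperature, degrees C.
#' @examples
#' effective_temperature(37, 100, 2)   # 37: fixed point
#' effective_temperature(10.3, 81, 0.2)
#' @export
effective_temperature <- function(air_temp, rel_humidity, wind_speed) {
  if (any(!is.finite(air_temp)) || any(!is.finite(rel_humidity)) ||
      any(!is.finite(wind_speed))) {
    stop("effective_temperature: inputs must be finite")
  }
  if (any(rel_humidity < 0 | rel_humidity > 100)) {
    stop("effective_temperature: relative humidity must lie in [0, 100]")
  }
  if (any(wind_speed < 0)) {
    stop("effective_temperature: wind speed must be non-negative")
  }
  denom <- 0.68 - 0.0014 * rel_humidity + 1 / (1.76 + 1.4 * wind_speed^0.75)
  37 - (37 - air_temp) / denom - 0.29 * air_temp * (1 - rel_humidity / 100)
}

#' Hourly effective-temperature series
#'
#' Applies [effective_temperature()] to every row of a validated hourly
#' climate table.
#'
#' @param climate data frame with columns `timestamp` (POSIXct), `air_temp`,
#'   `rel_humidity`, `wind_speed`.
#' @param et_fun the comfort index; defaults to [effective_temperature()].
#' @return data frame with columns `timestamp`, `effective_temp`.
#' @export
hourly_et_series <- function(climate, et_fun = effective_temperature) {
  stopifnot(all(c("timestamp", "air_temp", "rel_humidity", "wind_speed")
                %in% names(climate)))
  data.frame(
    timestamp = climate$timestamp,
    effective_temp = if (nrow(climate) == 0) numeric(0) else
      et_fun(climate$air_temp, climate$rel_humidity, climate$wind_speed)
  )
}

#' Column dialect for climate files
#'
#' @param timestamp,air_temp,rel_humidity,wind_speed column names in the file.
#' @param tz timezone used to parse timestamps (the study site is a single
#'   farm; timestamps are treated as timezone-naive local time).
#' @param sep field separator.
#' @return a named list usable as the `dialect` argument of [read_climate()].
#' @export
climate_dialect <- function(timestamp = "timestamp", air_temp = "air_temp",
                            rel_humidity = "rel_humidity",
                            wind_speed = "wind_speed",
                            tz = "UTC", sep = ",") {
  list(timestamp = timestamp, air_temp = air_temp,
       rel_humidity = rel_humidity, wind_speed = wind_speed,
       tz = tz, sep = sep)
}

#' Read and quality-control an hourly climate file
#'
#' Parses a delimited text file of hourly climate records (ISO-8601
#' timestamps), drops rows violating the physical invariants (relative
#' humidity outside \[0, 100\], negative wind speed, unparseable timestamp),
#' de-duplicates exact repeats, sorts ascending, and optionally forward-fills
#' short gaps. Hourly stamps denote the start of the hour they describe.
#'
#' Duplicate timestamps with conflicting measurements indicate a corrupted
#' download and are a hard error, as is an empty file.
#'
#' @param path path to a delimited text file.
#' @param dialect column mapping from [climate_dialect()].
#' @param max_gap_hours gaps of at most this many consecutive missing hours
#'   are forward-filled from the last observed hour (and flagged in the
#'   report); longer gaps are left absent so the missing hours drop out of
#'   both numerator and denominator of downstream exposure proportions.
#' @return list with `records` (validated data frame: timestamp, air_temp,
#'   rel_humidity, wind_speed, filled flag) and `report` (counts plus a
#'   data frame of dropped rows and reasons).
#' @export
read_climate <- function(path, dialect = climate_dialect(),
                         max_gap_hours = 3) {
  if (!file.exists(path)) stop("read_climate: file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0) stop("read_climate: file contains no data rows")
  for (col in c("timestamp", "air_temp", "rel_humidity", "wind_speed")) {
    if (!dialect[[col]] %in% names(raw)) {
      stop("read_climate: column '", dialect[[col]], "' (", col,
           ") not found in ", path)
    }
  }
  ts <- as.POSIXct(raw[[dialect$timestamp]],
                   tz = dialect$tz,
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                  "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"))
  df <- data.frame(
    timestamp = ts,
    air_temp = suppressWarnings(as.numeric(raw[[dialect$air_temp]])),
    rel_humidity = suppressWarnings(as.numeric(raw[[dialect$rel_humidity]])),
    wind_speed = suppressWarnings(as.numeric(raw[[dialect$wind_speed]]))
  )

  reason <- rep(NA_character_, nrow(df))
  reason[is.na(df$timestamp)] <- "unparseable timestamp"
  ok <- is.na(reason)
  bad_val <- ok & (is.na(df$air_temp) | is.na(df$rel_humidity) |
                     is.na(df$wind_speed))
  reason[bad_val] <- "non-numeric measurement"
  ok <- is.na(reason)
  bad_rh <- ok & (df$rel_humidity < 0 | df$rel_humidity > 100)
  reason[bad_rh] <- "relative humidity outside [0, 100]"
  ok <- is.na(reason)
  bad_wind <- ok & df$wind_speed < 0
  reason[bad_wind] <- "negative wind speed"
  ok <- is.na(reason)

  dropped <- data.frame(row = which(!ok), reason = reason[!ok])
  df <- df[ok, , drop = FALSE]
  if (nrow(df) == 0) stop("read_climate: no valid rows after validation")

  df <- unique(df)
  dup <- duplicated(df$timestamp)
  if (any(dup)) {
    stop("read_climate: conflicting duplicate timestamps at ",
         paste(format(unique(df$timestamp[dup])), collapse = ", "))
  }
  dropped_ts <- raw_ts_dropped(ts, ok)
  df <- df[order(df$timestamp), , drop = FALSE]
  rownames(df) <- NULL
  df$filled <- FALSE

  filled <- fill_climate_gaps(df, max_gap_hours, exclude = dropped_ts)
  list(
    records = filled,
    report = list(
      n_input = nrow(raw),
      n_retained = sum(!filled$filled),
      n_filled = sum(filled$filled),
      dropped = dropped
    )
  )
}

# Timestamps of rows removed by validation (kept out of gap filling: an
# hour dropped for a bad measurement stays excluded rather than being
# resurrected by forward-fill).
raw_ts_dropped <- function(ts, ok) {
  out <- ts[!ok]
  out[!is.na(out)]
}

#' Forward-fill short gaps in an hourly series
#'
#' @param climate sorted, de-duplicated climate data frame with a `filled`
#'   logical column.
#' @param max_gap_hours maximum run of missing hours to fill.
#' @param exclude timestamps never to fill (hours removed by validation).
#' @return climate data frame with filled rows inserted and flagged.
#' @keywords internal
fill_climate_gaps <- function(climate, max_gap_hours = 3,
                              exclude = NULL) {
  if (nrow(climate) < 2 || max_gap_hours < 1) return(climate)
  gaps <- as.numeric(difftime(climate$timestamp[-1],
                              climate$timestamp[-nrow(climate)],
                              units = "hours"))
  extra <- list()
  for (i in which(gaps > 1 & gaps <= max_gap_hours + 1)) {
    n_miss <- round(gaps[i]) - 1
    tmpl <- climate[i, , drop = FALSE]
    for (k in seq_len(n_miss)) {
      stamp <- tmpl$timestamp + k * 3600
      if (!is.null(exclude) && stamp %in% exclude) next
      row <- tmpl
      row$timestamp <- stamp
      row$filled <- TRUE
      extra[[length(extra) + 1]] <- row
    }
  }
  if (length(extra) == 0) return(climate)
  out <- rbind(climate, do.call(rbind, extra))
  out <- out[order(out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  out
}
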