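#' Utah-model hourly chilling contribution
#'
#' Weight of a single hourly temperature reading under the Utah chill-unit
#' model (Richardson et al. 1974). Temperatures are banded at one-decimal
#' resolution: mild cold (2.5--9.1 C) contributes one full chill unit, the
#' flanking bands contribute half a unit, temperate readings contribute
#' nothing, and warm readings (>= 16 C) subtract units.
#'
#' @param temp_c Numeric vector of hourly temperatures in degrees Celsius.
#' @return Numeric vector of chill-unit contributions (one per reading), in
#'   \{-1, -0.5, 0, 0.5, 1\}.
#' @examples
#' utah_chill_hourly(c(5, 14, 25))
#' @export
utah_chill_hourly <- function(temp_c) {
  if (!is.numeric(temp_c) || anyNA(temp_c) || any(!is.finite(temp_c))) {
    stop("`temp_c` must be finite numeric temperatures")
  }
  cu <- numeric(length(temp_c))
  cu[temp_c >= 1.45 & temp_c < 2.45] <- 0.5
  cu[temp_c >= 2.45 & temp_c < 9.15] <- 1.0
  cu[temp_c >= 9.15 & temp_c < 12.45] <- 0.5
  # 12.45 <= T < 15.95 contributes 0
  cu[temp_c >= 15.95 & temp_c <= 18.0] <- -0.5
  cu[temp_c > 18.0] <- -1.0
  cu
}

#' Accumulate chilling units over an hourly temperature series
#'
#' Sums Utah-model hourly contributions from a start date onward and returns
#' the cumulative total per calendar day. Daily min/max input is first
#' expanded to hourly values by sine interpolation (minimum at sunrise-like
#' 05:00, maximum at 14:00 local).
#'
#' @param series A data.frame with either columns `timestamp` (POSIXct,
#'   hourly) and `temp_c`, or columns `date` (Date) plus `tmin` and `tmax`.
#' @param start_date Date from which accumulation starts (chill units before
#'   it are ignored).
#' @param clamp_daily_negative If TRUE, a day's net contribution is floored at
#'   zero before accumulation. Default FALSE (negative accumulation allowed).
#' @return A data.frame with columns `date` and `cu_cumulative`.
#' @export
accumulate_chill <- function(series, start_date, clamp_daily_negative = FALSE) {
  start_date <- as.Date(start_date)
  if (all(c("date", "tmin", "tmax") %in% names(series))) {
    series <- sine_interpolate_hourly(series)
  }
  if (!all(c("timestamp", "temp_c") %in% names(series))) {
    stop("`series` needs columns timestamp/temp_c or date/tmin/tmax")
  }
  ts <- as.POSIXct(series$timestamp, tz = "UTC")
  o <- order(ts)
  ts <- ts[o]
  temp <- series$temp_c[o]
  gaps <- diff(as.numeric(ts)) / 3600
  if (length(gaps) && any(gaps > 24)) {
    i <- which(gaps > 24)[1]
    stop(sprintf("temperature series has a gap of %.1f h after %s",
                 gaps[i], format(ts[i])))
  }
  keep <- as.Date(ts, tz = "UTC") >= start_date
  if (!any(keep)) stop("series does not cover `start_date`")
  ts <- ts[keep]
  temp <- temp[keep]
  day <- as.Date(ts, tz = "UTC")
  daily <- tapply(utah_chill_hourly(temp), day, sum)
  if (clamp_daily_negative) daily <- pmax(daily, 0)
  data.frame(
    date = as.Date(names(daily)),
    cu_cumulative = unname(cumsum(daily))
  )
}

# Expand daily tmin/tmax to 24 hourly values with a sine curve: minimum at
# 05:00, maximum at 14:00, symmetric fall-off overnight.
sine_interpolate_hourly <- function(daily) {
  hours <- 0:23
  out <- do.call(rbind, lapply(seq_len(nrow(daily)), function(i) {
    tmin <- daily$tmin[i]
    tmax <- daily$tmax[i]
    mid <- (tmax + tmin) / 2
    amp <- (tmax - tmin) / 2
    # phase chosen so temp(5h) = tmin and temp(14h) = tmax
    temp <- mid + amp * sin(2 * pi * (hours - 9.5) / 18)
    temp[hours < 5 | hours > 14] <-
      mid + amp * cos(pi * ((hours[hours < 5 | hours > 14] - 14) %% 24) / 15)
    data.frame(
      timestamp = as.POSIXct(paste(daily$date[i], sprintf("%02d:00:00", hours)),
                             tz = "UTC"),
      temp_c = temp
    )
  }))
  out
}

#' Day length (photoperiod) from the sunrise equation
#'
#' Computes sunset minus sunrise in decimal hours using the standard sunrise
#' equation with the solar declination of the day (Spencer Fourier series) and
#' an effective zenith of 90.833 degrees (atmospheric refraction plus solar
#' radius). Longitude does not affect day length and is accepted only for
#' interface symmetry with site coordinates.
#'
#' @param date Date (or coercible) vector.
#' @param latitude_deg Site latitude in degrees (positive north). Must satisfy
#'   |latitude| < 66.5; polar day/night is not supported.
#' @param longitude_deg Site longitude in degrees; unused in the computation.
#' @return Numeric vector of day lengths in decimal hours.
#' @examples
#' day_length(as.Date("2021-12-21"), 45.35, 11.96)
#' @export
day_length <- function(date, latitude_deg, longitude_deg = 0) {
  date <- as.Date(date)
  if (abs(latitude_deg) >= 66.5) {
    stop("|latitude| must be < 66.5 degrees (polar day/night unsupported)")
  }
  doy <- as.integer(strftime(date, "%j"))
  g <- 2 * pi / 365 * (doy - 1 + 0.5)
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  phi <- latitude_deg * pi / 180
  zen <- 90.833 * pi / 180
  cosw <- (cos(zen) - sin(phi) * sin(decl)) / (cos(phi) * cos(decl))
  if (any(cosw < -1 | cosw > 1)) {
    stop("sunrise equation has no solution for this date/latitude")
  }
  2 * acos(cosw) * 180 / pi / 15
}

#' Build the per-sample environmental trait table
#'
#' Looks up cumulative chilling units and computes day length for each
#' sampling date, yielding the CHILLING and LOD covariates used downstream in
#' module-trait correlation.
#'
#' @param sample_metadata data.frame with columns `sample_id` and `date`.
#' @param chilling_series Output of [accumulate_chill()].
#' @param lat,lon Site coordinates in degrees (defaults: Legnaro, Italy).
#' @return data.frame with columns `sample_id`, `date`, `CHILLING`, `LOD`.
#' @export
build_trait_table <- function(sample_metadata, chilling_series,
                              lat = 45.35, lon = 11.96) {
  if (nrow(sample_metadata) == 0) {
    return(data.frame(sample_id = character(), date = as.Date(character()),
                      CHILLING = numeric(), LOD = numeric()))
  }
  if (anyDuplicated(sample_metadata$sample_id)) {
    stop("duplicated sample ids in metadata")
  }
  dates <- as.Date(sample_metadata$date)
  idx <- match(dates, chilling_series$date)
  if (anyNA(idx)) {
    stop(sprintf("sample date %s not covered by the chilling series",
                 dates[which(is.na(idx))[1]]))
  }
  data.frame(
    sample_id = sample_metadata$sample_id,
    date = dates,
    CHILLING = chilling_series$cu_cumulative[idx],
    LOD = day_length(dates, lat, lon)
  )
}
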