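#' Sunrise and sunset times
#'
#' Computes sunrise and sunset for a date and location with the NOAA
#' solar calculator equations (Fourier-series solar declination and
#' equation of time, zenith 90.833 degrees including refraction and
#' solar radius).  Accuracy is well within five minutes of the NOAA
#' reference calculator for non-polar latitudes.
#'
#' @param latitude,longitude degrees; longitude positive east.
#'   Latitudes beyond 66 degrees (polar day/night possible) are not
#'   supported.
#' @param date a `Date` (or string coercible to one).
#' @param tz timezone of the returned `POSIXct` times.
#' @return list with `date`, `sunrise`, `sunset` (`POSIXct`), and
#'   `day_length_hours`.
#' @export
sun_times <- function(latitude, longitude, date, tz = "UTC") {
  if (abs(latitude) >= 66) {
    stop("latitudes beyond 66 degrees are not supported ",
         "(polar day/night)")
  }
  date <- as.Date(date)
  doy <- as.integer(strftime(date, "%j"))
  gamma <- 2 * pi / 365 * (doy - 1)   # fractional year at solar noon
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(gamma) -
                      0.032077 * sin(gamma) - 0.014615 * cos(2 * gamma) -
                      0.040849 * sin(2 * gamma))
  decl <- 0.006918 - 0.399912 * cos(gamma) + 0.070257 * sin(gamma) -
    0.006758 * cos(2 * gamma) + 0.000907 * sin(2 * gamma) -
    0.002697 * cos(3 * gamma) + 0.00148 * sin(3 * gamma)
  lat <- latitude * pi / 180
  zen <- 90.833 * pi / 180
  cos_ha <- cos(zen) / (cos(lat) * cos(decl)) - tan(lat) * tan(decl)
  cos_ha <- pmin(pmax(cos_ha, -1), 1)
  ha <- acos(cos_ha) * 180 / pi       # degrees
  sunrise_min <- 720 - 4 * (longitude + ha) - eqtime   # minutes UTC
  sunset_min <- 720 - 4 * (longitude - ha) - eqtime
  midnight <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  sunrise <- midnight + sunrise_min * 60
  sunset <- midnight + sunset_min * 60
  attr(sunrise, "tzone") <- tz
  attr(sunset, "tzone") <- tz
  list(date = date, latitude = latitude, longitude = longitude,
       sunrise = sunrise, sunset = sunset,
       day_length_hours = as.numeric(2 * 4 * ha / 60))
}

#' Transform a timestamp to solar time (radians)
#'
#' Double-anchored transform: sunrise maps to \eqn{\pi/2}, sunset to
#' \eqn{3\pi/2}, with linear interpolation inside the day segment and
#' inside the night segment (wrapping through \eqn{2\pi} at solar
#' midnight).  This removes seasonal day-length variation so activity
#' curves are comparable across the year.
#'
#' @param timestamp `POSIXct` time(s) within about a day of the
#'   supplied sun times.
#' @param sun the [sun_times()] list for the record's date and
#'   location.
#' @param next_sunrise,prev_sunset sunrise of the following day and
#'   sunset of the preceding day; default to the supplied ones shifted
#'   by 24 h, adequate away from the solstice discontinuities.
#' @return angle(s) in `[0, 2*pi)`.
#' @export
to_solar_time <- function(timestamp, sun,
                          next_sunrise = sun$sunrise + 86400,
                          prev_sunset = sun$sunset - 86400) {
  t <- as.numeric(timestamp)
  sr <- as.numeric(sun$sunrise); ss <- as.numeric(sun$sunset)
  nsr <- as.numeric(next_sunrise); pss <- as.numeric(prev_sunset)
  ang <- numeric(length(t))
  day <- t >= sr & t <= ss
  ang[day] <- pi / 2 + (t[day] - sr) / (ss - sr) * pi
  evening <- t > ss
  ang[evening] <- 3 * pi / 2 + (t[evening] - ss) / (nsr - ss) * pi
  morning <- t < sr
  ang[morning] <- 3 * pi / 2 + (t[morning] - pss) / (sr - pss) * pi
  ang %% (2 * pi)
}

#' Classify a detection time as nocturnal, diurnal or crepuscular
#'
#' Nocturnal records fall from one hour after sunset up to one hour
#' before the following sunrise; diurnal records from one hour after
#' sunrise up to one hour before sunset.  Records within the hour
#' around sunrise or sunset are `"crepuscular_excluded"` so twilight
#' activity does not contaminate nocturnality estimates.  Night spans
#' two dates: a pre-dawn record is classified against the previous
#' evening's sunset.
#'
#' @param timestamp `POSIXct` time(s).
#' @param latitude,longitude station coordinates in degrees.
#' @param exclusion_hours half-width of the twilight exclusion band.
#' @return character vector: `"nocturnal"`, `"diurnal"` or
#'   `"crepuscular_excluded"`.
#' @export
classify_diel <- function(timestamp, latitude, longitude,
                          exclusion_hours = 1) {
  tz <- attr(timestamp, "tzone")
  if (is.null(tz) || tz == "") tz <- "UTC"
  date <- as.Date(format(timestamp, "%Y-%m-%d"))
  out <- character(length(timestamp))
  ex <- exclusion_hours * 3600
  for (d in unique(date)) {
    idx <- which(date == d)
    dd <- as.Date(d, origin = "1970-01-01")
    s0 <- sun_times(latitude, longitude, dd, tz = tz)
    s_prev <- sun_times(latitude, longitude, dd - 1, tz = tz)
    s_next <- sun_times(latitude, longitude, dd + 1, tz = tz)
    t <- as.numeric(timestamp[idx])
    sr <- as.numeric(s0$sunrise); ss <- as.numeric(s0$sunset)
    pss <- as.numeric(s_prev$sunset); nsr <- as.numeric(s_next$sunrise)
    cls <- rep("crepuscular_excluded", length(idx))
    cls[t >= sr + ex & t <= ss - ex] <- "diurnal"
    cls[t >= ss + ex & t <= nsr - ex] <- "nocturnal"   # evening night
    cls[t <= sr - ex & t >= pss + ex] <- "nocturnal"   # pre-dawn night
    out[idx] <- cls
  }
  out
}

#' Annotate detection records with diel class and solar angle
#'
#' Joins station coordinates onto the records and applies
#' [classify_diel()] and [to_solar_time()] per record.
#'
#' @param records detection records (`station_id`, `species`,
#'   `timestamp`).
#' @param stations station table with `station_id`, `latitude`,
#'   `longitude`.
#' @param exclusion_hours twilight exclusion half-width in hours.
#' @return `records` with added `diel_class` and `solar_angle` columns.
#' @export
diel_annotate <- function(records, stations, exclusion_hours = 1) {
  idx <- match(records$station_id, stations$station_id)
  if (anyNA(idx)) {
    stop("records reference stations missing from the station table: ",
         paste(unique(records$station_id[is.na(idx)]), collapse = ", "))
  }
  records$diel_class <- NA_character_
  records$solar_angle <- NA_real_
  for (sid in unique(records$station_id)) {
    rows <- which(records$station_id == sid)
    i <- idx[rows[1L]]
    ts <- records$timestamp[rows]
    records$diel_class[rows] <- classify_diel(
      ts, stations$latitude[i], stations$longitude[i], exclusion_hours)
    date <- as.Date(format(ts, "%Y-%m-%d"))
    ang <- numeric(length(rows))
    for (d in unique(date)) {
      sel <- date == d
      dd <- as.Date(d, origin = "1970-01-01")
      tz <- attr(ts, "tzone") %||% "UTC"
      s0 <- sun_times(stations$latitude[i], stations$longitude[i], dd,
                      tz = tz)
      s_next <- sun_times(stations$latitude[i], stations$longitude[i],
                          dd + 1, tz = tz)
      s_prev <- sun_times(stations$latitude[i], stations$longitude[i],
                          dd - 1, tz = tz)
      ang[sel] <- to_solar_time(ts[sel], s0,
                                next_sunrise = s_next$sunrise,
                                prev_sunset = s_prev$sunset)
    }
    records$solar_angle[rows] <- ang
  }
  records
}

`%||%` <- function(a, b) if (is.null(a)) b else a
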