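# Small in-code fixtures shared across test files.

TZ6 <- "Etc/GMT-6"  # UTC+6, the default zone for offset-less timestamps

ts6 <- function(...) as.POSIXct(c(...), tz = TZ6)

# detection records at one or more stations; `minutes` are offsets from
# a common origin
make_records <- function(station, species, minutes,
                         origin = "2021-01-10 08:00:00") {
  data.frame(
    station_id = rep_len(station, length(minutes)),
    species = rep_len(species, length(minutes)),
    timestamp = as.POSIXct(origin, tz = TZ6) + minutes * 60,
    stringsAsFactors = FALSE
  )
}

make_stations <- function(n, hm = NULL, hp = NULL) {
  data.frame(
    station_id = sprintf("ST%03d", seq_len(n)),
    latitude = 29.5, longitude = 95.25,
    start_date = as.Date("2020-11-01"),
    end_date = as.Date("2021-03-26"),
    elevation = seq(1500, 3500, length.out = n),
    forest_cover = seq(0.2, 0.9, length.out = n),
    human_modification = hm %||% seq(0.04, 0.28, length.out = n),
    human_presence = hp %||% seq(0, 40, length.out = n),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sym_from_upper_test <- function(m) {
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

# Frozen reference sunrise/sunset (minutes after 00:00 UTC) from an
# independent implementation of the full NOAA spreadsheet algorithm.
noaa_reference <- data.frame(
  latitude = c(0, 29.5, 29.5, 51.5, 29.5),
  longitude = c(0, 95.25, 95.25, -0.13, 95.25),
  date = as.Date(c("2021-03-20", "2021-01-15", "2020-12-21",
                   "2021-06-21", "2021-04-01")),
  sunrise_min = c(364.04, 34.55, 29.81, 223.25, -31.82),
  sunset_min = c(1090.71, 662.44, 644.82, 1221.50, 717.37)
)

# independent brute-force R from a loading matrix (scalar arithmetic,
# no package code)
brute_R <- function(L) {
  S <- nrow(L)
  R <- matrix(NA_real_, S, S)
  for (i in seq_len(S)) for (j in seq_len(S)) {
    oij <- sum(L[i, ] * L[j, ])
    oii <- sum(L[i, ]^2)
    ojj <- sum(L[j, ]^2)
    R[i, j] <- oij / sqrt(oii * ojj)
  }
  R
}
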