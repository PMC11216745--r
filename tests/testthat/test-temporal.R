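
test_that("sun times agree with the NOAA reference within 5 minutes", {
  for (i in seq_len(nrow(noaa_reference))) {
    s <- sun_times(noaa_reference$latitude[i], noaa_reference$longitude[i],
                   noaa_reference$date[i])
    mid <- as.POSIXct(paste(noaa_reference$date[i], "00:00:00"), tz = "UTC")
    expect_lt(abs(as.numeric(s$sunrise - mid, units = "mins") -
                  noaa_reference$sunrise_min[i]), 5)
    expect_lt(abs(as.numeric(s$sunset - mid, units = "mins") -
                  noaa_reference$sunset_min[i]), 5)
  }
})

test_that("equator equinox sunrise and sunset sit near 06:00/18:00 UTC", {
  s <- sun_times(0, 0, as.Date("2021-03-20"))
  mid <- as.POSIXct("2021-03-20 00:00:00", tz = "UTC")
  # refraction (zenith 90.833) and the equation of time displace the
  # true NOAA values ~5-11 min from the idealised 06:00/18:00
  expect_lt(abs(as.numeric(s$sunrise - mid, units = "mins") - 360), 15)
  expect_lt(abs(as.numeric(s$sunset - mid, units = "mins") - 1080), 15)
  expect_identical(s, sun_times(0, 0, as.Date("2021-03-20")))
})

test_that("polar latitudes are rejected", {
  expect_error(sun_times(70, 0, as.Date("2021-06-01")), "polar")
})

test_that("solar time anchors sunrise at pi/2 and sunset at 3*pi/2", {
  s <- sun_times(29.5, 95.25, as.Date("2021-01-15"), tz = TZ6)
  expect_equal(to_solar_time(s$sunrise, s), pi / 2, tolerance = 1e-9)
  expect_equal(to_solar_time(s$sunset, s), 3 * pi / 2, tolerance = 1e-9)
  midday <- s$sunrise + as.numeric(s$sunset - s$sunrise, units = "secs") / 2
  expect_equal(to_solar_time(midday, s), pi, tolerance = 1e-9)
})

test_that("solar time is monotone within segments and continuous at anchors", {
  s <- sun_times(29.5, 95.25, as.Date("2021-01-15"), tz = TZ6)
  day_grid <- s$sunrise + as.numeric(s$sunset - s$sunrise, units = "secs") *
    seq(0, 1, by = 0.1)
  ang <- to_solar_time(day_grid, s)
  expect_true(all(diff(ang) > 0))
  night_grid <- s$sunset + seq(60, 6 * 3600, by = 1800)
  ang_n <- to_solar_time(night_grid, s)
  expect_true(all(diff(ang_n) > 0))
  expect_lt(abs(to_solar_time(s$sunset + 1, s) - 3 * pi / 2), 1e-3)
})

test_that("diel classification partitions records around the twilight band", {
  lat <- 29.5; lon <- 95.25
  s <- sun_times(lat, lon, as.Date("2021-01-15"), tz = TZ6)
  expect_equal(classify_diel(s$sunset + 30 * 60, lat, lon),
               "crepuscular_excluded")
  expect_equal(classify_diel(s$sunrise - 30 * 60, lat, lon),
               "crepuscular_excluded")
  noon <- s$sunrise + as.numeric(s$sunset - s$sunrise, units = "secs") / 2
  expect_equal(classify_diel(noon, lat, lon), "diurnal")
  midnight <- s$sunset + 6.5 * 3600    # deep night
  expect_equal(classify_diel(midnight, lat, lon), "nocturnal")
  predawn <- s$sunrise - 2 * 3600 + 86400
  expect_equal(classify_diel(predawn, lat, lon), "nocturnal")
  # exhaustive partition over a full day
  grid <- s$sunrise - 6 * 3600 + seq(0, 86399, by = 600)
  cls <- classify_diel(grid, lat, lon)
  expect_true(all(cls %in% c("nocturnal", "diurnal",
                             "crepuscular_excluded")))
  expect_equal(sum(cls == "nocturnal") + sum(cls == "diurnal") +
               sum(cls == "crepuscular_excluded"), length(grid))
})

test_that("disturbance strata take the extreme quarters with stable ties", {
  st <- make_stations(8, hp = c(5, 1, 8, 3, 9, 2, 7, 4))
  s <- disturbance_strata(st, "human_presence")
  expect_equal(sort(s$low), sort(st$station_id[c(2, 6)]))
  expect_equal(sort(s$high), sort(st$station_id[c(5, 3)]))
  expect_length(s$low, 2); expect_length(s$high, 2)

  st322 <- make_stations(322)
  s322 <- disturbance_strata(st322, "human_modification")
  expect_length(s322$low, 81)   # ceiling(322 / 4)
  expect_length(s322$high, 81)

  st_tie <- make_stations(8, hp = rep(3, 8))
  expect_error(disturbance_strata(st_tie, "human_presence"), "constant")
})

test_that("identical strata give a zero nocturnality shift", {
  set.seed(5)
  n <- 80
  r <- make_records("A", "civet", seq(0, by = 500, length.out = n))
  r$diel_class <- sample(c("nocturnal", "diurnal"), n, replace = TRUE)
  meta <- data.frame(species = "civet", mass_kg = 4, guild = "carnivore")
  out <- nocturnality_shift(r, r, meta, min_detections = 30,
                            n_boot = 500, seed = 1)
  expect_equal(out$species$difference, 0)
  g <- out$guilds[out$guilds$guild == "carnivore", ]
  expect_equal(g$mean_difference, 0)
  expect_true(g$ci_lower <= 0 & g$ci_upper >= 0)
  expect_false(g$significant)
})

test_that("a total day-to-night flip gives a shift of one", {
  n <- 40
  r_lo <- make_records("A", "civet", seq(0, by = 500, length.out = n))
  r_lo$diel_class <- "diurnal"
  r_hi <- r_lo; r_hi$diel_class <- "nocturnal"
  meta <- data.frame(species = "civet", mass_kg = 4, guild = "carnivore")
  out <- nocturnality_shift(r_lo, r_hi, meta, n_boot = 200, seed = 1)
  expect_equal(out$species$difference, 1)
  expect_equal(out$guilds$mean_difference[1], 1)
})

test_that("species below the detection threshold are dropped", {
  n <- 40
  r_lo <- rbind(make_records("A", "civet", seq(0, by = 500, length.out = n)),
                make_records("A", "tiger", seq(0, by = 500, length.out = 10)))
  r_lo$diel_class <- "diurnal"
  r_hi <- r_lo; r_hi$diel_class <- "nocturnal"
  meta <- data.frame(species = c("civet", "tiger"), mass_kg = c(4, 180),
                     guild = "carnivore", stringsAsFactors = FALSE)
  out <- nocturnality_shift(r_lo, r_hi, meta, min_detections = 30,
                            n_boot = 100, seed = 1)
  expect_equal(out$species$species, "civet")
  expect_warning(
    empty <- nocturnality_shift(r_lo[0, ], r_hi[0, ], meta,
                                n_boot = 10, seed = 1),
    "threshold")
  expect_null(empty$guilds)
})

test_that("encounter intervals follow the consecutive-record rule", {
  r <- rbind(make_records("A", "muntjac", 0),
             make_records("A", "serow", 2 * 1440))
  out <- time_to_encounter(r)
  expect_equal(nrow(out), 1L)
  expect_equal(out$delta_days, 2)
  expect_equal(out$log_delta, log(2), tolerance = 1e-9)
  expect_equal(round(out$log_delta, 4), 0.6931)

  # A at day 0 and 1, B at day 3: one cross interval A@1 -> B@3
  r2 <- rbind(make_records("A", "muntjac", c(0, 1440)),
              make_records("A", "serow", 3 * 1440))
  out2 <- time_to_encounter(r2)
  expect_equal(nrow(out2), 1L)
  expect_equal(out2$delta_days, 2)
  expect_equal(out2$species_a, "muntjac")
  expect_equal(out2$species_b, "serow")

  # one species only: nothing
  expect_equal(nrow(time_to_encounter(make_records("A", "muntjac",
                                                   c(0, 500)))), 0L)
})

test_that("encounter output ignores input order and floors simultaneity", {
  set.seed(8)
  r <- rbind(make_records("A", "muntjac", c(0, 700, 2000)),
             make_records("A", "serow", c(350, 1500)),
             make_records("B", "muntjac", c(100, 900)),
             make_records("B", "civet", c(400, 2200)))
  base <- time_to_encounter(r)
  shuffled <- r[sample.int(nrow(r)), , drop = FALSE]
  expect_equal(time_to_encounter(shuffled), base)

  r0 <- rbind(make_records("A", "muntjac", 0),
              make_records("A", "serow", 0))
  expect_warning(out0 <- time_to_encounter(r0), "simultaneous")
  expect_equal(out0$delta_days, 1 / 1440)
})

test_that("bootstrap contrast is reproducible with degenerate CIs on constants", {
  v <- rep(2.5, 20)
  out <- bootstrap_diff(v, v, n_boot = 200, seed = 3)
  expect_equal(out$mean_difference, 0)
  expect_equal(out$ci_lower, 0)
  expect_equal(out$ci_upper, 0)
  expect_false(out$significant)
  set.seed(91)
  x <- rnorm(30); y <- rnorm(30)
  a <- bootstrap_diff(x, y, n_boot = 500, seed = 11)
  b <- bootstrap_diff(x, y, n_boot = 500, seed = 11)
  expect_identical(a, b)
  expect_error(bootstrap_diff(numeric(0), 1:5), "non-empty")
})

test_that("a known log shift is recovered by the bootstrap contrast", {
  set.seed(21)
  delta <- 0.5
  lo <- rnorm(300, 1.0, 0.8)
  hi <- rnorm(300, 1.0 - delta, 0.8)
  out <- bootstrap_diff(lo, hi, n_boot = 2000, seed = 4)
  expect_lt(abs(out$mean_difference - (-delta)), 2 * out$boot_sd)
  expect_true(out$significant)
})
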