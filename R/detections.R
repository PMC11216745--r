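#' Read camera-trap detection, station and species tables
#'
#' Comma-delimited UTF-8 files with header rows.  The detections table
#' needs columns `station_id`, `species`, `timestamp` (ISO 8601, with
#' or without a UTC offset); the station table needs `station_id`,
#' `latitude`, `longitude`, `start_date`, `end_date`, `elevation`,
#' `forest_cover`, `human_modification`; the species table needs
#' `species`, `mass_kg`, `guild`.
#'
#' Timestamps without an explicit UTC offset are interpreted in `tz`
#' (default `"Etc/GMT-6"`, i.e. UTC+6, local solar-adjacent time for
#' the eastern-Himalaya study region these tools were written around).
#'
#' @param path file path.
#' @param tz timezone applied to offset-less timestamps.
#' @return a data frame; detection timestamps are `POSIXct`.
#' @export
read_detections <- function(path, tz = "Etc/GMT-6") {
  df <- read_table_checked(path, c("station_id", "species", "timestamp"))
  df$timestamp <- parse_timestamps(df$timestamp, tz = tz, where = path)
  df$station_id <- as.character(df$station_id)
  df$species <- as.character(df$species)
  df[order(df$station_id, df$timestamp), , drop = FALSE]
}

#' @rdname read_detections
#' @export
read_stations <- function(path) {
  df <- read_table_checked(path, c("station_id", "latitude", "longitude",
                                   "start_date", "end_date", "elevation",
                                   "forest_cover", "human_modification"))
  df$station_id <- as.character(df$station_id)
  df$start_date <- as.Date(df$start_date)
  df$end_date <- as.Date(df$end_date)
  if (any(is.na(df$start_date) | is.na(df$end_date))) {
    stop("unparseable operation dates in ", path)
  }
  if (any(df$end_date < df$start_date)) {
    stop("station operation window ends before it starts in ", path)
  }
  if (any(df$human_modification < 0 | df$human_modification > 1)) {
    stop("human_modification must lie in [0, 1]")
  }
  if (any(abs(df$latitude) > 90)) stop("latitude out of range")
  df
}

#' @rdname read_detections
#' @export
read_species <- function(path) {
  df <- read_table_checked(path, c("species", "mass_kg", "guild"))
  df$species <- as.character(df$species)
  df
}

read_table_checked <- function(path, required) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("file ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  }
  df
}

# ISO 8601 parser accepting "YYYY-mm-dd HH:MM:SS", a "T" separator and
# an optional +HHMM / +HH:MM offset.
parse_timestamps <- function(x, tz = "Etc/GMT-6", where = "input") {
  x <- sub("T", " ", as.character(x), fixed = TRUE)
  has_offset <- grepl("[+-][0-9]{2}:?[0-9]{2}$", x)
  out <- rep(as.POSIXct(NA), length(x))
  if (any(has_offset)) {
    xo <- sub("([+-][0-9]{2}):([0-9]{2})$", "\\1\\2", x[has_offset])
    out[has_offset] <- as.POSIXct(xo, format = "%Y-%m-%d %H:%M:%S%z",
                                  tz = tz)
  }
  if (any(!has_offset)) {
    out[!has_offset] <- as.POSIXct(x[!has_offset],
                                   format = "%Y-%m-%d %H:%M:%S", tz = tz)
  }
  if (anyNA(out)) {
    bad <- which(is.na(out))[1L]
    stop("unparseable timestamp in ", where, " at row ", bad, ": ",
         x[bad])
  }
  attr(out, "tzone") <- tz
  out
}

#' Filter records to independent detections
#'
#' Applies the standard camera-trap independence rule: within each
#' station-by-species stream, a record is kept if and only if at least
#' `window_minutes` have elapsed since the last *kept* record of that
#' stream (greedy forward scan; each kept record restarts the clock).
#' Records of different species, or at different stations, never
#' suppress each other.  The operation is idempotent and invariant to
#' the input row order.
#'
#' @param records data frame with `station_id`, `species`, `timestamp`
#'   (`POSIXct`), e.g. from [read_detections()].
#' @param window_minutes minimum separation between kept records.
#' @return the filtered data frame, sorted by station, species, time.
#' @export
filter_independent <- function(records, window_minutes = 60) {
  stopifnot(inherits(records$timestamp, "POSIXct"))
  if (nrow(records) == 0L) return(records)
  ord <- order(records$station_id, records$species, records$timestamp)
  records <- records[ord, , drop = FALSE]
  key <- paste(records$station_id, records$species, sep = "\r")
  t <- as.numeric(records$timestamp)
  keep <- logical(nrow(records))
  last_key <- ""
  last_t <- -Inf
  win <- window_minutes * 60
  for (i in seq_len(nrow(records))) {
    if (key[i] != last_key || t[i] - last_t >= win) {
      keep[i] <- TRUE
      last_key <- key[i]
      last_t <- t[i]
    }
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sampling effort of a station in camera-days
#'
#' Inclusive whole-day count of the operation window; a station that
#' starts and ends on the same date contributes one camera-day.
#'
#' @param station one row of a station table (list or data frame row)
#'   with `start_date` and `end_date`.
#' @return number of camera-days.
#' @export
effort_days <- function(station) {
  s <- as.Date(station$start_date); e <- as.Date(station$end_date)
  if (length(s) != 1L || length(e) != 1L || is.na(s) || is.na(e)) {
    stop("station must carry valid start_date and end_date")
  }
  if (e < s) stop("end_date precedes start_date")
  as.numeric(e - s) + 1
}

#' Human-presence detection rate of a station
#'
#' Independent detections of the special species code `"Human"` per 100
#' camera-days of effort.
#'
#' @param records independence-filtered detection records.
#' @param station station row with `station_id`, `start_date`,
#'   `end_date`.
#' @return detections per 100 camera-days.
#' @export
human_presence_rate <- function(records, station) {
  ed <- effort_days(station)
  if (ed <= 0) stop("zero sampling effort")
  n_human <- sum(records$station_id == station$station_id &
                 records$species == "Human")
  100 * n_human / ed
}

#' Station-level human-presence rates for a whole station table
#'
#' @param records independence-filtered detection records.
#' @param stations station table from [read_stations()].
#' @return named numeric vector, one rate per station in table order.
#' @export
human_presence_rates <- function(records, stations) {
  human <- records[records$species == "Human", , drop = FALSE]
  counts <- table(factor(human$station_id, levels = stations$station_id))
  effort <- as.numeric(stations$end_date - stations$start_date) + 1
  stats::setNames(100 * as.numeric(counts) / effort, stations$station_id)
}

#' Build the standardized station-level design matrix
#'
#' Human-presence rates are first log-transformed as \eqn{\log(x +
#' 0.1)} to tame their skew, then (by default) z-scored; elevation,
#' forest cover and the human-modification index are z-scored directly.
#' Standardization uses the sample standard deviation (denominator
#' \eqn{n - 1}).  An intercept column of ones is prepended and the raw
#' covariate values are retained (attribute `"raw"`) for later
#' context predictions on the original scale.
#'
#' @param stations station table from [read_stations()].
#' @param presence_rates per-station human-presence rates in station
#'   table order, e.g. from [human_presence_rates()].
#' @param standardize_presence z-score the log-presence column too
#'   (default); set `FALSE` to keep it on the raw log scale.
#' @return data frame with columns `station_id`, `intercept`,
#'   `elevation_z`, `forest_z`, `human_modification_z`,
#'   `human_presence_logz`, with raw values in `attr(, "raw")`.
#' @export
transform_covariates <- function(stations, presence_rates,
                                 standardize_presence = TRUE) {
  if (nrow(stations) < 2L) stop("at least two stations are required")
  if (length(presence_rates) != nrow(stations)) {
    stop("`presence_rates` must have one value per station")
  }
  zscore <- function(v, name) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) {
      stop("covariate `", name, "` has zero variance across stations")
    }
    (v - mean(v)) / s
  }
  log_presence <- log(presence_rates + 0.1)
  out <- data.frame(
    station_id = stations$station_id,
    intercept = 1,
    elevation_z = zscore(stations$elevation, "elevation"),
    forest_z = zscore(stations$forest_cover, "forest_cover"),
    human_modification_z = zscore(stations$human_modification,
                                  "human_modification"),
    human_presence_logz = if (standardize_presence) {
      zscore(log_presence, "human_presence")
    } else {
      log_presence
    },
    stringsAsFactors = FALSE
  )
  attr(out, "raw") <- data.frame(
    station_id = stations$station_id,
    elevation = stations$elevation,
    forest_cover = stations$forest_cover,
    human_modification = stations$human_modification,
    human_presence = as.numeric(presence_rates),
    stringsAsFactors = FALSE
  )
  out
}

#' Build the presence-absence matrix of focal species
#'
#' Collapses independent detections to a station-by-species binary
#' matrix.  The `"Human"` code is excluded, and a species is retained
#' only if its body mass exceeds `min_mass_kg` and it was detected at
#' strictly more than `min_stations` stations.
#'
#' @param records independence-filtered detection records.
#' @param stations station table (defines the row order).
#' @param species_meta species table with `species`, `mass_kg`.
#' @param min_stations station-count threshold (strict).
#' @param min_mass_kg body-mass threshold in kg (strict).
#' @return binary matrix, stations as rows (names = station ids),
#'   retained species as columns.
#' @export
build_matrix <- function(records, stations, species_meta,
                         min_stations = 10, min_mass_kg = 1) {
  wild <- records[records$species != "Human", , drop = FALSE]
  sp <- sort(unique(wild$species))
  if (length(sp)) {
    mass <- species_meta$mass_kg[match(sp, species_meta$species)]
    if (anyNA(mass)) {
      stop("species missing from metadata (no mass): ",
           paste(sp[is.na(mass)], collapse = ", "))
    }
  }
  m <- matrix(0L, nrow(stations), length(sp),
              dimnames = list(stations$station_id, sp))
  if (nrow(wild)) {
    hit <- unique(wild[c("station_id", "species")])
    hit <- hit[hit$station_id %in% stations$station_id, , drop = FALSE]
    m[cbind(hit$station_id, hit$species)] <- 1L
  }
  if (length(sp)) {
    n_st <- colSums(m)
    keep <- mass > min_mass_kg & n_st > min_stations
    m <- m[, keep, drop = FALSE]
  }
  m
}
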