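#' Simulation configuration for a synthetic camera-trap community
#'
#' Bundles the ground-truth parameters of the generative model: the
#' fixed-effect matrix `beta_true` (species x covariates, probit
#' scale), the loading coefficient array `lambda_true`
#' (`[k, j, h]` = context covariate k, species j, factor h), circular
#' diel activity kernels per species, and the detection-process
#' settings.  Defaults emulate the dry-season survey the package was
#' designed around: 322 stations, 17 species, 3 latent factors.
#'
#' Species diel kernels are two-component circular mixtures (wrapped
#' normal components centred on night and day); `nocturnal_shift`
#' scales how much a station's human-modification index moves weight
#' onto the night component.
#'
#' @param n_stations,n_species,n_factors community dimensions.
#' @param survey_days nominal detection-stream length per station.
#' @param beta_true species x 5 matrix (intercept, elevation, forest,
#'   human modification, log human presence); defaults are drawn from
#'   the prior ranges typical of montane mammal surveys.
#' @param lambda_true loading coefficient array `[nc_star, S, nf]`
#'   (contexts: intercept, human modification, human presence); the
#'   default gives every species a shared intercept factor plus a
#'   disturbance-strengthened shared factor, so residual associations
#'   grow with disturbance.
#' @param diel_params per-species list with `weights` (length-2,
#'   night/day, summing to 1), `means` (radians, 0 = solar midnight,
#'   pi = solar noon), `kappa` (concentrations, >= 0) and
#'   `nocturnal_shift` (added night weight per unit of scaled direct
#'   human presence; the default gives alternating species -- the
#'   carnivore guild positions -- a positive shift and the rest none).
#' @param base_rate expected independent detections per occupied
#'   station-day.
#' @param seed integer seed for all downstream generators.
#' @return a list of class `"sim_config"`.
#' @export
sim_config <- function(n_stations = 322L, n_species = 17L,
                       n_factors = 3L, survey_days = 134L,
                       beta_true = NULL, lambda_true = NULL,
                       diel_params = NULL, base_rate = 0.06,
                       seed = 1L) {
  stopifnot(n_stations >= 2L, n_species >= 2L, n_factors >= 1L,
            survey_days >= 1L, base_rate >= 0)
  set.seed(as.integer(seed) + 1000L)
  if (is.null(beta_true)) {
    beta_true <- cbind(
      intercept = stats::rnorm(n_species, -0.4, 0.5),
      elevation = stats::rnorm(n_species, 0, 0.4),
      forest = stats::rnorm(n_species, 0.3, 0.3),
      human_modification = stats::rnorm(n_species, 0, 0.4),
      human_presence = stats::rnorm(n_species, 0, 0.3)
    )
  }
  if (is.null(lambda_true)) {
    # factor 1: a community-wide factor whose loadings strengthen with
    # human modification, so positive residual associations accumulate
    # along that gradient; factor 2: a stable two-group contrast;
    # factor 3: a weak human-presence-dependent factor.  Magnitudes
    # vary across species so no true correlation is pinned at +/-1 and
    # loadings stay away from zero over the observed gradient.
    lambda_true <- array(0, c(3L, n_species, n_factors))
    u <- rep_len(c(1.2, 0.9, 1.1, 0.8, 1.0), n_species)
    lambda_true[1L, , 1L] <- 0.6 * u
    lambda_true[2L, , 1L] <- 0.45
    if (n_factors >= 2L) {
      v <- rep_len(c(0.9, 0.7, 0.8, 1.0), n_species)
      lambda_true[1L, , 2L] <- rep_len(c(1, -1), n_species) * 0.8 * v
    }
    if (n_factors >= 3L) {
      lambda_true[1L, , 3L] <- rep_len(c(0.3, -0.3, 0.2), n_species)
      lambda_true[3L, , 3L] <- 0.25
    }
  }
  lambda_true <- as_lambda_array(lambda_true)
  if (is.null(diel_params)) {
    # alternating guilds (carnivore, ungulate, ...): carnivores shift
    # towards nocturnality under direct human presence, ungulates do not
    shifts <- rep_len(c(0.8, 0), n_species)
    diel_params <- lapply(seq_len(n_species), function(j) list(
      weights = c(night = 0.35, day = 0.65),
      means = c(0, pi),
      kappa = c(4, 4),
      nocturnal_shift = shifts[j]
    ))
  }
  for (dp in diel_params) {
    stopifnot(abs(sum(dp$weights) - 1) < 1e-8, all(dp$kappa >= 0))
  }
  structure(list(n_stations = as.integer(n_stations),
                 n_species = as.integer(n_species),
                 n_factors = as.integer(n_factors),
                 survey_days = as.integer(survey_days),
                 beta_true = beta_true, lambda_true = lambda_true,
                 diel_params = diel_params, base_rate = base_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic station table
#'
#' Draws station locations, dry-season operation windows and raw
#' covariates that match the survey statistics the package emulates:
#' the human-modification index is a rescaled Beta on
#' \eqn{[0.04, 0.28]} with mean 0.12 and sd 0.05, and the
#' human-presence detection rate is a zero-inflated lognormal truncated
#' to \eqn{[0, 46.81]} with mean 6.42 and sd 8.61 per 100 camera-days.
#' Elevation is normal, forest cover Beta on \eqn{[0, 1]}.
#'
#' @param n_stations number of stations (at least 2).
#' @param seed integer seed.
#' @return a station table in [read_stations()] layout plus a
#'   `human_presence` column of true detection rates.
#' @export
sim_covariates <- function(n_stations, seed = 1L) {
  if (n_stations < 2L) stop("`n_stations` must be at least 2")
  set.seed(as.integer(seed) + 2000L)
  n <- as.integer(n_stations)

  # human modification: u ~ Beta(a, b) on [0, 1] rescaled to
  # [0.04, 0.28]; (a, b) solve mean 1/3, sd 0.05/0.24 on the unit scale
  m_u <- (0.12 - 0.04) / 0.24
  s_u <- 0.05 / 0.24
  conc <- m_u * (1 - m_u) / s_u^2 - 1
  hm <- 0.04 + 0.24 * stats::rbeta(n, m_u * conc, (1 - m_u) * conc)

  # human presence: zero-inflated (p0 = 0.3) lognormal truncated at
  # 46.81; (mu, sigma) solve the truncated-moment equations so the
  # overall mean is 6.42 and sd 8.61
  mu <- 1.843083331
  sigma <- 1.110168426
  hp <- numeric(n)
  pos <- stats::runif(n) > 0.3
  n_pos <- sum(pos)
  draw <- stats::rlnorm(n_pos, mu, sigma)
  while (any(draw > 46.81)) {
    bad <- draw > 46.81
    draw[bad] <- stats::rlnorm(sum(bad), mu, sigma)
  }
  hp[pos] <- draw

  start <- as.Date("2020-11-01") + sample.int(45L, n, replace = TRUE) - 1L
  effort <- pmin(147L, pmax(89L, round(stats::rnorm(n, 134, 12))))

  data.frame(
    station_id = sprintf("ST%03d", seq_len(n)),
    latitude = stats::runif(n, 29, 30),
    longitude = stats::runif(n, 94.5, 96),
    start_date = start,
    end_date = start + effort - 1L,
    elevation = stats::rnorm(n, 2500, 700),
    forest_cover = stats::rbeta(n, 5, 2),
    human_modification = hm,
    human_presence = hp,
    stringsAsFactors = FALSE
  )
}

#' Generate ground-truth occupancy from the latent-factor model
#'
#' Standardizes the covariates, draws latent scores \eqn{z_{ih} \sim
#' N(0, 1)}, forms \eqn{\eta = X \beta^T + \Lambda(x^*_i) z_i} and
#' occupancy \eqn{y_{ij} \sim Bern(\Phi(\eta_{ij}))}.  The returned
#' truth object carries `true_R(x_star)`, the exact residual
#' correlation matrix implied by `lambda_true` at any context.
#'
#' @param config a [sim_config()].
#' @param stations a station table from [sim_covariates()] (or real
#'   data in the same layout).
#' @return a list of class `"sim_truth"` with elements `config`,
#'   `stations`, `covariates` (standardized table), `z`, `psi`,
#'   `occupancy` and the function `true_R`.
#' @export
sim_community <- function(config, stations) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(stations) != config$n_stations) {
    stop("station table rows must match config$n_stations")
  }
  covariates <- transform_covariates(stations, stations$human_presence)
  dm <- design_matrices(covariates,
                        c("human_modification", "human_presence"))
  S <- config$n_species; nf <- config$n_factors
  if (!identical(dim(config$beta_true), c(S, ncol(dm$x)))) {
    stop("beta_true must be ", S, " x ", ncol(dm$x))
  }
  if (!identical(dim(config$lambda_true),
                 c(ncol(dm$x_star), S, nf))) {
    stop("lambda_true must be ", ncol(dm$x_star), " x ", S, " x ", nf)
  }
  set.seed(config$seed + 3000L)
  n <- config$n_stations
  z <- matrix(stats::rnorm(n * nf), n, nf)
  eta <- linear_predictor(config$beta_true, config$lambda_true, z,
                          dm$x, dm$x_star)
  psi <- stats::pnorm(eta)
  y <- matrix(stats::rbinom(n * S, 1L, psi), n, S)
  sp_names <- sprintf("SP%02d", seq_len(S))
  dimnames(y) <- list(stations$station_id, sp_names)
  dimnames(psi) <- dimnames(y)
  lambda_true <- config$lambda_true
  true_R <- function(x_star) {
    association_matrix(loadings_at(lambda_true, x_star))
  }
  structure(list(config = config, stations = stations,
                 covariates = covariates, z = z, psi = psi,
                 occupancy = y, species = sp_names, true_R = true_R,
                 x_star = dm$x_star),
            class = "sim_truth")
}

#' Generate a time-stamped detection stream
#'
#' For every occupied station-species cell, daily detection counts are
#' Poisson with mean `base_rate` over the station's operation window;
#' each detection receives a clock time drawn from the species'
#' circular diel kernel, with the night-component weight increased by
#' `nocturnal_shift` times the station's scaled human-presence rate
#' (rate per 100 camera-days divided by 50), emulating fear-driven
#' shifts towards nocturnality near people.
#' Records of the special species `"Human"` are appended at each
#' station's true human-presence rate so the stream round-trips
#' through the full preparation workflow.  When the expected count
#' `base_rate * survey_days` is at least 20, an occupied cell is
#' guaranteed at least one record.
#'
#' @param truth a `sim_truth` from [sim_community()].
#' @param include_humans append `"Human"` records.
#' @return detection records (`station_id`, `species`, `timestamp`)
#'   sorted by station then time; timestamps are `POSIXct` in UTC+6.
#' @export
sim_detections <- function(truth, include_humans = TRUE) {
  stopifnot(inherits(truth, "sim_truth"))
  config <- truth$config
  set.seed(config$seed + 4000L)
  st <- truth$stations
  tz <- "Etc/GMT-6"
  out_station <- character(0); out_species <- character(0)
  out_time <- numeric(0)

  day_starts <- function(i) {
    n_days <- as.numeric(st$end_date[i] - st$start_date[i]) + 1
    n_days <- min(n_days, config$survey_days)
    as.numeric(as.POSIXct(paste(st$start_date[i], "00:00:00"),
                          tz = tz)) + 86400 * (seq_len(n_days) - 1)
  }

  for (i in seq_len(nrow(st))) {
    starts <- day_starts(i)
    occ <- which(truth$occupancy[i, ] == 1L)
    for (j in occ) {
      counts <- stats::rpois(length(starts), config$base_rate)
      total <- sum(counts)
      if (total == 0L &&
          config$base_rate * length(starts) >= 20) {
        day <- sample.int(length(starts), 1L)
        counts[day] <- 1L
        total <- 1L
      }
      if (total == 0L) next
      days <- rep(starts, counts)
      # diel disturbance: direct human presence, scaled to [0, ~1]
      ang <- diel_draw(config$diel_params[[j]], total,
                       st$human_presence[i] / 50)
      out_station <- c(out_station, rep(st$station_id[i], total))
      out_species <- c(out_species, rep(truth$species[j], total))
      out_time <- c(out_time, days + ang / (2 * pi) * 86400)
    }
    if (include_humans && st$human_presence[i] > 0) {
      lam_day <- st$human_presence[i] / 100
      counts <- stats::rpois(length(starts), lam_day)
      total <- sum(counts)
      if (total > 0L) {
        days <- rep(starts, counts)
        hrs <- stats::runif(total, 8, 18) / 24 * 2 * pi  # people by day
        out_station <- c(out_station, rep(st$station_id[i], total))
        out_species <- c(out_species, rep("Human", total))
        out_time <- c(out_time, days + hrs / (2 * pi) * 86400)
      }
    }
  }
  ts <- as.POSIXct(out_time, origin = "1970-01-01", tz = tz)
  out <- data.frame(station_id = out_station, species = out_species,
                    timestamp = ts, stringsAsFactors = FALSE)
  out <- out[order(out$station_id, out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Draw clock-time angles in [0, 2pi) from a two-component wrapped
# normal mixture; disturbance moves weight onto the night component.
diel_draw <- function(dp, n, disturbance) {
  w_night <- min(0.95, max(0.05, dp$weights[1L] +
                           dp$nocturnal_shift * disturbance))
  comp <- ifelse(stats::runif(n) < w_night, 1L, 2L)
  sd <- 1 / sqrt(pmax(dp$kappa[comp], 1e-6))
  (dp$means[comp] + stats::rnorm(n) * sd) %% (2 * pi)
}

#' Write a simulated dataset to CSV plus a ground-truth JSON
#'
#' Emits `detections.csv`, `stations.csv`, `species.csv` (synthetic
#' body masses > 1 kg, carnivore/ungulate guilds) and `truth.json`
#' (beta, lambda, and `true_R` evaluated at the min/mean/max
#' human-modification contexts).  All files round-trip through the
#' package readers.
#'
#' @param truth a `sim_truth`.
#' @param records detection records from [sim_detections()].
#' @param dir output directory (created if needed).
#' @return invisibly, the file paths.
#' @export
write_simulation <- function(truth, records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(truth$config$seed + 5000L)
  det <- records
  det$timestamp <- format(det$timestamp, "%Y-%m-%dT%H:%M:%S+0600")
  paths <- c(detections = file.path(dir, "detections.csv"),
             stations = file.path(dir, "stations.csv"),
             species = file.path(dir, "species.csv"),
             truth = file.path(dir, "truth.json"))
  utils::write.csv(det, paths[["detections"]], row.names = FALSE)
  st <- truth$stations
  st$human_presence <- NULL   # derived downstream from the records
  utils::write.csv(st, paths[["stations"]], row.names = FALSE)
  S <- truth$config$n_species
  sp <- data.frame(
    species = truth$species,
    mass_kg = round(exp(stats::runif(S, log(1.5), log(120))), 1),
    guild = rep_len(c("carnivore", "ungulate"), S),
    stringsAsFactors = FALSE
  )
  utils::write.csv(sp, paths[["species"]], row.names = FALSE)
  hm <- truth$x_star[, "human_modification_z"]
  ctx <- list(min = min(hm), mean = mean(hm), max = max(hm))
  truths <- list(
    beta_true = truth$config$beta_true,
    lambda_true = truth$config$lambda_true,
    true_R = lapply(ctx, function(v) {
      truth$true_R(c(1, v, 0))
    })
  )
  jsonlite::write_json(truths, paths[["truth"]], digits = NA,
                       matrix = "rowmajor")
  invisible(paths)
}
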