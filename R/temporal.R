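#' Split stations into low- and high-disturbance strata
#'
#' Ranks stations by a disturbance metric and returns the 25% least
#' disturbed (`low`) and 25% most disturbed (`high`) station ids.
#' Ties spanning a cut are resolved by rank with stable station-id
#' ordering, so strata are reproducible; each stratum holds
#' `ceiling(n * quantile)` stations.
#'
#' @param stations station table.
#' @param metric `"human_presence"` or `"human_modification"`; the
#'   named column must exist in `stations` unless `values` is given.
#' @param quantile stratum size as a fraction of stations.
#' @param values optional explicit metric values (one per station),
#'   overriding the column lookup.
#' @return list with character vectors `low` and `high`.
#' @export
disturbance_strata <- function(stations,
                               metric = c("human_presence",
                                          "human_modification"),
                               quantile = 0.25, values = NULL) {
  metric <- match.arg(metric)
  if (is.null(values)) {
    if (!metric %in% names(stations)) {
      stop("station table has no `", metric, "` column; pass `values`")
    }
    values <- stations[[metric]]
  }
  n <- nrow(stations)
  if (n < 4L) stop("at least four stations are required")
  if (length(values) != n) stop("`values` must have one entry per station")
  if (max(values) == min(values)) {
    stop("disturbance metric is constant across stations; ",
         "strata are undefined")
  }
  k <- ceiling(n * quantile)
  asc <- order(values, stations$station_id)
  desc <- order(-values, stations$station_id)
  list(low = stations$station_id[asc[seq_len(k)]],
       high = stations$station_id[desc[seq_len(k)]])
}

#' Nocturnality shift between disturbance strata
#'
#' For each species with at least `min_detections` usable (non-
#' crepuscular) detections in *both* strata, computes the difference in
#' nocturnal proportion (high minus low).  Guild-level effects are the
#' mean of the member species' differences, with a bootstrap confidence
#' interval obtained by resampling detections within species and
#' stratum (`n_boot` replicates); a two-proportion z-test p-value is
#' reported per species alongside.
#'
#' @param records_low,records_high detection records carrying a
#'   `diel_class` column (see [diel_annotate()]) for the low and high
#'   strata.
#' @param species_meta species table with `species` and `guild`.
#' @param min_detections per-stratum detection threshold, applied
#'   after crepuscular exclusion.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @param conf confidence level of the equal-tailed interval.
#' @return list with data frames `species` (per-species proportions,
#'   difference, CI, z-test p-value) and `guilds` (per-guild and
#'   combined mean difference with bootstrap CI and `significant`
#'   flag).  Guilds with no qualifying species are dropped with a
#'   warning.
#' @export
nocturnality_shift <- function(records_low, records_high, species_meta,
                               min_detections = 30L, n_boot = 10000L,
                               seed = 1L, conf = 0.95) {
  usable <- function(r) r[r$diel_class != "crepuscular_excluded", ,
                          drop = FALSE]
  lo <- usable(records_low); hi <- usable(records_high)
  sp <- intersect(unique(lo$species), unique(hi$species))
  sp <- setdiff(sp, "Human")
  stat <- lapply(sp, function(s) {
    nl <- sum(lo$species == s); nh <- sum(hi$species == s)
    if (nl < min_detections || nh < min_detections) return(NULL)
    kl <- sum(lo$species == s & lo$diel_class == "nocturnal")
    kh <- sum(hi$species == s & hi$diel_class == "nocturnal")
    data.frame(species = s, n_low = nl, n_high = nh,
               p_low = kl / nl, p_high = kh / nh,
               difference = kh / nh - kl / nl,
               stringsAsFactors = FALSE)
  })
  stat <- do.call(rbind, stat)
  if (is.null(stat) || nrow(stat) == 0L) {
    warning("no species passed the detection threshold in both strata")
    return(list(species = NULL, guilds = NULL))
  }
  stat$guild <- species_meta$guild[match(stat$species,
                                         species_meta$species)]
  ## two-proportion z-test (normal approximation, no continuity corr.)
  p_pool <- (stat$p_low * stat$n_low + stat$p_high * stat$n_high) /
    (stat$n_low + stat$n_high)
  se <- sqrt(p_pool * (1 - p_pool) *
             (1 / stat$n_low + 1 / stat$n_high))
  z <- ifelse(se > 0, stat$difference / se, 0)
  stat$p_value <- 2 * stats::pnorm(-abs(z))

  ## bootstrap within species x stratum; resampling detections with
  ## replacement is a binomial redraw of the nocturnal count
  set.seed(as.integer(seed))
  nsp <- nrow(stat)
  boot_diff <- matrix(NA_real_, n_boot, nsp)
  for (i in seq_len(nsp)) {
    bl <- stats::rbinom(n_boot, stat$n_low[i], stat$p_low[i]) /
      stat$n_low[i]
    bh <- stats::rbinom(n_boot, stat$n_high[i], stat$p_high[i]) /
      stat$n_high[i]
    boot_diff[, i] <- bh - bl
  }
  alpha <- (1 - conf) / 2
  groups <- c(sort(unique(stat$guild)), "all")
  guilds <- lapply(groups, function(g) {
    cols <- if (g == "all") seq_len(nsp) else which(stat$guild == g)
    if (!length(cols)) return(NULL)
    bm <- rowMeans(boot_diff[, cols, drop = FALSE])
    ci <- stats::quantile(bm, c(alpha, 1 - alpha), names = FALSE)
    data.frame(guild = g, n_species = length(cols),
               mean_difference = mean(stat$difference[cols]),
               ci_lower = ci[1L], ci_upper = ci[2L],
               n_boot = as.integer(n_boot),
               significant = ci[1L] > 0 | ci[2L] < 0,
               stringsAsFactors = FALSE)
  })
  guilds <- do.call(rbind, guilds)
  list(species = stat, guilds = guilds)
}

#' Time between successive detections of different species
#'
#' Within each station that detected at least two species, records are
#' sorted by time and every consecutive pair of records belonging to
#' *different* species yields one encounter interval in days (plus its
#' natural log).  Consecutive same-species records yield nothing.
#' Simultaneous cross-species timestamps are replaced by a configurable
#' floor (default one minute) with a warning.
#'
#' @param records independence-filtered detection records.
#' @param stations_subset optional character vector of station ids to
#'   restrict to (e.g. one stratum from [disturbance_strata()]).
#' @param floor_days minimum interval assigned to simultaneous
#'   detections.
#' @return data frame with `station_id`, `species_a`, `species_b`,
#'   `delta_days`, `log_delta`; zero rows if no station qualifies.
#' @export
time_to_encounter <- function(records, stations_subset = NULL,
                              floor_days = 1 / 1440) {
  r <- records[records$species != "Human", , drop = FALSE]
  if (!is.null(stations_subset)) {
    r <- r[r$station_id %in% stations_subset, , drop = FALSE]
  }
  r <- r[order(r$station_id, r$timestamp), , drop = FALSE]
  out <- list()
  n_floored <- 0L
  for (sid in unique(r$station_id)) {
    rows <- r[r$station_id == sid, , drop = FALSE]
    if (length(unique(rows$species)) < 2L) next
    sp <- rows$species
    dt <- diff(as.numeric(rows$timestamp)) / 86400
    cross <- sp[-length(sp)] != sp[-1L]
    if (!any(cross)) next
    d <- dt[cross]
    floored <- d <= 0
    n_floored <- n_floored + sum(floored)
    d[floored] <- floor_days
    out[[sid]] <- data.frame(
      station_id = sid,
      species_a = sp[-length(sp)][cross],
      species_b = sp[-1L][cross],
      delta_days = d, log_delta = log(d),
      stringsAsFactors = FALSE)
  }
  if (n_floored > 0L) {
    warning(n_floored, " simultaneous cross-species timestamp(s) ",
            "floored to ", format(floor_days), " days")
  }
  if (!length(out)) {
    return(data.frame(station_id = character(), species_a = character(),
                      species_b = character(), delta_days = numeric(),
                      log_delta = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Bootstrap contrast of two sets of values
#'
#' Estimates `mean(values_high) - mean(values_low)` with a percentile
#' bootstrap confidence interval: each arm is resampled with
#' replacement at its own size `n_boot` times.  Used for the
#' (log-scale) time-to-encounter contrast between disturbance strata.
#'
#' @param values_low,values_high numeric vectors (non-empty).
#' @param n_boot bootstrap replicates.
#' @param seed integer seed; results are exactly reproducible.
#' @param conf confidence level.
#' @return list with `mean_difference`, `ci_lower`, `ci_upper`,
#'   `boot_sd`, `n_boot`, `n_low`, `n_high`, `significant` (zero
#'   outside the CI).
#' @export
bootstrap_diff <- function(values_low, values_high, n_boot = 10000L,
                           seed = 1L, conf = 0.95) {
  if (!length(values_low) || !length(values_high)) {
    stop("both value sets must be non-empty")
  }
  set.seed(as.integer(seed))
  nl <- length(values_low); nh <- length(values_high)
  boot <- vapply(seq_len(n_boot), function(b) {
    mean(values_high[sample.int(nh, nh, replace = TRUE)]) -
      mean(values_low[sample.int(nl, nl, replace = TRUE)])
  }, numeric(1))
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(boot, c(alpha, 1 - alpha), names = FALSE)
  est <- mean(values_high) - mean(values_low)
  list(mean_difference = est,
       ci_lower = ci[1L], ci_upper = ci[2L],
       boot_sd = stats::sd(boot),
       n_boot = as.integer(n_boot), n_low = nl, n_high = nh,
       significant = ci[1L] > 0 | ci[2L] < 0)
}
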