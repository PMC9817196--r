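## Synthetic detection-bin generator.
##
## Emulates a multi-year HARP monitoring data set: per site x click type, a
## two-state (active/inactive) bout process with lag-1 persistence modulates
## an inhomogeneous Poisson click-count process on the 5-min bin grid.  One
## additive temporal predictor (diel, seasonal, multi-year, nighttime lunar)
## drives both the log click rate while active and the log-odds of bout
## activity, so the diel and seasonal structure survives into hourly
## presence/absence even when click rates sit far above the retention
## thresholds.  Classifier label noise is injected so that the long-run
## fraction of labelled bins that are true equals the stated precision.  A
## bout process, rather than pure Poisson counts, is used because duty-cycle
## losses are type-specific exactly when detections are clustered in time:
## species with long bouts lose fewer detection-positive minutes to a duty
## cycle than species with scattered single-bin detections.

#' Retention threshold in "true" clicks per 5-min bin for a type class
#'
#' Bins are retained only when their precision-adjusted click count strictly
#' exceeds the class threshold: 50 clicks for delphinids, 20 for beaked
#' whales and Kogia spp. (reflecting their lower clicking rates).
#'
#' @param type_class "delphinid" or "beaked_kogia".
#' @return numeric threshold.
#' @export
binThreshold <- function(type_class) {
  thr <- c(delphinid = 50, beaked_kogia = 20)
  if (!all(type_class %in% names(thr)))
    stop("unknown type_class: ", paste(setdiff(type_class, names(thr)),
                                       collapse = ", "), call. = FALSE)
  unname(thr[type_class])
}

#' Construct a synthetic monitoring scenario
#'
#' @param params data.frame, one row per site x type; see
#'   [SyntheticScenario-class] for required columns.  Missing optional
#'   columns are filled with defaults: `diel_amplitude` 0, `season_amplitude`
#'   0, `lunar_coefficient` 0, `presence_persistence` 0, `occupancy` 0.2,
#'   `precision` 1.
#' @param deployments data.frame with columns `site`, `deployment_id`,
#'   `start`, `end` (POSIXct or ISO-8601 character), `listen_s`, `period_s`,
#'   and optionally `offset_s`, `depth_m`, `sample_rate_hz`.
#' @param yearEffects named list keyed `"site|type"`, each a named numeric
#'   vector of per-year multiplicative rate factors (default: all 1).
#' @param siteCoords data.frame with `site`, `lat`, `lon`; defaults to a
#'   Hawai'i-region location for every site.
#' @param lunarNightOnly apply the lunar term only when the sun is below the
#'   horizon (default TRUE) -- illumination is behaviourally meaningful only
#'   at night.
#' @param seed integer RNG seed.
#' @return a validated [SyntheticScenario-class] object.
#' @export
syntheticScenario <- function(params, deployments, yearEffects = list(),
                              siteCoords = NULL, lunarNightOnly = TRUE,
                              seed = 1L) {
  defaults <- list(diel_peak_hour = 0, diel_amplitude = 0,
                   season_peak_doy = 1, season_amplitude = 0,
                   lunar_coefficient = 0, presence_persistence = 0,
                   occupancy = 0.2, precision = 1)
  for (nm in names(defaults))
    if (is.null(params[[nm]])) params[[nm]] <- defaults[[nm]]
  if (is.character(deployments$start))
    deployments$start <- parsePamTime(deployments$start)
  if (is.character(deployments$end))
    deployments$end <- parsePamTime(deployments$end)
  if (is.null(deployments$offset_s)) deployments$offset_s <- 0
  if (is.null(deployments$depth_m)) deployments$depth_m <- 700
  if (is.null(deployments$sample_rate_hz)) deployments$sample_rate_hz <- 200000
  sites <- unique(params$site)
  if (is.null(siteCoords))
    siteCoords <- data.frame(site = sites, lat = 19.6, lon = -156.0)
  new("SyntheticScenario", sites = sites, types = unique(params$type),
      params = params, yearEffects = yearEffects,
      deployments = deployments, siteCoords = siteCoords,
      lunarNightOnly = lunarNightOnly, seed = as.integer(seed))
}

## Additive temporal predictor (diel + seasonal + year + nighttime lunar)
## for one site x type at given times; `ephem` is the covariate table from
## computeEphemeris() at those times.  The same predictor modulates both the
## log click rate (clicking intensity while active) and the log-odds of the
## bout process being active (acoustic presence), mirroring how diel and
## seasonal behaviour move both bout occurrence and click output.
#' @noRd
temporalPredictor <- function(scenario, prow, ephem) {
  a <- prow$diel_amplitude *
    cos(2 * pi * (ephem$hour_of_day - prow$diel_peak_hour) / 24) +
    prow$season_amplitude *
      cos(2 * pi * (ephem$doy_frac - (prow$season_peak_doy - 1) / 365.25))
  key <- paste(prow$site, prow$type, sep = "|")
  ye <- scenario@yearEffects[[key]]
  if (!is.null(ye)) {
    idx <- match(as.character(ephem$year), names(ye))
    a <- a + log(ifelse(is.na(idx), 1, ye[idx]))
  }
  if (prow$lunar_coefficient != 0) {
    gate <- if (scenario@lunarNightOnly) ephem$sun_altitude < 0 else TRUE
    a <- a + prow$lunar_coefficient * ephem$lunar_fraction * gate
  }
  a
}

## Time-varying bout occupancy: additive predictor on the log-odds scale
#' @noRd
binOccupancy <- function(prow, a) plogis(qlogis(prow$occupancy) + a)

## Two-state bout chain: time-varying marginal occupancy pi_t, lag-1
## persistence rho.  At each step the state is kept with probability rho,
## else redrawn Bernoulli(pi_t).  Vectorised via the redraw positions.
#' @noRd
simulateBoutChain <- function(occupancy, persistence) {
  n <- length(occupancy)
  if (n == 0) return(integer(0))
  redraw <- runif(n) >= persistence
  redraw[1] <- TRUE
  draws <- as.integer(runif(n) < occupancy)
  grp <- cumsum(redraw)
  draws[redraw][grp]
}

#' Simulate labelled 5-min detection bins from a scenario
#'
#' For every (site, type, deployment): evaluates the scenario's additive
#' temporal predictor on the deployment's 5-min bin grid, simulates the
#' bout chain (log-odds of activity shifted by the predictor) and Poisson
#' click counts (log rate shifted by the same predictor), injects
#' false-positive bins at empty slots so that the long-run fraction of
#' labelled bins that are true equals the (site, type) precision, and
#' finally subsamples the bins through the deployment's duty cycle.  Only
#' bins with a positive labelled count are emitted.  Deterministic given
#' the scenario seed.
#'
#' @param scenario a [SyntheticScenario-class].
#' @return named list of [DetectionBins-class] objects, one per
#'   (site, type, deployment), names `"site|type|deployment_id"`.
#' @examples
#' sc <- exampleScenario(n_years = 1, seed = 7)
#' bins <- simulateClickBins(sc)
#' bins[[1]]
#' @export
simulateClickBins <- function(scenario) {
  validObject(scenario)
  deps <- scenario@deployments
  out <- list()
  withSeed(scenario@seed, {
    for (i in seq_len(nrow(deps))) {
      dep <- deps[i, ]
      coords <- scenario@siteCoords[scenario@siteCoords$site == dep$site, ]
      t0 <- as.numeric(dep$start); t1 <- as.numeric(dep$end)
      starts <- seq(ceiling(t0 / 300) * 300, t1 - 1e-9, by = 300)
      starts <- starts[starts + 300 <= t1 + 1e-9]
      times <- as.POSIXct(starts, origin = "1970-01-01", tz = PAM_TZ)
      prows <- scenario@params[scenario@params$site == dep$site, ]
      if (nrow(prows) == 0 || length(times) == 0) next
      ephem <- computeEphemeris(times, coords$lat[1], coords$lon[1])
      for (j in seq_len(nrow(prows))) {
        prow <- prows[j, ]
        a <- temporalPredictor(scenario, prow, ephem)
        lambda <- prow$base_rate * exp(a)
        state <- simulateBoutChain(binOccupancy(prow, a),
                                   prow$presence_persistence)
        counts <- rpois(length(times), lambda) * state
        # classifier label noise: false-positive bins at empty slots
        nTrue <- sum(counts > 0)
        nFalse <- round(nTrue * (1 - prow$precision) / prow$precision)
        empty <- which(counts == 0)
        nFalse <- min(nFalse, length(empty))
        if (nFalse > 0) {
          slots <- if (length(empty) == 1) empty else
            sample(empty, nFalse)
          counts[slots] <- pmax(1, rpois(nFalse, prow$base_rate))
        }
        keep <- counts > 0
        db <- detectionBins(dep$site, dep$deployment_id, prow$type,
                            times[keep], counts[keep])
        cyc <- dutyCycle(dep$listen_s, dep$period_s, dep$offset_s)
        if (!isContinuous(cyc)) db <- applyDutyCycle(db, cyc)
        out[[paste(dep$site, prow$type, dep$deployment_id, sep = "|")]] <- db
      }
    }
  })
  out
}

#' Subsample a detection-bin series through a duty cycle
#'
#' Seconds are recorded when `((t - offset_s) mod period_s) < listen_s`
#' (phase anchored at the epoch, which lies on the 5-min grid).  Bins with
#' no overlap with recorded time are removed; partially overlapping bins are
#' retained with counts thinned in proportion to the recorded fraction of
#' the bin.  A continuous cycle returns the input unchanged.
#'
#' @param series a [DetectionBins-class].
#' @param cycle a [DutyCycleSpec-class].
#' @return a [DetectionBins-class] with the mask applied.
#' @export
applyDutyCycle <- function(series, cycle) {
  validObject(cycle)
  if (isContinuous(cycle)) return(series)
  b <- series@bins
  if (nrow(b) == 0) return(series)
  ov <- recordedOverlap(as.numeric(b$bin_start),
                        as.numeric(b$bin_start) + series@binWidth, cycle)
  keep <- ov > 0
  b <- b[keep, , drop = FALSE]
  b$click_count <- b$click_count * ov[keep] / series@binWidth
  detectionBins(series@site, series@deploymentId, series@type,
                b$bin_start, b$click_count, series@binWidth)
}

## Recorded seconds of the interval [a, b) under a duty cycle.
#' @noRd
recordedOverlap <- function(a, b, cycle) {
  if (isContinuous(cycle)) return(b - a)
  L <- cycle@listen_s; P <- cycle@period_s; off <- cycle@offset_s
  f <- function(t) floor(t / P) * L + pmin(L, t %% P)
  f(b - off) - f(a - off)
}

#' Closed-form ground-truth presence for a scenario
#'
#' Evaluates the scenario's rate model, with no simulation noise, on the
#' 5-min grid of every deployment span: the marginal probability that a bin
#' holds a retained detection is `occupancy(t) * P(Poisson(lambda(t)) > thr)`
#' with `thr` the type-class click threshold; hourly detection probability
#' is the complement of the product over the hour's 12 bins (treating bins
#' as independent -- bout persistence concentrates detections and lowers the
#' realised hourly probability below this marginal form, without moving peak
#' locations); expected detection minutes is 60 times the mean bin
#' probability.  Results are aggregated to the 24-hour diel grid.
#'
#' @param scenario a [SyntheticScenario-class].
#' @return data.frame with columns `site`, `type`, `hour_of_day` (0..23),
#'   `probability` (true hourly detection probability) and
#'   `expected_minutes` (true detection minutes per hour).
#' @export
groundTruth <- function(scenario) {
  validObject(scenario)
  deps <- scenario@deployments
  rows <- list()
  for (i in seq_len(nrow(deps))) {
    dep <- deps[i, ]
    coords <- scenario@siteCoords[scenario@siteCoords$site == dep$site, ]
    t0 <- as.numeric(dep$start); t1 <- as.numeric(dep$end)
    starts <- seq(ceiling(t0 / 300) * 300, t1 - 1e-9, by = 300)
    starts <- starts[starts + 300 <= t1 + 1e-9]
    if (!length(starts)) next
    times <- as.POSIXct(starts, origin = "1970-01-01", tz = PAM_TZ)
    ephem <- computeEphemeris(times, coords$lat[1], coords$lon[1])
    hour <- floor(ephem$hour_of_day)
    hourId <- floor(starts / 3600)
    prows <- scenario@params[scenario@params$site == dep$site, ]
    for (j in seq_len(nrow(prows))) {
      prow <- prows[j, ]
      a <- temporalPredictor(scenario, prow, ephem)
      lambda <- prow$base_rate * exp(a)
      thr <- binThreshold(prow$type_class)
      pBin <- binOccupancy(prow, a) * ppois(thr, lambda, lower.tail = FALSE)
      # hourly probability under bin independence
      logq <- tapply(log1p(-pBin), hourId, sum)
      pHour <- 1 - exp(as.numeric(logq))
      hod <- tapply(hour, hourId, function(h) h[1])
      mins <- 60 * tapply(pBin, hourId, mean)
      rows[[length(rows) + 1]] <- data.frame(
        site = dep$site, type = prow$type, hour_of_day = as.integer(hod),
        probability = pHour, expected_minutes = as.numeric(mins))
    }
  }
  all <- do.call(rbind, rows)
  agg <- aggregate(cbind(probability, expected_minutes) ~
                     site + type + hour_of_day, data = all, FUN = mean)
  agg[order(agg$site, agg$type, agg$hour_of_day), , drop = FALSE]
}

#' A ready-made study-like scenario
#'
#' Three sites, eight click types (six delphinid classes, two beaked/Kogia
#' classes), multi-year deployments mixing continuous and 5-min-on /
#' 10-min-off duty-cycled recording, diel and seasonal structure of varying
#' phase, mild multi-year variation, bout persistence, and classifier
#' precision below 1 for the noisier classes.
#'
#' @param n_years number of years of deployments (default 2).
#' @param start_year first calendar year (default 2015).
#' @param seed integer RNG seed.
#' @return a [SyntheticScenario-class].
#' @export
exampleScenario <- function(n_years = 2, start_year = 2015, seed = 1L) {
  sites <- c("Hawaii", "Kauai", "Manawai")
  types <- data.frame(
    type = c("FKW", "RT", "SFPW", "BMH", "Bb", "Zc", "Sten", "Kogia"),
    type_class = c(rep("delphinid", 5), "beaked_kogia", "delphinid",
                   "beaked_kogia"),
    base_rate = c(120, 200, 250, 180, 60, 70, 400, 55),
    diel_peak_hour = c(10, 2, 1, 23, 13, 8, 0, 13),
    diel_amplitude = c(0.8, 1.0, 0.9, 1.0, 0.4, 0.7, 1.2, 0.6),
    season_peak_doy = c(280, 120, 20, 60, 200, 330, 90, 150),
    season_amplitude = c(0.5, 0.6, 0.4, 0.4, 0.3, 0.5, 0.6, 0.3),
    lunar_coefficient = c(0, 0, 0, -0.4, 0, 0, -0.3, 0),
    presence_persistence = c(0.5, 0.7, 0.7, 0.6, 0.8, 0.7, 0.8, 0.5),
    occupancy = c(0.004, 0.03, 0.04, 0.015, 0.06, 0.03, 0.09, 0.02),
    precision = c(0.55, 0.90, 0.85, 0.80, 0.95, 0.95, 0.90, 0.92))
  params <- do.call(rbind, lapply(sites, function(s)
    cbind(site = s, types)))
  # site-level occupancy contrasts (composition differs among sites)
  adj <- c(Hawaii = 1, Kauai = 0.8, Manawai = 0.7)
  params$occupancy <- pmin(1, params$occupancy * adj[params$site])
  params$occupancy[params$site == "Manawai" & params$type == "Bb"] <- 0.12
  params <- params[!(params$site == "Kauai" & params$type == "Zc"), ]
  deps <- do.call(rbind, lapply(sites, function(s) {
    yrs <- start_year + seq_len(n_years) - 1
    do.call(rbind, lapply(seq_along(yrs), function(k) {
      duty <- s != "Hawaii" && k %% 2 == 0   # alternate duty-cycled years
      data.frame(site = s,
                 deployment_id = sprintf("%s-%02d", s, k),
                 start = parsePamTime(sprintf("%d-01-05T00:00:00", yrs[k])),
                 end = parsePamTime(sprintf("%d-12-20T00:00:00", yrs[k])),
                 listen_s = if (duty) 300 else 900, period_s = 900,
                 offset_s = 0)
    }))
  }))
  coords <- data.frame(site = sites,
                       lat = c(19.58, 21.95, 27.73),
                       lon = c(-156.02, -159.89, -175.60))
  syntheticScenario(params, deps, siteCoords = coords, seed = seed)
}
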