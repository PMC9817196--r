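# Shared fixture builders.  All fixtures are generated in code; no data
# files are stored.

pamT <- function(x) parsePamTime(x)

# a single-site single-type scenario with configurable structure
flatScenario <- function(base_rate = 150, occupancy = 0.3, persistence = 0,
                         precision = 1, diel_amplitude = 0,
                         diel_peak_hour = 0, season_amplitude = 0,
                         season_peak_doy = 1, lunar_coefficient = 0,
                         type_class = "delphinid",
                         start = "2015-01-01T00:00:00",
                         end = "2016-01-01T00:00:00",
                         listen_s = 900, period_s = 900, seed = 1) {
  params <- data.frame(site = "S", type = "T", type_class = type_class,
                       base_rate = base_rate, occupancy = occupancy,
                       presence_persistence = persistence,
                       precision = precision,
                       diel_amplitude = diel_amplitude,
                       diel_peak_hour = diel_peak_hour,
                       season_amplitude = season_amplitude,
                       season_peak_doy = season_peak_doy,
                       lunar_coefficient = lunar_coefficient)
  deps <- data.frame(site = "S", deployment_id = "S-1", start = start,
                     end = end, listen_s = listen_s, period_s = period_s)
  syntheticScenario(params, deps, seed = seed)
}

# DetectionBins on the 5-min grid from second offsets (relative to an
# hour-aligned anchor)
binsAt <- function(offsets_s, counts = 100,
                   anchor = "2015-06-01T00:00:00",
                   site = "S", dep = "S-1", type = "T") {
  t0 <- as.numeric(pamT(anchor))
  detectionBins(site, dep, type,
                as.POSIXct(t0 + offsets_s, origin = "1970-01-01",
                           tz = "Etc/GMT+10"),
                rep_len(counts, length(offsets_s)))
}

# effort record data.frame for one continuous deployment
effortRec <- function(start, end, listen_s = 3600, period_s = 3600,
                      site = "S", dep = "S-1") {
  data.frame(site = site, deployment_id = dep, start = pamT(start),
             end = pamT(end), listen_s = listen_s, period_s = period_s,
             offset_s = 0)
}

# hourly covariates + presence simulated from a cyclic logistic model
simDielSeason <- function(n_hours = 8760, intercept = -2, dielAmp = 2,
                          dielPeak = 13, seasAmp = 2, seasPeak = 180,
                          start = "2015-01-01T00:00:00", seed = 1) {
  h <- seq(pamT(start), by = 3600, length.out = n_hours)
  cov <- computeEphemeris(h, 19.6, -156.0)
  eta <- intercept +
    dielAmp * cos(2 * pi * (cov$hour_of_day - dielPeak) / 24) +
    seasAmp * cos(2 * pi * (cov$doy_frac - (seasPeak - 1) / 365))
  set.seed(seed)
  list(hours = h, cov = cov, eta = eta,
       y = rbinom(n_hours, 1, plogis(eta)))
}

# small fitted cyclic-hour GEE used by several diagnostic tests
fitSmallModel <- function(seed = 30, n = 3000) {
  sim <- simDielSeason(n_hours = n, seasAmp = 0, seed = seed)
  d <- buildDesign(sim$cov,
                   list(smoothSpec("hour_of_day", "cyclic", period = 24)))
  fitGee(sim$y, d, assignClusters(sim$hours, 12))
}

# independent de Boor recursion for M-splines: the test-side oracle
mSplineOracle <- function(x, knots, degree) {
  # knots: full (non-decreasing) knot sequence; returns basis matrix for
  # M-splines of the given degree (order degree + 1)
  k <- degree + 1
  nb <- length(knots) - k
  M <- function(i, ord, t) {
    ti <- knots[i]; tik <- knots[i + ord]
    if (tik <= ti) return(0)
    if (ord == 1) return(as.numeric(t >= ti & t < tik) / (tik - ti))
    (ord * ((t - ti) * M(i, ord - 1, t) +
              (tik - t) * M(i + 1, ord - 1, t))) /
      ((ord - 1) * (tik - ti))
  }
  out <- matrix(0, length(x), nb)
  for (i in seq_len(nb)) for (j in seq_along(x))
    out[j, i] <- M(i, k, x[j])
  out
}
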