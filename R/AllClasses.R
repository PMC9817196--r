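## Central S4 containers.  All timestamps are POSIXct in Hawai'i standard
## time (UTC-10, no DST).

#' DutyCycleSpec: a recording duty-cycle schedule
#'
#' A duty cycle alternates `listen_s` seconds of recording with
#' `period_s - listen_s` seconds of silence, repeating every `period_s`
#' seconds, optionally phase-shifted by `offset_s`.  Continuous recording is
#' represented as `listen_s == period_s`.
#'
#' @slot listen_s seconds recorded per cycle.
#' @slot period_s cycle length in seconds.
#' @slot offset_s phase offset in seconds.
#' @export
setClass("DutyCycleSpec",
         representation(listen_s = "numeric", period_s = "numeric",
                        offset_s = "numeric"),
         prototype(offset_s = 0))

setValidity("DutyCycleSpec", function(object) {
  if (length(object@period_s) != 1 || object@period_s <= 0)
    return("period_s must be a single positive number")
  if (length(object@listen_s) != 1 || object@listen_s <= 0 ||
      object@listen_s > object@period_s)
    return("listen_s must satisfy 0 < listen_s <= period_s")
  if (length(object@offset_s) != 1 || object@offset_s < 0)
    return("offset_s must be a single non-negative number")
  TRUE
})

#' Construct a duty-cycle specification
#'
#' @param listen_s seconds recorded per cycle.
#' @param period_s cycle length in seconds; `listen_s == period_s` means
#'   continuous recording.
#' @param offset_s phase offset in seconds (default 0).
#' @return a [DutyCycleSpec-class] object.
#' @examples
#' dutyCycle(300, 900)        # 5 min on, 10 min off
#' dutyCycle(600, 600)        # continuous
#' @export
dutyCycle <- function(listen_s, period_s, offset_s = 0) {
  new("DutyCycleSpec", listen_s = as.numeric(listen_s),
      period_s = as.numeric(period_s), offset_s = as.numeric(offset_s))
}

#' Is a duty cycle continuous?
#' @param cycle a [DutyCycleSpec-class].
#' @return logical.
#' @export
isContinuous <- function(cycle) cycle@listen_s >= cycle@period_s

#' DetectionBins: 5-minute click-count bins for one click type at one
#' deployment
#'
#' The raw currency of the pipeline: start times of 5-min bins that carried
#' classifier labels of a given click type, with the labelled click count in
#' each bin.  Counts become real-valued after precision adjustment.
#'
#' @slot site site identifier.
#' @slot deploymentId deployment identifier.
#' @slot type click-type identifier.
#' @slot bins data.frame with columns `bin_start` (POSIXct) and
#'   `click_count` (numeric, >= 0), strictly increasing in `bin_start` and
#'   aligned to the 5-min grid.
#' @slot binWidth bin width in seconds (300).
#' @export
setClass("DetectionBins",
         representation(site = "character", deploymentId = "character",
                        type = "character", bins = "data.frame",
                        binWidth = "numeric"),
         prototype(binWidth = 300))

setValidity("DetectionBins", function(object) {
  b <- object@bins
  if (!all(c("bin_start", "click_count") %in% names(b)))
    return("bins must have columns bin_start and click_count")
  if (nrow(b) > 0) {
    if (any(diff(as.numeric(b$bin_start)) <= 0))
      return("bin_start must be strictly increasing")
    if (any(b$click_count < 0))
      return("click_count must be non-negative")
    if (any(as.numeric(b$bin_start) %% object@binWidth != 0))
      return("bin_start must be aligned to the bin-width grid")
  }
  TRUE
})

#' Construct a DetectionBins object
#' @param site site id.
#' @param deploymentId deployment id.
#' @param type click-type id.
#' @param bin_start POSIXct vector of 5-min bin start times.
#' @param click_count numeric vector of labelled click counts.
#' @param binWidth bin width in seconds (default 300).
#' @return a [DetectionBins-class] object.
#' @export
detectionBins <- function(site, deploymentId, type, bin_start, click_count,
                          binWidth = 300) {
  o <- order(bin_start)
  new("DetectionBins", site = site, deploymentId = deploymentId, type = type,
      bins = data.frame(bin_start = bin_start[o],
                        click_count = as.numeric(click_count)[o]),
      binWidth = binWidth)
}

#' HourlyDetections: detection minutes per hour with recording effort
#'
#' The pipeline's central currency: for every hour in a deployment period,
#' the number of minutes credited with detections of a click type and the
#' number of minutes actually recorded.  Hours with `recorded_minutes == 0`
#' are off effort and are excluded from modelling.  After duty-cycle
#' boosting, `detection_minutes` estimates minutes that would have been
#' detected under continuous recording and may exceed `recorded_minutes`
#' (never 60).
#'
#' @slot site site identifier.
#' @slot type click-type identifier.
#' @slot hours data.frame with columns `hour_start` (POSIXct),
#'   `detection_minutes` and `recorded_minutes` (both in \[0, 60\]).
#' @slot boosted has duty-cycle boosting been applied?
#' @export
setClass("HourlyDetections",
         representation(site = "character", type = "character",
                        hours = "data.frame", boosted = "logical"),
         prototype(boosted = FALSE))

setValidity("HourlyDetections", function(object) {
  h <- object@hours
  need <- c("hour_start", "detection_minutes", "recorded_minutes")
  if (!all(need %in% names(h)))
    return("hours must have columns hour_start, detection_minutes, recorded_minutes")
  if (nrow(h) > 0) {
    if (any(h$detection_minutes < 0 | h$detection_minutes > 60 + 1e-9))
      return("detection_minutes must be in [0, 60]")
    if (any(h$recorded_minutes < 0 | h$recorded_minutes > 60 + 1e-9))
      return("recorded_minutes must be in [0, 60]")
    if (any(h$detection_minutes > 0 & h$recorded_minutes == 0))
      return("detection_minutes must be 0 wherever recorded_minutes is 0")
    if (any(duplicated(h$hour_start)))
      return("hour_start must be unique")
  }
  TRUE
})

#' Construct an HourlyDetections object
#' @param site site id.
#' @param type click-type id.
#' @param hour_start POSIXct vector of hour start times.
#' @param detection_minutes numeric in \[0,60\].
#' @param recorded_minutes numeric in \[0,60\].
#' @param boosted logical flag, default FALSE.
#' @return an [HourlyDetections-class] object.
#' @export
hourlyDetections <- function(site, type, hour_start, detection_minutes,
                             recorded_minutes, boosted = FALSE) {
  o <- order(hour_start)
  new("HourlyDetections", site = site, type = type,
      hours = data.frame(hour_start = hour_start[o],
                         detection_minutes = detection_minutes[o],
                         recorded_minutes = recorded_minutes[o]),
      boosted = boosted)
}

#' SyntheticScenario: ground-truth rate model for synthetic detection data
#'
#' Fully parameterised description of the data-generating process used by
#' [simulateClickBins()]: per site x type, a two-state (active/inactive)
#' bout process with lag-1 persistence modulates an inhomogeneous Poisson
#' click-count process.  A single additive temporal predictor -- diel,
#' seasonal, multi-year and (nighttime) lunar terms -- drives both the log
#' click rate while active and the log-odds of the bout process being
#' active, so temporal structure is expressed in hourly presence as well as
#' in click counts.  Classifier label noise is injected so the long-run
#' fraction of labelled bins that are true equals `precision`.
#'
#' @slot sites character vector of site ids.
#' @slot types character vector of click-type ids.
#' @slot params data.frame, one row per site x type, with columns `site`,
#'   `type`, `type_class` ("delphinid" or "beaked_kogia"), `base_rate`
#'   (expected clicks per 5-min bin when active), `diel_peak_hour` (\[0,24)),
#'   `diel_amplitude` (>= 0, log-rate scale), `season_peak_doy` (\[1,366\]),
#'   `season_amplitude` (>= 0), `lunar_coefficient`,
#'   `presence_persistence` (\[0,1)), `occupancy` ((0,1\], the stationary
#'   bout-active probability per 5-min bin when the temporal predictor is
#'   zero) and `precision` ((0,1\]).
#' @slot yearEffects named list keyed "site|type"; each element a named
#'   numeric vector of strictly positive per-year multiplicative factors.
#' @slot deployments data.frame with columns `site`, `deployment_id`,
#'   `start`, `end` (POSIXct), `listen_s`, `period_s`, `offset_s`,
#'   `depth_m`, `sample_rate_hz`.
#' @slot siteCoords data.frame with columns `site`, `lat`, `lon`.
#' @slot lunarNightOnly apply the lunar term only when the sun is below the
#'   horizon (default TRUE).
#' @slot seed integer RNG seed.
#' @export
setClass("SyntheticScenario",
         representation(sites = "character", types = "character",
                        params = "data.frame", yearEffects = "list",
                        deployments = "data.frame", siteCoords = "data.frame",
                        lunarNightOnly = "logical", seed = "integer"),
         prototype(lunarNightOnly = TRUE, seed = 1L))

setValidity("SyntheticScenario", function(object) {
  p <- object@params
  need <- c("site", "type", "type_class", "base_rate", "diel_peak_hour",
            "diel_amplitude", "season_peak_doy", "season_amplitude",
            "lunar_coefficient", "presence_persistence", "occupancy",
            "precision")
  miss <- setdiff(need, names(p))
  if (length(miss)) return(paste("params missing field:", miss[1]))
  if (any(p$base_rate <= 0)) return("invalid field base_rate: must be > 0")
  if (any(p$diel_peak_hour < 0 | p$diel_peak_hour >= 24))
    return("invalid field diel_peak_hour: must be in [0, 24)")
  if (any(p$diel_amplitude < 0))
    return("invalid field diel_amplitude: must be >= 0")
  if (any(p$season_peak_doy < 1 | p$season_peak_doy > 366))
    return("invalid field season_peak_doy: must be in [1, 366]")
  if (any(p$season_amplitude < 0))
    return("invalid field season_amplitude: must be >= 0")
  if (any(p$presence_persistence < 0 | p$presence_persistence >= 1))
    return("invalid field presence_persistence: must be in [0, 1)")
  if (any(p$occupancy <= 0 | p$occupancy > 1))
    return("invalid field occupancy: must be in (0, 1]")
  if (any(p$precision <= 0 | p$precision > 1))
    return("invalid field precision: must be in (0, 1]")
  if (!all(p$type_class %in% c("delphinid", "beaked_kogia")))
    return("invalid field type_class: must be 'delphinid' or 'beaked_kogia'")
  for (ye in object@yearEffects)
    if (any(ye <= 0)) return("invalid field year_effects: must be > 0")
  d <- object@deployments
  if (nrow(d)) {
    if (any(d$end <= d$start))
      return("invalid field deployments: end must follow start")
    for (s in unique(d$site)) {
      ds <- d[d$site == s, ]
      ds <- ds[order(ds$start), ]
      if (nrow(ds) > 1 &&
          any(as.numeric(ds$start[-1]) < as.numeric(ds$end[-nrow(ds)])))
        return("invalid field deployments: overlapping deployments within a site")
    }
  }
  TRUE
})

#' GeeFit: a fitted binomial GEE with independence working correlation
#'
#' Logit-link binomial marginal model fitted by the independence estimating
#' equations (point estimates coincide with the ordinary GLM), retaining
#' both the model-based and the cluster-robust (sandwich) covariance, the
#' blocking-cluster ids, and the term-to-column map and basis metadata
#' needed for term tests, QIC, bootstrap partial fits and diagnostics.
#'
#' @slot coefficients named numeric vector.
#' @slot modelCov model-based covariance (inverse information).
#' @slot robustCov cluster-robust sandwich covariance.
#' @slot clusters cluster id per observation.
#' @slot termMap named list: term -> design-column indices.
#' @slot designInfo list of basis metadata per term (from [buildDesign()]).
#' @slot y binary response.
#' @slot fitted fitted probabilities.
#' @slot X design matrix.
#' @slot converged logical.
#' @slot nObs number of observations.
#' @slot nPresence number of presence (y = 1) hours.
#' @export
setClass("GeeFit",
         representation(coefficients = "numeric", modelCov = "matrix",
                        robustCov = "matrix", clusters = "ANY",
                        termMap = "list", designInfo = "list",
                        y = "numeric", fitted = "numeric", X = "matrix",
                        converged = "logical", nObs = "integer",
                        nPresence = "integer"))

setValidity("GeeFit", function(object) {
  p <- length(object@coefficients)
  if (!all(dim(object@modelCov) == p) || !all(dim(object@robustCov) == p))
    return("covariance dimensions must match coefficient length")
  if (max(abs(object@modelCov - t(object@modelCov))) > 1e-8)
    return("model-based covariance must be symmetric")
  if (max(abs(object@robustCov - t(object@robustCov))) > 1e-8)
    return("robust covariance must be symmetric")
  if (ncol(object@X) != p)
    return("design width must equal coefficient length")
  TRUE
})
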