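## From labelled 5-min bins to duty-cycle-corrected hourly detection
## minutes and hourly presence/absence.
##
## Order of operations: counts are precision-adjusted first, then the strict
## click thresholds are applied at the bin level, bins are rolled up to
## detection minutes per hour against recording effort, duty-cycle losses
## estimated from continuous reference data are used to linearly boost
## duty-cycled hours, and finally types are consolidated and subsites
## merged.

#' Adjust labelled click counts by classifier precision
#'
#' Multiplies every bin count by the (site, type) precision -- the fraction
#' of classifier labels of that type that are true positives -- to
#' approximate the number of "true" clicks per bin.  Counts become
#' real-valued; no rounding is applied.
#'
#' @param bins a [DetectionBins-class].
#' @param precision either a single numeric in (0, 1\] or a data.frame with
#'   columns `site`, `type`, `precision`.
#' @return a [DetectionBins-class] with adjusted counts.
#' @export
adjustCountsByPrecision <- function(bins, precision) {
  if (is.data.frame(precision)) {
    hit <- precision$site == bins@site & precision$type == bins@type
    if (!any(hit))
      stop("no precision entry for site ", bins@site, ", type ", bins@type,
           call. = FALSE)
    precision <- precision$precision[which(hit)[1]]
  }
  stopIfNot(is.numeric(precision) && length(precision) == 1 &&
              precision > 0 && precision <= 1,
            "precision must be a single value in (0, 1]")
  b <- bins@bins
  b$click_count <- b$click_count * precision
  detectionBins(bins@site, bins@deploymentId, bins@type,
                b$bin_start, b$click_count, bins@binWidth)
}

#' Retain bins whose adjusted click count exceeds the class threshold
#'
#' Strict inequality: a delphinid bin needs more than 50 "true" clicks, a
#' beaked-whale or Kogia bin more than 20.  Counts must already be
#' precision-adjusted.
#'
#' @param bins a [DetectionBins-class] with precision-adjusted counts.
#' @param type_class "delphinid" or "beaked_kogia".
#' @return a [DetectionBins-class] with only the retained bins.
#' @export
filterBins <- function(bins, type_class) {
  thr <- binThreshold(type_class)
  b <- bins@bins[bins@bins$click_count > thr, , drop = FALSE]
  detectionBins(bins@site, bins@deploymentId, bins@type,
                b$bin_start, b$click_count, bins@binWidth)
}

#' Roll retained 5-min bins up to detection minutes per hour
#'
#' Every minute of a retained bin is credited with detections, so an hour's
#' detection minutes are 5 times the number of retained bins starting in it,
#' clipped to the recorded minutes of that hour.  Recording effort comes
#' from the deployment records (span plus duty cycle); hours with no
#' recorded time get `recorded_minutes = 0` and are excluded from modelling
#' downstream.  Bins outside any effort interval are dropped with a warning.
#'
#' @param bins a filtered [DetectionBins-class].
#' @param effort data.frame of deployment records with columns `site`,
#'   `deployment_id`, `start`, `end`, `listen_s`, `period_s`, `offset_s`.
#' @return an [HourlyDetections-class] spanning the matching deployments.
#' @export
binsToHourly <- function(bins, effort) {
  eff <- effort[effort$site == bins@site, , drop = FALSE]
  if (!is.null(bins@deploymentId) && bins@deploymentId %in% eff$deployment_id)
    eff <- eff[eff$deployment_id == bins@deploymentId, , drop = FALSE]
  stopIfNot(nrow(eff) > 0, paste("no effort records for site", bins@site))
  if (is.character(eff$start)) eff$start <- parsePamTime(eff$start)
  if (is.character(eff$end)) eff$end <- parsePamTime(eff$end)
  if (is.null(eff$offset_s)) eff$offset_s <- 0
  hr0 <- floor(min(as.numeric(eff$start)) / 3600) * 3600
  hr1 <- ceiling(max(as.numeric(eff$end)) / 3600) * 3600
  hours <- seq(hr0, hr1 - 3600, by = 3600)
  recorded <- numeric(length(hours))
  for (i in seq_len(nrow(eff))) {
    dep <- eff[i, ]
    a <- pmax(hours, as.numeric(dep$start))
    b <- pmin(hours + 3600, as.numeric(dep$end))
    ok <- b > a
    if (!any(ok)) next
    cyc <- dutyCycle(dep$listen_s, dep$period_s, dep$offset_s)
    recorded[ok] <- recorded[ok] + recordedOverlap(a[ok], b[ok], cyc)
  }
  recorded_minutes <- pmin(60, recorded / 60)
  bt <- as.numeric(bins@bins$bin_start)
  inEffort <- vapply(bt, function(t) {
    any(t >= as.numeric(eff$start) & t < as.numeric(eff$end))
  }, logical(1))
  if (any(!inEffort))
    warning(sum(!inEffort), " bins outside any effort interval were dropped")
  bt <- bt[inEffort]
  nBins <- tabulate(match(floor(bt / 3600) * 3600, hours),
                    nbins = length(hours))
  detection_minutes <- pmin(5 * nBins, recorded_minutes)
  hourlyDetections(bins@site, bins@type,
                   as.POSIXct(hours, origin = "1970-01-01", tz = PAM_TZ),
                   detection_minutes, recorded_minutes)
}

#' Estimate the detection-minute loss a duty cycle would cause
#'
#' Subsamples a continuous (reference) retained-bin series through the duty
#' cycle at every 5-min phase offset over the cycle period, rebuilds total
#' detection minutes, and reports the mean fraction of detection minutes
#' lost relative to the continuous series.  Averaging over offsets removes
#' phase-alignment artifacts.
#'
#' @param bins a [DetectionBins-class] (or list of them, pooled) of retained
#'   bins from continuous deployments of one site x type.
#' @param cycle the [DutyCycleSpec-class] to evaluate.
#' @return data.frame row with `site`, `type`, `listen_s`, `period_s`,
#'   `missed_fraction` and `n_reference_hours`.
#' @export
estimateDutyCycleLoss <- function(bins, cycle) {
  validObject(cycle)
  if (is(bins, "DetectionBins")) bins <- list(bins)
  stopIfNot(length(bins) > 0 && all(vapply(bins, is, logical(1),
                                           "DetectionBins")),
            "bins must be DetectionBins from continuous deployments")
  site <- bins[[1]]@site; type <- bins[[1]]@type
  bt <- sort(unlist(lapply(bins, function(b) as.numeric(b@bins$bin_start))))
  stopIfNot(length(bt) > 0,
            paste("no continuous reference detections for site", site,
                  "- use the loss from the nearest site with data"))
  if (isContinuous(cycle))
    return(data.frame(site = site, type = type, listen_s = cycle@listen_s,
                      period_s = cycle@period_s, missed_fraction = 0,
                      n_reference_hours = length(unique(floor(bt / 3600)))))
  total <- 5 * length(bt)
  offsets <- seq(0, cycle@period_s - 300, by = 300)
  lost <- vapply(offsets, function(off) {
    cyc <- dutyCycle(cycle@listen_s, cycle@period_s, off)
    ov <- recordedOverlap(bt, bt + 300, cyc)
    1 - sum(5 * ov / 300) / total
  }, numeric(1))
  data.frame(site = site, type = type, listen_s = cycle@listen_s,
             period_s = cycle@period_s, missed_fraction = mean(lost),
             n_reference_hours = length(unique(floor(bt / 3600))))
}

#' Linearly boost duty-cycled detection minutes
#'
#' Inverts the expected retention of a duty cycle: detection minutes are
#' divided by `1 - missed_fraction` and capped at 60 min/h.  Zeros stay
#' zero: boosting never creates presence where no bin was retained.
#'
#' @param hourly an [HourlyDetections-class] from a duty-cycled deployment.
#' @param loss a row from [estimateDutyCycleLoss()] or a single numeric
#'   missed fraction in \[0, 1).
#' @return the boosted [HourlyDetections-class] (flag `boosted` set).
#' @export
boostCounts <- function(hourly, loss) {
  mf <- if (is.data.frame(loss)) loss$missed_fraction[1] else loss
  stopIfNot(is.numeric(mf) && mf >= 0, "missed_fraction must be >= 0")
  if (mf >= 1)
    stop("missed_fraction >= 1: degenerate correction", call. = FALSE)
  h <- hourly@hours
  h$detection_minutes <- pmin(60, h$detection_minutes / (1 - mf))
  new("HourlyDetections", site = hourly@site, type = hourly@type,
      hours = h, boosted = TRUE)
}

#' Consolidate click types into analysis groups
#'
#' For [DetectionBins-class] input, merging is a union at the 5-min bin
#' level: a bin is detection-positive for the group if it was retained for
#' any member type (counts are summed per bin but each bin is credited only
#' once downstream).  For [HourlyDetections-class] input, group detection
#' minutes are `min(60, sum)` across member types on a shared hour grid.
#'
#' @param series named or unnamed list of [DetectionBins-class] or
#'   [HourlyDetections-class] objects sharing a site.
#' @param mapping named character vector: type -> group.
#' @return list of merged objects, one per group (per deployment for bin
#'   input).
#' @export
consolidateTypes <- function(series, mapping) {
  types <- vapply(series, typeId, character(1))
  unknown <- setdiff(types, names(mapping))
  if (length(unknown))
    stop("mapping has no entry for type: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  groups <- mapping[types]
  out <- list()
  if (all(vapply(series, is, logical(1), "DetectionBins"))) {
    key <- paste(groups, vapply(series, function(x) x@deploymentId,
                                character(1)), sep = "|")
    for (k in unique(key)) {
      members <- series[key == k]
      g <- groups[key == k][1]
      allBins <- do.call(rbind, lapply(members, binTable))
      agg <- aggregate(click_count ~ bin_start, data = allBins, FUN = sum)
      out[[k]] <- detectionBins(members[[1]]@site,
                                members[[1]]@deploymentId, unname(g),
                                agg$bin_start, agg$click_count)
    }
  } else if (all(vapply(series, is, logical(1), "HourlyDetections"))) {
    for (g in unique(groups)) {
      members <- series[groups == g]
      grid <- hourTable(members[[1]])$hour_start
      for (m in members[-1])
        stopIfNot(identical(as.numeric(hourTable(m)$hour_start),
                            as.numeric(grid)),
                  "hourly series must share a time grid for consolidation")
      dm <- pmin(60, Reduce(`+`, lapply(members, detectionMinutes)))
      rm_ <- Reduce(pmax, lapply(members, recordedMinutes))
      out[[g]] <- hourlyDetections(members[[1]]@site, unname(g), grid, dm,
                                   rm_,
                                   boosted = any(vapply(members,
                                                        function(m) m@boosted,
                                                        logical(1))))
    }
  } else stop("series must be all DetectionBins or all HourlyDetections",
              call. = FALSE)
  out
}

#' Merge subsite (or per-deployment) hourly series under one site id
#'
#' Deployment periods of the inputs are normally non-overlapping, in which
#' case the series are simply concatenated.  Where hours overlap, presence
#' is the union and minutes the maximum.
#'
#' @param series list of [HourlyDetections-class] of one type.
#' @param merged_site_id site id for the merged series.
#' @return an [HourlyDetections-class].
#' @export
mergeSubsites <- function(series, merged_site_id) {
  stopIfNot(length(series) >= 1, "need at least one series")
  all <- do.call(rbind, lapply(series, hourTable))
  agg <- aggregate(cbind(detection_minutes, recorded_minutes) ~ hour_start,
                   data = all, FUN = max)
  hourlyDetections(merged_site_id, series[[1]]@type, agg$hour_start,
                   agg$detection_minutes, agg$recorded_minutes,
                   boosted = any(vapply(series, function(m) m@boosted,
                                        logical(1))))
}

#' Hourly binary presence from detection minutes
#'
#' An on-effort hour scores 1 if any detection minutes were credited, 0
#' otherwise; off-effort hours are excluded from the output.
#'
#' @param hourly an [HourlyDetections-class].
#' @return data.frame with columns `hour_start`, `presence` (0/1).
#' @export
hourlyPresence <- function(hourly) {
  h <- hourly@hours[hourly@hours$recorded_minutes > 0, , drop = FALSE]
  data.frame(hour_start = h$hour_start,
             presence = as.integer(h$detection_minutes > 0))
}
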