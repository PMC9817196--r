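## Plain-text interchange: detection-bin CSV, deployment-metadata YAML,
## precision CSV, hourly-timeseries CSV, ground-truth CSV.

#' Write detection bins to CSV
#'
#' Columns: `site`, `deployment_id`, `type`, `bin_start_iso` (ISO-8601 with
#' the fixed -10:00 offset), `click_count`.
#'
#' @param bins a [DetectionBins-class] or list of them.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeDetectionBinsCsv <- function(bins, path) {
  if (is(bins, "DetectionBins")) bins <- list(bins)
  rows <- lapply(bins, function(b) {
    if (nrow(b@bins) == 0) return(NULL)
    data.frame(site = b@site, deployment_id = b@deploymentId, type = b@type,
               bin_start_iso = formatPamTime(b@bins$bin_start),
               click_count = b@bins$click_count)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read detection bins from CSV
#'
#' @param path CSV written by [writeDetectionBinsCsv()] (or matching its
#'   columns).
#' @return named list of [DetectionBins-class], keys
#'   `"site|type|deployment_id"`.
#' @export
readDetectionBinsCsv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE,
                colClasses = c(site = "character",
                               deployment_id = "character",
                               type = "character",
                               bin_start_iso = "character"))
  need <- c("site", "deployment_id", "type", "bin_start_iso", "click_count")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("detection-bin CSV missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  d$bin_start <- parsePamTime(d$bin_start_iso)
  key <- paste(d$site, d$type, d$deployment_id, sep = "|")
  out <- lapply(split(d, key), function(g)
    detectionBins(g$site[1], g$deployment_id[1], g$type[1],
                  g$bin_start, g$click_count))
  out
}

#' Write deployment metadata to YAML
#'
#' One record per deployment with the fields `site`, `deployment_id`,
#' `start`, `end`, `listen_s`, `period_s`, `offset_s`, `depth_m`,
#' `sample_rate_hz`.
#'
#' @param deployments deployment data.frame (e.g. the `deployments` slot of
#'   a [SyntheticScenario-class]).
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeDeploymentYaml <- function(deployments, path) {
  recs <- lapply(seq_len(nrow(deployments)), function(i) {
    d <- deployments[i, ]
    list(site = d$site, deployment_id = d$deployment_id,
         start = formatPamTime(d$start), end = formatPamTime(d$end),
         listen_s = d$listen_s, period_s = d$period_s,
         offset_s = if (is.null(d$offset_s)) 0 else d$offset_s,
         depth_m = if (is.null(d$depth_m)) NA else d$depth_m,
         sample_rate_hz = if (is.null(d$sample_rate_hz)) NA
                          else d$sample_rate_hz)
  })
  yaml::write_yaml(list(deployments = recs), path)
  invisible(path)
}

#' Read deployment metadata from YAML
#'
#' @param path YAML written by [writeDeploymentYaml()].
#' @return data.frame of deployment records with POSIXct `start`/`end`.
#' @export
readDeploymentYaml <- function(path) {
  recs <- yaml::read_yaml(path)$deployments
  out <- do.call(rbind, lapply(recs, function(r)
    data.frame(site = r$site, deployment_id = r$deployment_id,
               start = r$start, end = r$end, listen_s = r$listen_s,
               period_s = r$period_s, offset_s = r$offset_s,
               depth_m = r$depth_m, sample_rate_hz = r$sample_rate_hz)))
  out$start <- parsePamTime(out$start)
  out$end <- parsePamTime(out$end)
  out
}

#' Read a classifier precision table from CSV
#'
#' @param path CSV with columns `site`, `type`, `precision`.
#' @return data.frame.
#' @export
readPrecisionCsv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("site", "type", "precision"), names(d))
  if (length(miss))
    stop("precision CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  stopIfNot(all(d$precision > 0 & d$precision <= 1),
            "precision values must be in (0, 1]")
  d
}

#' Write hourly detection timeseries to CSV
#'
#' Columns: `site`, `type`, `hour_start_iso`, `detection_minutes`,
#' `recorded_minutes`, `presence` (blank off effort).
#'
#' @param hourly an [HourlyDetections-class] or list of them.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeHourlyCsv <- function(hourly, path) {
  if (is(hourly, "HourlyDetections")) hourly <- list(hourly)
  rows <- lapply(hourly, function(h) {
    tb <- hourTable(h)
    data.frame(site = siteId(h), type = typeId(h),
               hour_start_iso = formatPamTime(tb$hour_start),
               detection_minutes = tb$detection_minutes,
               recorded_minutes = tb$recorded_minutes,
               presence = ifelse(tb$recorded_minutes > 0,
                                 as.integer(tb$detection_minutes > 0), NA))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
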