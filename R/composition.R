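## Site- and season-level species composition: percent of recording days
## with detections, seasonal changes, Bray-Curtis focal-site comparison and
## weekly detection summaries.

#' Assign calendar seasons
#'
#' Winter is January-March, spring April-June, summer July-September, fall
#' October-December.
#'
#' @param dates Date, POSIXct, or anything `as.POSIXlt` accepts.
#' @return factor with levels winter, spring, summer, fall.
#' @examples
#' assignSeason(as.Date(c("2015-02-15", "2015-04-01", "2015-12-31")))
#' @export
assignSeason <- function(dates) {
  m <- as.POSIXlt(dates, tz = PAM_TZ)$mon + 1
  factor(c("winter", "spring", "summer", "fall")[(m - 1) %/% 3 + 1],
         levels = c("winter", "spring", "summer", "fall"))
}

#' Percent of recording days with detections, by site and type
#'
#' A recording day is a calendar day with at least one on-effort hour at the
#' site; it counts as detection-positive for a type when any of its
#' on-effort hours has presence.  The percentage of recording days with
#' detections serves as the abundance proxy for compositional analysis.
#'
#' @param series list of [HourlyDetections-class] objects (all types at all
#'   sites; effort is shared within a site).
#' @param by_season also split by season? (default FALSE)
#' @return data.frame with columns `site`, `type`, optionally `season`,
#'   `percent_days`, `n_recording_days`.
#' @export
percentDays <- function(series, by_season = FALSE) {
  rows <- lapply(series, function(s) {
    h <- hourTable(s)
    on <- h$recorded_minutes > 0
    data.frame(site = siteId(s), type = typeId(s),
               day = as.Date(h$hour_start[on], tz = PAM_TZ),
               det = h$detection_minutes[on] > 0)
  })
  all <- do.call(rbind, rows)
  all$season <- if (by_season) assignSeason(all$day) else
    factor("overall", levels = "overall")
  out <- list()
  for (sea in levels(all$season)) {
    a <- all[all$season == sea, , drop = FALSE]
    for (site in unique(a$site)) {
      asite <- a[a$site == site, , drop = FALSE]
      recDays <- unique(asite$day)   # effort shared across types at a site
      if (length(recDays) == 0)
        stop("zero recording days at site ", site, call. = FALSE)
      for (type in unique(asite$type)) {
        at <- asite[asite$type == type, , drop = FALSE]
        pos <- unique(at$day[at$det])
        out[[length(out) + 1]] <- data.frame(
          site = site, type = type, season = sea,
          percent_days = 100 * length(pos) / length(recDays),
          n_recording_days = length(recDays))
      }
    }
  }
  out <- do.call(rbind, out)
  if (!by_season) out$season <- NULL
  out
}

#' Season-to-season changes in percent presence
#'
#' For each site x type, the change in percent recording days with
#' detections between consecutive seasons, cyclically: SpSu (summer minus
#' spring), SuFa, FaWi and WiSp (spring minus winter).  Changes of magnitude
#' greater than 10 percentage points are flagged.
#'
#' @param comp a by-season table from `percentDays(..., by_season = TRUE)`.
#' @param flag_threshold magnitude that flags a change (default 10).
#' @return data.frame with `site`, `type`, `transition`, `change`, `flagged`.
#' @export
seasonalDifference <- function(comp, flag_threshold = 10) {
  trans <- list(SpSu = c("spring", "summer"), SuFa = c("summer", "fall"),
                FaWi = c("fall", "winter"), WiSp = c("winter", "spring"))
  out <- list()
  for (site in unique(comp$site)) for (type in unique(comp$type)) {
    ct <- comp[comp$site == site & comp$type == type, , drop = FALSE]
    for (tr in names(trans)) {
      from <- ct$percent_days[ct$season == trans[[tr]][1]]
      to <- ct$percent_days[ct$season == trans[[tr]][2]]
      if (!length(from) || !length(to)) {
        warning("season missing for ", site, "/", type, ": ", tr, " omitted")
        next
      }
      ch <- to - from
      out[[length(out) + 1]] <- data.frame(
        site = site, type = type, transition = tr, change = ch,
        flagged = abs(ch) > flag_threshold)
    }
  }
  do.call(rbind, out)
}

#' Bray-Curtis similarity between two abundance vectors
#'
#' `1 - sum(|x - y|) / sum(x + y) = 2 * sum(pmin(x, y)) / sum(x + y)`:
#' one when the same species are present in the same numbers, zero when the
#' sites share no species.  The complementary dissimilarity is `1 -`
#' similarity.
#'
#' @param x,y non-negative numeric vectors of equal length (e.g. percent
#'   recording days per type), not both all-zero.
#' @return similarity in \[0, 1\].
#' @examples
#' brayCurtisSimilarity(c(90, 62), c(79, 82))  # 2*(79+62)/313
#' @export
brayCurtisSimilarity <- function(x, y) {
  stopIfNot(length(x) == length(y), "x and y must have equal length")
  stopIfNot(all(x >= 0) && all(y >= 0), "entries must be non-negative")
  tot <- sum(x + y)
  stopIfNot(tot > 0, "x and y must not both be all-zero")
  2 * sum(pmin(x, y)) / tot
}

#' Bray-Curtis comparison of every site against a focal site
#'
#' Builds site x type abundance vectors (percent recording days) over the
#' common type set -- types absent at a site enter as zero, not dropped --
#' and reports the Bray-Curtis similarity (and dissimilarity) of each site
#' against the focal site, overall and, if a by-season table is supplied,
#' per season.
#'
#' @param comp table from [percentDays()]; may include a `season` column.
#' @param focal_site focal site id.
#' @return data.frame with `focal`, `site`, `season`, `similarity`,
#'   `dissimilarity`.
#' @export
focalSiteComparison <- function(comp, focal_site) {
  stopIfNot(focal_site %in% comp$site,
            paste("focal site", focal_site, "absent from composition table"))
  if (is.null(comp$season)) comp$season <- "overall"
  types <- sort(unique(comp$type))
  out <- list()
  for (sea in unique(comp$season)) {
    cs <- comp[comp$season == sea, , drop = FALSE]
    vec <- function(site) {
      v <- cs$percent_days[cs$site == site][match(types,
                                                  cs$type[cs$site == site])]
      ifelse(is.na(v), 0, v)
    }
    if (!focal_site %in% cs$site) next
    xf <- vec(focal_site)
    for (site in unique(cs$site)) {
      sim <- brayCurtisSimilarity(xf, vec(site))
      out[[length(out) + 1]] <- data.frame(
        focal = focal_site, site = site, season = sea,
        similarity = sim, dissimilarity = 1 - sim)
    }
  }
  do.call(rbind, out)
}

#' Weekly detection-hour summary across years
#'
#' Weeks are 7-day blocks counted from January 1 (week 52 absorbs the final
#' 1-2 days of the year).  Detection hours are summed within each year --
#' deliberately not normalised by effort -- then averaged across the years
#' that had any recording effort in that week; the standard error is
#' `sd / sqrt(n_years)`, reported as 0 with a flag when only one year is
#' available.
#'
#' @param hourly an [HourlyDetections-class].
#' @return data.frame with `site`, `type`, `week`, `mean_hours`, `se_hours`,
#'   `n_years`, `single_year`.
#' @export
weeklySummary <- function(hourly) {
  h <- hourTable(hourly)
  lt <- as.POSIXlt(h$hour_start, tz = PAM_TZ)
  week <- pmin(52L, lt$yday %/% 7L + 1L)
  year <- lt$year + 1900L
  on <- h$recorded_minutes > 0
  det <- h$detection_minutes > 0 & on
  effort <- tapply(on, list(year, week), any)
  hours <- tapply(det, list(year, week), sum)
  out <- list()
  for (w in sort(unique(week))) {
    wc <- as.character(w)
    yrs <- rownames(effort)[!is.na(effort[, wc]) & effort[, wc]]
    if (!length(yrs)) next
    v <- hours[yrs, wc]
    v[is.na(v)] <- 0
    se <- if (length(v) > 1) sd(v) / sqrt(length(v)) else 0
    out[[length(out) + 1]] <- data.frame(
      site = siteId(hourly), type = typeId(hourly), week = w,
      mean_hours = mean(v), se_hours = se, n_years = length(v),
      single_year = length(v) == 1)
  }
  do.call(rbind, out)
}
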