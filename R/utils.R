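## Small internal helpers shared across modules.

#' Run code with a temporary RNG seed, restoring the caller's RNG state
#' @noRd
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(code)
}

#' Parse ISO-8601 timestamps into POSIXct in Hawai'i standard time
#'
#' Timestamps are stored throughout in local standard time UTC-10 with no
#' daylight saving ("Etc/GMT+10").
#'
#' @param x character vector of ISO-8601 timestamps.
#' @return POSIXct vector in the package time zone.
#' @export
parsePamTime <- function(x) {
  out <- as.POSIXct(x, tz = PAM_TZ, format = "%Y-%m-%dT%H:%M:%S")
  bad <- is.na(out) & !is.na(x)
  if (any(bad))
    out[bad] <- as.POSIXct(x[bad], tz = PAM_TZ)
  out
}

#' Format POSIXct as ISO-8601 with the fixed -10:00 offset
#' @param x POSIXct vector.
#' @return character vector.
#' @export
formatPamTime <- function(x) {
  format(as.POSIXct(x, tz = PAM_TZ), "%Y-%m-%dT%H:%M:%S-10:00")
}

#' @noRd
daysInYear <- function(year) {
  ifelse((year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0, 366L, 365L)
}

#' Shortest distance between two points on a circle of given period
#' @noRd
circularDistance <- function(a, b, period) {
  d <- abs(a - b) %% period
  pmin(d, period - d)
}

#' Floor POSIXct to a grid of `width` seconds
#' @noRd
floorToGrid <- function(t, width) {
  as.POSIXct(floor(as.numeric(t) / width) * width,
             origin = "1970-01-01", tz = PAM_TZ)
}

#' @noRd
stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
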