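## Generics and simple accessors / show methods for the S4 containers.

#' Site identifier of a pamgee object
#' @param x a DetectionBins or HourlyDetections object.
#' @return character site id.
#' @export
setGeneric("siteId", function(x) standardGeneric("siteId"))

#' Click-type identifier of a pamgee object
#' @param x a DetectionBins or HourlyDetections object.
#' @return character type id.
#' @export
setGeneric("typeId", function(x) standardGeneric("typeId"))

#' 5-min bin table of a DetectionBins object
#' @param x a DetectionBins object.
#' @return data.frame with bin_start, click_count.
#' @export
setGeneric("binTable", function(x) standardGeneric("binTable"))

#' Hour table of an HourlyDetections object
#' @param x an HourlyDetections object.
#' @return data.frame with hour_start, detection_minutes, recorded_minutes.
#' @export
setGeneric("hourTable", function(x) standardGeneric("hourTable"))

#' Detection minutes per hour
#' @param x an HourlyDetections object.
#' @return numeric vector.
#' @export
setGeneric("detectionMinutes", function(x) standardGeneric("detectionMinutes"))

#' Recorded (effort) minutes per hour
#' @param x an HourlyDetections object.
#' @return numeric vector.
#' @export
setGeneric("recordedMinutes", function(x) standardGeneric("recordedMinutes"))

#' Model-based covariance of a fitted GEE
#' @param x a GeeFit object.
#' @return covariance matrix.
#' @export
setGeneric("modelCov", function(x) standardGeneric("modelCov"))

#' Cluster-robust (sandwich) covariance of a fitted GEE
#' @param x a GeeFit object.
#' @return covariance matrix.
#' @export
setGeneric("robustCov", function(x) standardGeneric("robustCov"))

#' Term-to-column map of a fitted GEE
#' @param x a GeeFit object.
#' @return named list of design-column indices.
#' @export
setGeneric("termMap", function(x) standardGeneric("termMap"))

#' Number of presence hours underlying a fitted GEE
#' @param x a GeeFit object.
#' @return integer.
#' @export
setGeneric("nPresence", function(x) standardGeneric("nPresence"))

#' @describeIn siteId site of a DetectionBins object
#' @export
setMethod("siteId", "DetectionBins", function(x) x@site)
#' @describeIn siteId site of an HourlyDetections object
#' @export
setMethod("siteId", "HourlyDetections", function(x) x@site)
#' @describeIn typeId type of a DetectionBins object
#' @export
setMethod("typeId", "DetectionBins", function(x) x@type)
#' @describeIn typeId type of an HourlyDetections object
#' @export
setMethod("typeId", "HourlyDetections", function(x) x@type)
#' @describeIn binTable bin table of a DetectionBins object
#' @export
setMethod("binTable", "DetectionBins", function(x) x@bins)
#' @describeIn hourTable hour table of an HourlyDetections object
#' @export
setMethod("hourTable", "HourlyDetections", function(x) x@hours)
#' @describeIn detectionMinutes detection minutes of an HourlyDetections
#' @export
setMethod("detectionMinutes", "HourlyDetections",
          function(x) x@hours$detection_minutes)
#' @describeIn recordedMinutes recorded minutes of an HourlyDetections
#' @export
setMethod("recordedMinutes", "HourlyDetections",
          function(x) x@hours$recorded_minutes)

#' @describeIn modelCov model-based covariance of a GeeFit
#' @export
setMethod("modelCov", "GeeFit", function(x) x@modelCov)
#' @describeIn robustCov robust covariance of a GeeFit
#' @export
setMethod("robustCov", "GeeFit", function(x) x@robustCov)
#' @describeIn termMap term map of a GeeFit
#' @export
setMethod("termMap", "GeeFit", function(x) x@termMap)
#' @describeIn nPresence presence hours of a GeeFit
#' @export
setMethod("nPresence", "GeeFit", function(x) x@nPresence)

#' Coefficients of a fitted GEE
#' @param object a GeeFit object.
#' @param ... ignored.
#' @return named numeric vector.
#' @export
setMethod("coef", "GeeFit", function(object, ...) object@coefficients)

#' Fitted probabilities of a fitted GEE
#' @param object a GeeFit object.
#' @param ... ignored.
#' @return numeric vector of fitted probabilities.
#' @export
setMethod("fitted", "GeeFit", function(object, ...) object@fitted)

setMethod("show", "DutyCycleSpec", function(object) {
  if (isContinuous(object))
    cat("DutyCycleSpec: continuous (", object@period_s, "s period )\n")
  else
    cat(sprintf("DutyCycleSpec: %g s on / %g s off (period %g s, offset %g s)\n",
                object@listen_s, object@period_s - object@listen_s,
                object@period_s, object@offset_s))
})

setMethod("show", "DetectionBins", function(object) {
  cat(sprintf("DetectionBins: site %s, deployment %s, type %s\n",
              object@site, object@deploymentId, object@type))
  cat(sprintf("  %d labelled 5-min bins", nrow(object@bins)))
  if (nrow(object@bins))
    cat(sprintf(" spanning %s .. %s",
                formatPamTime(min(object@bins$bin_start)),
                formatPamTime(max(object@bins$bin_start))))
  cat("\n")
})

setMethod("show", "HourlyDetections", function(object) {
  h <- object@hours
  cat(sprintf("HourlyDetections: site %s, type %s%s\n", object@site,
              object@type, if (object@boosted) " (duty-cycle boosted)" else ""))
  cat(sprintf("  %d hours, %d on effort, %d with detections\n", nrow(h),
              sum(h$recorded_minutes > 0), sum(h$detection_minutes > 0)))
})

setMethod("show", "SyntheticScenario", function(object) {
  cat(sprintf("SyntheticScenario: %d sites x %d types, %d deployments, seed %d\n",
              length(object@sites), length(object@types),
              nrow(object@deployments), object@seed))
})

setMethod("show", "GeeFit", function(object) {
  cat("GeeFit: binomial GEE (logit link, independence working correlation)\n")
  cat(sprintf("  n = %d observations in %d clusters; %d presence hours\n",
              object@nObs, length(unique(object@clusters)), object@nPresence))
  cat(sprintf("  terms: %s\n",
              paste(setdiff(names(object@termMap), "(Intercept)"),
                    collapse = ", ")))
})
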