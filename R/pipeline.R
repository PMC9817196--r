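## Pipeline orchestration: configuration, stage wiring, model gating,
## output tables and the run manifest.

#' Assemble a pipeline configuration
#'
#' Holds the inputs and the fixed analysis constants: the bin retention
#' thresholds (more than 50 true clicks for delphinids, more than 20 for
#' beaked whales and Kogia spp.), the 100 detection-hour modelling gate, the
#' 0.1 residual-autocorrelation blocking cutoff and the 0.05 significance
#' level, plus spline settings and seeds.
#'
#' @param outdir output directory.
#' @param scenario optional [SyntheticScenario-class]; when supplied the
#'   pipeline simulates its own input data.
#' @param bins_csv,deployments_yaml,precision_csv,covariates_csv input file
#'   paths (used when no scenario is given; `covariates_csv` optionally
#'   overrides computed ephemeris values).
#' @param type_classes named character vector type -> "delphinid" or
#'   "beaked_kogia".
#' @param type_map optional named vector consolidating types into groups.
#' @param subsite_map optional named vector mapping subsite ids to merged
#'   site ids.
#' @param site_coords data.frame `site`, `lat`, `lon`.
#' @param focal_site focal site for the Bray-Curtis comparison.
#' @param include_lunar offer lunar illumination (form chosen by QIC) as a
#'   model candidate (default TRUE).
#' @param min_detection_hours modelling gate (strictly more than this many
#'   detection hours; default 100).
#' @param acf_cutoff residual-autocorrelation blocking cutoff (default 0.1).
#' @param alpha term-significance cutoff (default 0.05).
#' @param year_smooth_min_years offer a year smooth only when a site spans
#'   more than this many years (default 5).
#' @param n_knots,degree spline settings (default 4 knots, cubic).
#' @param n_boot bootstrap draws for partial-fit bands (default 1000).
#' @param seed integer seed for all stochastic steps.
#' @return a list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(outdir, scenario = NULL, bins_csv = NULL,
                           deployments_yaml = NULL, precision_csv = NULL,
                           covariates_csv = NULL, type_classes = NULL,
                           type_map = NULL, subsite_map = NULL,
                           site_coords = NULL, focal_site = NULL,
                           include_lunar = TRUE, min_detection_hours = 100,
                           acf_cutoff = 0.1, alpha = 0.05,
                           year_smooth_min_years = 5, n_knots = 4,
                           degree = 3, n_boot = 1000, seed = 1L) {
  stopIfNot(min_detection_hours > 0 && acf_cutoff > 0 && alpha > 0,
            "thresholds must be positive")
  if (is.null(scenario)) {
    for (f in c(bins_csv, deployments_yaml, precision_csv))
      if (!is.null(f) && !file.exists(f))
        stop("configured input file does not exist: ", f, call. = FALSE)
    stopIfNot(!is.null(bins_csv) && !is.null(deployments_yaml),
              "need either a scenario or bins_csv + deployments_yaml")
  }
  structure(list(outdir = outdir, scenario = scenario, bins_csv = bins_csv,
                 deployments_yaml = deployments_yaml,
                 precision_csv = precision_csv,
                 covariates_csv = covariates_csv,
                 type_classes = type_classes, type_map = type_map,
                 subsite_map = subsite_map, site_coords = site_coords,
                 focal_site = focal_site, include_lunar = include_lunar,
                 min_detection_hours = min_detection_hours,
                 acf_cutoff = acf_cutoff, alpha = alpha,
                 year_smooth_min_years = year_smooth_min_years,
                 n_knots = n_knots, degree = degree, n_boot = n_boot,
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [pipelineConfig()] arguments.
#' @return a `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  for (nm in c("type_classes", "type_map", "subsite_map"))
    if (!is.null(y[[nm]])) y[[nm]] <- unlist(y[[nm]])
  if (!is.null(y$site_coords)) y$site_coords <- as.data.frame(y$site_coords)
  do.call(pipelineConfig, y)
}

#' Modelling gate: which site x type series have enough detection hours?
#'
#' Temporal models are evaluated only where the number of detection-positive
#' on-effort hours strictly exceeds the gate (100 by default); the rest are
#' reported as "<gate" rows.
#'
#' @param series list of [HourlyDetections-class].
#' @param min_detection_hours the gate (default 100).
#' @return data.frame with `site`, `type`, `detection_hours`, `eligible`.
#' @export
modelGate <- function(series, min_detection_hours = 100) {
  out <- do.call(rbind, lapply(series, function(h) {
    p <- hourlyPresence(h)
    data.frame(site = siteId(h), type = typeId(h),
               detection_hours = sum(p$presence))
  }))
  out$eligible <- out$detection_hours > min_detection_hours
  rownames(out) <- NULL
  out
}

## Preprocess all deployments of one site x type into a boosted hourly
## series.  Losses for duty-cycled deployments come from the site's
## continuous deployments; if the site has none, the nearest site with
## continuous data for the type is used, with a warning.
#' @noRd
preprocessSiteType <- function(binsList, site, type, effort, precision,
                               type_class) {
  keys <- vapply(binsList, function(b)
    b@site == site && b@type == type, logical(1))
  mine <- binsList[keys]
  if (!length(mine)) return(NULL)
  filtered <- lapply(mine, function(b)
    filterBins(adjustCountsByPrecision(b, precision), type_class))
  eff <- effort[effort$site == site, , drop = FALSE]
  contIds <- eff$deployment_id[eff$listen_s >= eff$period_s]
  hourlyPerDep <- list()
  for (b in filtered) {
    dep <- eff[eff$deployment_id == b@deploymentId, , drop = FALSE]
    if (nrow(dep) == 0) next
    h <- binsToHourly(b, dep)
    if (dep$listen_s[1] < dep$period_s[1]) {
      cyc <- dutyCycle(dep$listen_s[1], dep$period_s[1], dep$offset_s[1])
      ref <- filtered[vapply(filtered, function(x)
        x@deploymentId %in% contIds, logical(1))]
      if (!length(ref)) {
        others <- binsList[vapply(binsList, function(x)
          x@site != site && x@type == type, logical(1))]
        othEff <- effort[match(vapply(others, function(x) x@deploymentId,
                                      character(1)),
                               effort$deployment_id), , drop = FALSE]
        others <- others[othEff$listen_s >= othEff$period_s]
        stopIfNot(length(others) > 0,
                  paste("no continuous reference data anywhere for type",
                        type))
        warning("no continuous reference data at ", site, " for ", type,
                "; using loss from another site")
        ref <- lapply(others, function(b2)
          filterBins(adjustCountsByPrecision(b2, precision), type_class))
      }
      loss <- estimateDutyCycleLoss(ref, cyc)
      h <- boostCounts(h, loss)
    }
    hourlyPerDep[[b@deploymentId]] <- h
  }
  if (!length(hourlyPerDep)) return(NULL)
  mergeSubsites(hourlyPerDep, site)
}

## p-value band labels used in the model-results table
#' @noRd
pBand <- function(p) {
  ifelse(p < 0.001, "<.001",
         ifelse(p < 0.01, "<.01", ifelse(p < 0.05, "<.05", "ns")))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order -- simulate (when the config holds a
#' scenario), preprocess, composition, temporal models, report -- writing
#' every artifact as CSV (plus figures) under the configured output
#' directory together with a manifest of inputs, seeds and versions.
#'
#' @param config a [pipelineConfig()].
#' @param stages character vector of stages to run (default all).
#' @return invisibly, a list with the in-memory results of each stage.
#' @export
runPipeline <- function(config,
                        stages = c("simulate", "preprocess", "compose",
                                   "model", "report")) {
  stopIfNot(inherits(config, "PipelineConfig"), "config must be a PipelineConfig")
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  withStage <- function(name, expr) {
    message("[", name, "] starting")
    tryCatch(expr,
             error = function(e) stop("stage '", name, "' failed: ",
                                      conditionMessage(e), call. = FALSE))
  }

  ## -- inputs -------------------------------------------------------------
  if (!is.null(config$scenario) && "simulate" %in% stages) {
    res$bins <- withStage("simulate", simulateClickBins(config$scenario))
    effort <- config$scenario@deployments
    precision <- unique(config$scenario@params[, c("site", "type",
                                                   "precision")])
    typeClasses <- setNames(config$scenario@params$type_class,
                            config$scenario@params$type)
    typeClasses <- typeClasses[!duplicated(names(typeClasses))]
    siteCoords <- config$scenario@siteCoords
    writeDetectionBinsCsv(res$bins, file.path(config$outdir,
                                              "detection_bins.csv"))
    writeDeploymentYaml(effort, file.path(config$outdir, "deployments.yaml"))
    write.csv(groundTruth(config$scenario),
              file.path(config$outdir, "ground_truth.csv"),
              row.names = FALSE)
    message("[simulate] ", length(res$bins), " bin series written")
  } else {
    res$bins <- withStage("load", readDetectionBinsCsv(config$bins_csv))
    effort <- readDeploymentYaml(config$deployments_yaml)
    stopIfNot(!is.null(config$precision_csv),
              "precision_csv is required when no scenario is given")
    precision <- readPrecisionCsv(config$precision_csv)
    typeClasses <- config$type_classes
    siteCoords <- config$site_coords
  }
  stopIfNot(!is.null(typeClasses), "type_classes are required")

  ## -- preprocess ---------------------------------------------------------
  if ("preprocess" %in% stages) {
    res$hourly <- withStage("preprocess", {
      combos <- unique(data.frame(
        site = vapply(res$bins, siteId, character(1)),
        type = vapply(res$bins, typeId, character(1))))
      out <- list()
      for (i in seq_len(nrow(combos))) {
        h <- preprocessSiteType(res$bins, combos$site[i], combos$type[i],
                                effort, precision,
                                typeClasses[[combos$type[i]]])
        if (!is.null(h))
          out[[paste(combos$site[i], combos$type[i], sep = "|")]] <- h
      }
      if (!is.null(config$type_map)) {
        bySite <- split(out, vapply(out, siteId, character(1)))
        out <- list()
        for (sl in bySite) {
          merged <- consolidateTypes(sl, config$type_map)
          for (g in names(merged))
            out[[paste(siteId(merged[[g]]), g, sep = "|")]] <- merged[[g]]
        }
      }
      if (!is.null(config$subsite_map)) {
        grp <- paste(config$subsite_map[vapply(out, siteId, character(1))],
                     vapply(out, typeId, character(1)), sep = "|")
        out <- lapply(split(out, grp), function(sl)
          mergeSubsites(sl, config$subsite_map[[siteId(sl[[1]])]]))
      }
      out
    })
    writeHourlyCsv(res$hourly, file.path(config$outdir,
                                         "hourly_timeseries.csv"))
    message("[preprocess] ", length(res$hourly), " hourly series, ",
            sum(vapply(res$hourly, function(h)
              nrow(hourTable(h)), integer(1))), " hours")
  }

  ## -- composition --------------------------------------------------------
  if ("compose" %in% stages) {
    res$composition <- withStage("compose", {
      overall <- percentDays(res$hourly)
      bySeason <- percentDays(res$hourly, by_season = TRUE)
      focal <- if (!is.null(config$focal_site)) config$focal_site else
        overall$site[1]
      both <- rbind(cbind(overall, season = "overall"), bySeason)
      list(overall = overall, by_season = bySeason,
           seasonal_diff = seasonalDifference(bySeason),
           bray_curtis = focalSiteComparison(both, focal),
           weekly = do.call(rbind, lapply(res$hourly, weeklySummary)))
    })
    write.csv(rbind(cbind(res$composition$overall, season = "overall"),
                    res$composition$by_season),
              file.path(config$outdir, "composition.csv"), row.names = FALSE)
    write.csv(res$composition$seasonal_diff,
              file.path(config$outdir, "seasonal_differences.csv"),
              row.names = FALSE)
    write.csv(res$composition$bray_curtis,
              file.path(config$outdir, "bray_curtis.csv"), row.names = FALSE)
    write.csv(res$composition$weekly,
              file.path(config$outdir, "weekly_summary.csv"),
              row.names = FALSE)
    message("[compose] composition tables written")
  }

  ## -- models -------------------------------------------------------------
  if ("model" %in% stages) {
    res$models <- withStage("model", {
      gate <- modelGate(res$hourly, config$min_detection_hours)
      fits <- list()
      for (key in names(res$hourly)) {
        h <- res$hourly[[key]]
        g <- gate[gate$site == siteId(h) & gate$type == typeId(h), ]
        if (!g$eligible[1]) next
        co <- if (!is.null(siteCoords) && siteId(h) %in% siteCoords$site)
          siteCoords[siteCoords$site == siteId(h), ] else
          data.frame(lat = 19.6, lon = -156.0)
        pres <- hourlyPresence(h)
        override <- if (!is.null(config$covariates_csv))
          read.csv(config$covariates_csv, stringsAsFactors = FALSE) else NULL
        cov <- computeEphemeris(pres$hour_start, co$lat[1], co$lon[1],
                                override = override)
        y <- pres$presence
        specs <- list(
          smoothSpec("hour_of_day", "cyclic", period = 24,
                     n_knots = config$n_knots, degree = config$degree),
          smoothSpec("doy_frac", "cyclic", period = 1,
                     n_knots = config$n_knots, degree = config$degree))
        span <- diff(range(cov$year_frac))
        if (span > config$year_smooth_min_years)
          specs <- c(specs, list(smoothSpec("year_frac", "open",
                                            n_knots = config$n_knots,
                                            degree = config$degree)))
        lunarForm <- NULL
        fullSpecs <- specs
        d0 <- buildDesign(cov, fullSpecs)
        lag0 <- blockingTimestep(y, d0$X, cutoff = config$acf_cutoff)
        cl0 <- assignClusters(pres$hour_start, lag0)
        if (config$include_lunar) {
          lunarForm <- chooseLunarForm(y, cov, cl0,
                                       n_knots = config$n_knots,
                                       degree = config$degree)
          fullSpecs <- c(fullSpecs, list(
            if (lunarForm$form == "linear")
              smoothSpec("lunar_fraction", "linear")
            else smoothSpec("lunar_fraction", "open",
                            n_knots = config$n_knots,
                            degree = config$degree)))
        }
        d <- buildDesign(cov, fullSpecs)
        lag <- blockingTimestep(y, d$X, cutoff = config$acf_cutoff)
        clusters <- assignClusters(pres$hour_start, lag)
        sel <- backwardSelection(y, cov, clusters, fullSpecs,
                                 alpha = config$alpha)
        pf <- if (!sel$intercept_only)
          do.call(rbind, lapply(sel$order$term, function(tm)
            cbind(site = siteId(h), type = typeId(h),
                  bootstrapPartialFit(sel$model, tm,
                                      n_boot = config$n_boot,
                                      seed = config$seed)))) else NULL
        br <- binnedResiduals(sel$model)
        fits[[key]] <- list(site = siteId(h), type = typeId(h),
                            lag = lag, lunar = lunarForm, selection = sel,
                            partial_fits = pf, binned = br,
                            tjur = tjurR2(sel$model))
      }
      list(gate = gate, fits = fits)
    })
    ## model-results table (one row per site x type x term)
    rows <- list()
    for (f in res$models$fits) {
      sel <- f$selection
      if (sel$intercept_only) next
      t <- sel$tests
      t <- t[match(sel$order$term, t$term), ]
      rows[[length(rows) + 1]] <- data.frame(
        site = f$site, type = f$type, term = t$term,
        p_value = t$p_value, p_band = pBand(t$p_value), df = t$df,
        chi2 = t$chi2, rank = sel$order$rank, n_pres = nPresence(sel$model),
        blocking_lag_h = f$lag)
    }
    gateRows <- res$models$gate[!res$models$gate$eligible, , drop = FALSE]
    if (nrow(gateRows))
      rows[[length(rows) + 1]] <- data.frame(
        site = gateRows$site, type = gateRows$type, term = NA,
        p_value = NA, p_band = sprintf("<=%d detection hours",
                                       config$min_detection_hours),
        df = NA, chi2 = NA, rank = NA, n_pres = gateRows$detection_hours,
        blocking_lag_h = NA)
    res$models$results_table <- do.call(rbind, rows)
    write.csv(res$models$results_table,
              file.path(config$outdir, "model_results.csv"),
              row.names = FALSE)
    evalTab <- do.call(rbind, lapply(res$models$fits, function(f)
      data.frame(site = f$site, type = f$type,
                 n_pres = nPresence(f$selection$model),
                 percent_res = f$binned$percent_within_bounds,
                 tjur_r2 = f$tjur)))
    res$models$evaluation_table <- evalTab
    write.csv(evalTab, file.path(config$outdir, "model_evaluation.csv"),
              row.names = FALSE)
    pfAll <- do.call(rbind, lapply(res$models$fits,
                                   function(f) f$partial_fits))
    if (!is.null(pfAll))
      write.csv(pfAll, file.path(config$outdir, "partial_fits.csv"),
                row.names = FALSE)
    message("[model] ", length(res$models$fits), " models fitted, ",
            sum(!res$models$gate$eligible), " combos below the gate")
  }

  ## -- report -------------------------------------------------------------
  if ("report" %in% stages) {
    res$figures <- withStage("report",
                             renderReports(res, config$outdir))
    message("[report] ", length(res$figures), " figures written")
  }

  ## -- manifest -----------------------------------------------------------
  outFiles <- list.files(config$outdir, full.names = TRUE)
  outFiles <- outFiles[!grepl("manifest\\.yaml$", outFiles)]
  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("pamgee")),
    outputs = lapply(outFiles, function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f)))))
  yaml::write_yaml(manifest, file.path(config$outdir, "manifest.yaml"))
  invisible(res)
}
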