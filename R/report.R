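## Figure rendering: weekly detection panels, percent-days bars,
## Bray-Curtis tiles and partial-fit panels with significance annotations.

#' Render report figures from pipeline results
#'
#' Produces the standard figure set -- weekly mean detection hours per site,
#' percent-days-with-detections bars, Bray-Curtis similarity tiles, and
#' partial-fit panels annotated with model order (1st..) and significance
#' stars -- and writes them as PNG files when an output directory is given.
#' Stages whose results are missing are skipped with a warning.  Layout is
#' deterministic.
#'
#' @param results result list from [runPipeline()] (needs `composition`
#'   and/or `models`).
#' @param outdir optional directory for PNG output.
#' @return named list of ggplot objects, invisibly.
#' @export
renderReports <- function(results, outdir = NULL) {
  figs <- list()
  comp <- results$composition
  if (is.null(comp)) {
    warning("composition results missing; skipping composition figures")
  } else {
    figs$weekly <- ggplot2::ggplot(comp$weekly,
        ggplot2::aes(x = week, y = mean_hours)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(0, mean_hours - se_hours),
                                        ymax = mean_hours + se_hours),
                           fill = "grey70") +
      ggplot2::geom_line() +
      ggplot2::facet_grid(type ~ site, scales = "free_y") +
      ggplot2::labs(x = "Week of year",
                    y = "Mean detection hours per week (± SE)") +
      ggplot2::theme_bw()
    figs$percent_days <- ggplot2::ggplot(comp$overall,
        ggplot2::aes(x = type, y = percent_days,
                     fill = percent_days > 50)) +
      ggplot2::geom_col() +
      ggplot2::scale_fill_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "darkgreen"),
                                 guide = "none") +
      ggplot2::facet_wrap(~site) +
      ggplot2::labs(x = NULL, y = "% recording days with detections") +
      ggplot2::theme_bw() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                         hjust = 1))
    bc <- comp$bray_curtis
    bc$season <- factor(bc$season, levels = c("overall", "winter", "spring",
                                              "summer", "fall"))
    figs$bray_curtis <- ggplot2::ggplot(bc,
        ggplot2::aes(x = season, y = site, fill = similarity)) +
      ggplot2::geom_tile() +
      ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", similarity)),
                         size = 3) +
      ggplot2::scale_fill_gradient(low = "steelblue", high = "firebrick",
                                   limits = c(0, 1)) +
      ggplot2::labs(x = NULL, y = NULL,
                    title = paste("Bray-Curtis similarity vs",
                                  bc$focal[1])) +
      ggplot2::theme_bw()
  }
  mods <- results$models
  if (is.null(mods)) {
    warning("model results missing; skipping partial-fit figures")
  } else if (length(mods$fits)) {
    pf <- do.call(rbind, lapply(mods$fits, function(f) f$partial_fits))
    if (!is.null(pf)) {
      ann <- do.call(rbind, lapply(mods$fits, function(f) {
        if (f$selection$intercept_only) return(NULL)
        t <- f$selection$tests
        o <- f$selection$order
        stars <- ifelse(t$p_value < 0.005, "***",
                        ifelse(t$p_value < 0.01, "**",
                               ifelse(t$p_value < 0.05, "*", "NA")))
        ordinal <- c("1st", "2nd", "3rd", paste0(4:9, "th"))
        data.frame(site = f$site, type = f$type, term = t$term,
                   label = paste0(ordinal[o$rank[match(t$term, o$term)]],
                                  " ", stars))
      }))
      for (tm in unique(pf$term)) {
        p1 <- pf[pf$term == tm, , drop = FALSE]
        a1 <- ann[ann$term == tm, , drop = FALSE]
        figs[[paste0("partial_", tm)]] <- ggplot2::ggplot(p1,
            ggplot2::aes(x = grid, y = fit_prob)) +
          ggplot2::geom_ribbon(ggplot2::aes(ymin = lower_prob,
                                            ymax = upper_prob),
                               fill = "grey75") +
          ggplot2::geom_line() +
          ggplot2::geom_text(data = a1, inherit.aes = FALSE,
                             ggplot2::aes(label = label),
                             x = -Inf, y = Inf, hjust = -0.1, vjust = 1.5,
                             size = 3) +
          ggplot2::facet_grid(type ~ site, scales = "free_y") +
          ggplot2::labs(x = tm, y = "P(detection)",
                        title = paste("Partial fit:", tm,
                                      "(2.5/97.5 percentile bands)")) +
          ggplot2::theme_bw()
      }
    }
  }
  if (!is.null(outdir) && length(figs)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(figs))
      suppressMessages(ggplot2::ggsave(
        file.path(outdir, paste0("fig_", nm, ".png")), figs[[nm]],
        width = 9, height = 7, dpi = 120))
  }
  invisible(figs)
}

## quiet R CMD check notes for ggplot2 aesthetic variables
utils::globalVariables(c("week", "mean_hours", "se_hours", "type",
                         "percent_days", "season", "site", "similarity",
                         "fit_prob", "lower_prob", "upper_prob", "label"))
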