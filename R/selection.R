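## Term pruning and backwards QIC ordering of the final model.

#' Significance pruning and backwards QIC ordering
#'
#' Two stages.  (1) Pruning: the full model is fitted and all terms with
#' robust Wald p >= alpha are dropped, the model refitted and retested,
#' until every remaining term is significant (iterative refit by default; a
#' single-shot pass is available).  (2) Ordering: each remaining term is
#' removed in turn and refitted; terms are ranked by
#' `deltaQIC = QIC(model without term) - QIC(final model)`, descending, so
#' the 1st-ranked term contributes most to predictive power.  Ties are
#' broken by the Wald chi-square.
#'
#' @param y binary response.
#' @param covariates covariate table.
#' @param clusters cluster ids.
#' @param specs list of candidate [smoothSpec()] terms.
#' @param alpha significance cutoff (default 0.05).
#' @param single_shot drop all nonsignificant terms in one pass without
#'   retesting (default FALSE: iterate to convergence).
#' @return list with `model` (final [GeeFit-class]), `order` (data.frame
#'   `term`, `delta_qic`, `chi2`, `rank`), `tests` (final Wald tests),
#'   `dropped` (character), and `intercept_only` flag.
#' @export
backwardSelection <- function(y, covariates, clusters, specs, alpha = 0.05,
                              single_shot = FALSE) {
  names(specs) <- vapply(specs, function(s) s$covariate, character(1))
  active <- names(specs)
  dropped <- character(0)
  repeat {
    if (!length(active)) {
      d <- buildDesign(covariates, list())
      fit <- fitGee(y, d, clusters)
      return(list(model = fit, order = data.frame(term = character(0),
                                                  delta_qic = numeric(0),
                                                  chi2 = numeric(0),
                                                  rank = integer(0)),
                  tests = NULL, dropped = dropped, intercept_only = TRUE))
    }
    d <- buildDesign(covariates, specs[active])
    fit <- fitGee(y, d, clusters)
    tests <- do.call(rbind, lapply(active, waldTermTest, fit = fit))
    ns <- tests$term[tests$p_value >= alpha]
    if (!length(ns)) break
    dropped <- c(dropped, ns)
    active <- setdiff(active, ns)
    if (single_shot) {
      if (length(active)) {
        d <- buildDesign(covariates, specs[active])
        fit <- fitGee(y, d, clusters)
        tests <- do.call(rbind, lapply(active, waldTermTest, fit = fit))
      }
      break
    }
  }
  if (!length(active))
    return(backwardSelection(y, covariates, clusters, list(), alpha))
  qFull <- qic(fit)
  dq <- vapply(active, function(tm) {
    rest <- setdiff(active, tm)
    dR <- buildDesign(covariates, specs[rest])
    qic(fitGee(y, dR, clusters)) - qFull
  }, numeric(1))
  chi2 <- tests$chi2[match(active, tests$term)]
  o <- order(-dq, -chi2)
  ord <- data.frame(term = active[o], delta_qic = dq[o], chi2 = chi2[o],
                    rank = seq_along(o))
  list(model = fit, order = ord, tests = tests, dropped = dropped,
       intercept_only = FALSE)
}
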