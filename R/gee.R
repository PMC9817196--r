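## Blocked binomial GEE machinery: autocorrelation blocking, the
## independence-working-correlation fit with model-based and cluster-robust
## covariances, QIC, and Wald term tests.

#' First lag at which residual autocorrelation drops below a cutoff
#'
#' @param resid residual series (evenly spaced; hourly in this pipeline).
#' @param cutoff autocorrelation cutoff (default 0.1).
#' @param max_lag cap on the search (default 14 days of hours); hitting the
#'   cap emits a warning.
#' @return integer lag >= 1.
#' @export
acfBlockLag <- function(resid, cutoff = 0.1, max_lag = 14 * 24) {
  a <- stats::acf(resid, lag.max = max_lag, plot = FALSE,
                  demean = TRUE, na.action = stats::na.pass)
  rho <- drop(a$acf)[-1]                 # lags 1..max_lag
  k <- which(rho < cutoff)
  if (!length(k)) {
    warning("residual autocorrelation never dropped below ", cutoff,
            " within ", max_lag, " lags; using the cap")
    return(as.integer(max_lag))
  }
  as.integer(k[1])
}

#' Temporal blocking time step from GLM residual autocorrelation
#'
#' Fits a basic independent-observations binomial GLM of presence on all
#' candidate variables and returns the smallest lag at which the residual
#' autocorrelation drops below the cutoff.  That lag defines the length of
#' the self-similar data blocks used as GEE clusters.
#'
#' @param y binary response (hourly presence, ordered in time).
#' @param X design matrix (from [buildDesign()]).
#' @param cutoff autocorrelation cutoff (default 0.1).
#' @param resid_type "deviance" (default), "pearson" or "response".
#' @param max_lag cap on the search (default 14 days).
#' @return integer lag in hours.
#' @export
blockingTimestep <- function(y, X, cutoff = 0.1,
                             resid_type = c("deviance", "pearson",
                                            "response"),
                             max_lag = 14 * 24) {
  resid_type <- match.arg(resid_type)
  fit <- glm.fit(X, y, family = binomial())
  if (!fit$converged)
    stop("basic GLM for blocking did not converge", call. = FALSE)
  mu <- fit$fitted.values
  r <- switch(resid_type,
              response = y - mu,
              pearson = (y - mu) / sqrt(mu * (1 - mu)),
              deviance = sign(y - mu) *
                sqrt(-2 * (y * log(mu) + (1 - y) * log(1 - mu))))
  acfBlockLag(r, cutoff = cutoff, max_lag = max_lag)
}

#' Cluster ids for temporal blocking
#'
#' Consecutive on-effort hours are grouped into contiguous blocks of `lag`
#' hours from the series start; a gap in the hourly grid starts a new block
#' (blocks never straddle effort gaps).
#'
#' @param hour_start POSIXct vector of on-effort hour starts, ordered.
#' @param lag block length in hours (>= 1).
#' @return integer cluster id per observation.
#' @export
assignClusters <- function(hour_start, lag) {
  stopIfNot(lag >= 1, "lag must be >= 1")
  t <- as.numeric(hour_start)
  stopIfNot(!is.unsorted(t), "hour_start must be ordered")
  runStart <- c(TRUE, diff(t) != 3600)
  run <- cumsum(runStart)
  posInRun <- sequence(rle(run)$lengths) - 1L
  block <- posInRun %/% lag
  as.integer(factor(paste(run, block)))
}

#' Fit a binomial GEE with independence working correlation
#'
#' Logit-link binomial marginal model.  Under an independence working
#' correlation the estimating equations coincide with the ordinary binomial
#' GLM score equations, so point estimates are the GLM fit; within-cluster
#' dependence is carried entirely by the cluster-robust sandwich covariance,
#' which is retained alongside the model-based (inverse-information)
#' covariance.
#'
#' @param y binary response.
#' @param design design list from [buildDesign()], or a bare design matrix.
#' @param clusters cluster id per observation (from [assignClusters()]).
#' @return a [GeeFit-class].
#' @export
fitGee <- function(y, design, clusters) {
  if (is.matrix(design)) design <- list(X = design,
                                        termMap = list(), info = list())
  X <- design$X
  stopIfNot(all(y %in% c(0, 1)), "response must be binary")
  stopIfNot(length(clusters) == length(y),
            "clusters must have one id per observation")
  stopIfNot(length(unique(clusters)) >= 2, "need at least 2 clusters")
  fit <- suppressWarnings(glm.fit(X, y, family = binomial()))
  if (!fit$converged)
    stop("GEE fit did not converge after ", fit$iter, " iterations",
         call. = FALSE)
  if (any(is.na(fit$coefficients)))
    stop("design is rank-deficient; check for aliased terms", call. = FALSE)
  mu <- fit$fitted.values
  if (any(mu < 1e-10 | mu > 1 - 1e-10) && max(abs(fit$coefficients)) > 15)
    stop("apparent separation: fitted probabilities at the boundary ",
         "after ", fit$iter, " iterations", call. = FALSE)
  w <- mu * (1 - mu)
  A <- crossprod(X * sqrt(w))                       # information
  modelCov <- solve(A)
  score <- X * (y - mu)                             # per-observation scores
  U <- rowsum(score, group = clusters)              # cluster score sums
  meat <- crossprod(U)
  robust <- modelCov %*% meat %*% modelCov
  robust <- (robust + t(robust)) / 2
  modelCov <- (modelCov + t(modelCov)) / 2
  dimnames(modelCov) <- dimnames(robust) <- list(colnames(X), colnames(X))
  new("GeeFit", coefficients = setNames(fit$coefficients, colnames(X)),
      modelCov = modelCov, robustCov = robust, clusters = clusters,
      termMap = design$termMap, designInfo = design$info,
      y = as.numeric(y), fitted = mu, X = X,
      converged = fit$converged, nObs = length(y),
      nPresence = as.integer(sum(y)))
}

#' Quasilikelihood under the Independence model Criterion (QIC)
#'
#' `QIC = -2 QL + 2 trace(Omega_I %*% V_r)` with the binomial
#' quasilikelihood `QL = sum(y log mu + (1 - y) log(1 - mu))`, `Omega_I` the
#' inverse of the model-based covariance of the independence fit, and `V_r`
#' the robust covariance.  When the robust and model-based covariances
#' agree, the penalty reduces to `2 p`.
#'
#' @param fit a [GeeFit-class].
#' @return QIC value (smaller is better).
#' @export
qic <- function(fit) {
  mu <- pmin(pmax(fit@fitted, 1e-12), 1 - 1e-12)
  ql <- sum(fit@y * log(mu) + (1 - fit@y) * log(1 - mu))
  omega <- tryCatch(solve(fit@modelCov),
                    error = function(e) stop("singular model-based covariance",
                                             call. = FALSE))
  -2 * ql + 2 * sum(diag(omega %*% fit@robustCov))
}

#' Wald test of one term's coefficient block
#'
#' Marginal (type III) Wald chi-square on the term's coefficient block using
#' the robust covariance: `chi2 = b' V[b]^{-1} b`, df = block size.
#'
#' @param fit a [GeeFit-class].
#' @param term term name (must be in `termMap(fit)`).
#' @return data.frame row with `term`, `df`, `chi2`, `p_value`.
#' @export
waldTermTest <- function(fit, term) {
  idx <- fit@termMap[[term]]
  if (is.null(idx)) stop("term not in model: ", term, call. = FALSE)
  b <- fit@coefficients[idx]
  V <- fit@robustCov[idx, idx, drop = FALSE]
  Vi <- tryCatch(solve(V),
                 error = function(e) stop("singular robust covariance block for ",
                                          term, call. = FALSE))
  chi2 <- drop(t(b) %*% Vi %*% b)
  data.frame(term = term, df = length(idx), chi2 = chi2,
             p_value = pchisq(chi2, df = length(idx), lower.tail = FALSE))
}

#' Choose the lunar-illumination term form by QIC
#'
#' Fits two lunar-only models -- illumination as a linear term and as an
#' open M-spline smooth -- and returns the form with the lower QIC; ties go
#' to the linear form (parsimony).
#'
#' @param y binary response.
#' @param covariates covariate table containing `lunar_fraction`.
#' @param clusters cluster ids.
#' @param n_knots,degree smooth settings for the smoothed form.
#' @return list with `form` ("linear" or "smooth"), `qic_linear`,
#'   `qic_smooth`.
#' @export
chooseLunarForm <- function(y, covariates, clusters, n_knots = 4,
                            degree = 3) {
  stopIfNot("lunar_fraction" %in% names(covariates),
            "covariates must contain lunar_fraction")
  dLin <- buildDesign(covariates,
                      list(smoothSpec("lunar_fraction", "linear")))
  dSmo <- buildDesign(covariates,
                      list(smoothSpec("lunar_fraction", "open",
                                      n_knots = n_knots, degree = degree)))
  qLin <- qic(fitGee(y, dLin, clusters))
  qSmo <- qic(fitGee(y, dSmo, clusters))
  list(form = if (qLin <= qSmo) "linear" else "smooth",
       qic_linear = qLin, qic_smooth = qSmo)
}
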