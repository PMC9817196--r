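## Model evaluation: binned residuals and Tjur's R2.

#' Binned-residual evaluation of a binary-response model
#'
#' Observations are sorted by fitted probability into roughly-equal-count
#' bins (about sqrt(n) of them by default); per bin the mean fitted value,
#' mean raw residual (y - mu), and the theoretical 95% error bound
#' `2 * sqrt(pbar * (1 - pbar) / n_bin)` are computed.  A well-calibrated
#' model is expected to keep at least 95% of bin means inside the bounds.
#'
#' @param fit a [GeeFit-class], or a numeric vector of fitted probabilities
#'   (then `y` must be given).
#' @param y binary response; taken from `fit` when omitted.
#' @param n_bins number of bins (default `floor(sqrt(n))`).
#' @return list with `bins` (data.frame `mean_fitted`, `mean_residual`,
#'   `bound`, `n`, `within`) and `percent_within_bounds`.
#' @export
binnedResiduals <- function(fit, y = NULL, n_bins = NULL) {
  if (is(fit, "GeeFit")) {
    mu <- fit@fitted
    if (is.null(y)) y <- fit@y
  } else mu <- fit
  stopIfNot(!is.null(y) && length(y) == length(mu),
            "need a response of the same length as the fitted values")
  n <- length(y)
  if (is.null(n_bins)) n_bins <- floor(sqrt(n))
  if (n_bins < 2) stop("need at least 2 bins", call. = FALSE)
  o <- order(mu)
  bin <- ceiling(seq_along(o) / (n / n_bins))
  bin <- pmin(bin, n_bins)
  mf <- tapply(mu[o], bin, mean)
  mr <- tapply((y - mu)[o], bin, mean)
  nb <- tapply(mu[o], bin, length)
  bound <- 2 * sqrt(mf * (1 - mf) / nb)
  within <- abs(mr) <= bound
  list(bins = data.frame(mean_fitted = as.numeric(mf),
                         mean_residual = as.numeric(mr),
                         bound = as.numeric(bound),
                         n = as.integer(nb), within = as.logical(within)),
       percent_within_bounds = 100 * mean(within))
}

#' Tjur's coefficient of discrimination
#'
#' Mean fitted probability among presence hours minus mean fitted
#' probability among absence hours: 1 for a perfect fit, 0 for a constant
#' fit.
#'
#' @param fit a [GeeFit-class], or fitted probabilities (then `y` required).
#' @param y binary response; taken from `fit` when omitted.
#' @return Tjur's R2 in \[-1, 1\].
#' @export
tjurR2 <- function(fit, y = NULL) {
  if (is(fit, "GeeFit")) {
    mu <- fit@fitted
    if (is.null(y)) y <- fit@y
  } else mu <- fit
  if (all(y == 1) || all(y == 0))
    stop("Tjur's R2 is undefined when the response is all one class",
         call. = FALSE)
  mean(mu[y == 1]) - mean(mu[y == 0])
}
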