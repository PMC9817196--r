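## Bootstrap partial-fit curves with percentile confidence bands.

#' Bootstrap partial-fit curve for one model term
#'
#' Draws coefficient vectors from a multivariate normal with mean the point
#' estimates and covariance the robust (sandwich) covariance, evaluates the
#' term's smooth contribution on a covariate grid for every draw, and takes
#' pointwise 2.5/97.5 percentile bands.  Curves are returned both on the
#' linear-predictor scale (the term's contribution alone) and on the
#' probability scale, with all other design columns held at their observed
#' means.  Deterministic given `seed`.
#'
#' @param fit a [GeeFit-class].
#' @param term term name.
#' @param grid covariate values at which to evaluate (within the fitted
#'   range); default 200 points over the observed range (or the period for
#'   cyclic terms).
#' @param n_boot number of coefficient draws (default 1000).
#' @param seed RNG seed.
#' @return data.frame with `term`, `grid`, `fit_link`, `lower_link`,
#'   `upper_link`, `fit_prob`, `lower_prob`, `upper_prob`; attributes
#'   `n_boot` and `seed`.
#' @export
bootstrapPartialFit <- function(fit, term, grid = NULL, n_boot = 1000,
                                seed = 1L) {
  info <- fit@designInfo[[term]]
  idx <- fit@termMap[[term]]
  if (is.null(info) || is.null(idx))
    stop("term not in model: ", term, call. = FALSE)
  if (is.null(grid)) {
    rng <- if (info$kind == "cyclic") c(0, info$period) else info$boundary
    grid <- seq(rng[1], rng[2], length.out = 200)
  }
  ev <- eigen(fit@robustCov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    stop("robust covariance is not positive semi-definite", call. = FALSE)
  B <- evalBasisInfo(info, grid)
  beta <- fit@coefficients
  draws <- withSeed(seed,
                    MASS::mvrnorm(n_boot, mu = beta, Sigma = fit@robustCov,
                                  tol = 1e-6))
  contrib <- B %*% t(draws[, idx, drop = FALSE])       # grid x n_boot
  fitLink <- drop(B %*% beta[idx])
  qs <- apply(contrib, 1, quantile, probs = c(0.025, 0.975), names = FALSE)
  # probability scale: other columns at their observed means
  xbar <- colMeans(fit@X)
  etaRef <- sum(xbar[-idx] * beta[-idx])
  etaRefDraws <- drop(draws[, -idx, drop = FALSE] %*% xbar[-idx])
  etaBoot <- sweep(contrib, 2, etaRefDraws, `+`)
  qp <- apply(plogis(etaBoot), 1, quantile, probs = c(0.025, 0.975),
              names = FALSE)
  out <- data.frame(term = term, grid = grid,
                    fit_link = fitLink,
                    lower_link = qs[1, ], upper_link = qs[2, ],
                    fit_prob = plogis(etaRef + fitLink),
                    lower_prob = qp[1, ], upper_prob = qp[2, ])
  attr(out, "n_boot") <- n_boot
  attr(out, "seed") <- seed
  out
}
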