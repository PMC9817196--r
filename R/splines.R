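## M-spline bases (open and cyclic) and design-matrix construction.
##
## Smooth terms use M-splines: non-negative polynomial spline basis
## functions, each integrating to one, built by rescaling the B-spline basis
## on the same knots (M_i = B_i * (degree + 1) / (t_{i+degree+1} - t_i)).
## "Four knots" means four distinct knots including the two boundaries, i.e.
## two interior knots; with a cubic basis and the first column dropped (the
## model supplies its own intercept) an open smooth contributes 5 free
## coefficients and a cyclic smooth 2 -- the degrees of freedom reported in
## the model tables.  Cyclic bases are periodic by construction: uniformly
## spaced knots are extended past the period and translated basis functions
## one period apart are folded together, so B(t) == B(t + period) exactly.

#' Declare a smooth (or linear) model term
#'
#' @param covariate name of the covariate column.
#' @param kind "cyclic" (periodic smooth, e.g. hour of day or annual cycle),
#'   "open" (non-periodic smooth, e.g. year), or "linear".
#' @param period cycle length for cyclic terms, in covariate units (24 for
#'   hour of day, 1 for the normalised annual cycle `doy_frac`).
#' @param n_knots number of distinct knots including both boundaries
#'   (default 4, to avoid overfitting).
#' @param degree polynomial degree (default 3, cubic).
#' @return an object of class `SmoothSpec`.
#' @examples
#' smoothSpec("hour_of_day", "cyclic", period = 24)
#' smoothSpec("year_frac", "open")
#' smoothSpec("lunar_fraction", "linear")
#' @export
smoothSpec <- function(covariate, kind = c("cyclic", "open", "linear"),
                       period = NULL, n_knots = 4, degree = 3) {
  kind <- match.arg(kind)
  if (kind == "cyclic" && is.null(period))
    stop("cyclic terms need a period", call. = FALSE)
  stopIfNot(n_knots >= 3 || kind == "linear",
            "smooth terms need at least 3 distinct knots")
  structure(list(covariate = covariate, kind = kind, period = period,
                 n_knots = n_knots, degree = degree),
            class = "SmoothSpec")
}

## Open M-spline basis matrix; attributes carry what evalBasisInfo needs.
#' @noRd
mSplineOpen <- function(x, boundary, n_knots, degree, intercept = FALSE) {
  distinct <- seq(boundary[1], boundary[2], length.out = n_knots)
  full <- c(rep(boundary[1], degree + 1), distinct[-c(1, n_knots)],
            rep(boundary[2], degree + 1))
  xc <- pmin(pmax(x, boundary[1]), boundary[2])
  B <- splines::splineDesign(full, xc, ord = degree + 1)
  nb <- ncol(B)
  scale <- (degree + 1) / (full[seq_len(nb) + degree + 1] - full[seq_len(nb)])
  M <- sweep(B, 2, scale, `*`)
  if (!intercept) M <- M[, -1, drop = FALSE]
  M
}

## Cyclic (periodic) M-spline basis on [0, period).
#' @noRd
mSplineCyclic <- function(x, period, n_knots, degree, intercept = FALSE) {
  K <- n_knots - 1                       # distinct knots per period
  h <- period / K
  u <- x %% period
  ext <- seq(-degree * h, period + degree * h, by = h)
  B <- splines::splineDesign(ext, u, ord = degree + 1)
  nb <- ncol(B)                          # == K + degree
  M <- matrix(0, nrow(B), K)
  for (j in seq_len(K)) {
    cols <- seq(j, nb, by = K)
    M[, j] <- rowSums(B[, cols, drop = FALSE])
  }
  M <- M * (degree + 1) / ((degree + 1) * h)   # uniform M-spline scaling
  if (!intercept) M <- M[, -1, drop = FALSE]
  M
}

## Evaluate the basis described by an info record at new covariate values.
#' @noRd
evalBasisInfo <- function(info, x) {
  switch(info$kind,
         linear = matrix(x, ncol = 1),
         open = mSplineOpen(x, info$boundary, info$n_knots, info$degree),
         cyclic = mSplineCyclic(x, info$period, info$n_knots, info$degree),
         stop("unknown term kind ", info$kind))
}

#' Build a GAM design matrix from smooth-term specifications
#'
#' Produces an intercept column plus one coefficient block per term:
#' M-spline bases for smooths (cyclic bases wrap by construction), raw
#' columns for linear terms.  The term-to-column map and the basis metadata
#' needed to re-evaluate each block on a new grid are returned alongside.
#'
#' @param covariates data.frame holding all referenced covariate columns
#'   (e.g. from [computeEphemeris()]).
#' @param specs list of [smoothSpec()] terms.
#' @return list with `X` (design matrix), `termMap` (named list of column
#'   indices, including "(Intercept)") and `info` (named list of basis
#'   metadata per term).
#' @export
buildDesign <- function(covariates, specs) {
  n <- nrow(covariates)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  termMap <- list("(Intercept)" = 1L)
  info <- list()
  for (sp in specs) {
    x <- covariates[[sp$covariate]]
    if (is.null(x))
      stop("covariate not found: ", sp$covariate, call. = FALSE)
    if (sp$kind != "linear" && diff(range(x)) == 0)
      stop("covariate ", sp$covariate,
           " is constant: use a linear term or drop it", call. = FALSE)
    rec <- list(kind = sp$kind, covariate = sp$covariate,
                n_knots = sp$n_knots, degree = sp$degree,
                period = sp$period, boundary = range(x))
    B <- evalBasisInfo(rec, x)
    colnames(B) <- paste(sp$covariate, seq_len(ncol(B)), sep = ".")
    idx <- ncol(X) + seq_len(ncol(B))
    X <- cbind(X, B)
    termMap[[sp$covariate]] <- idx
    info[[sp$covariate]] <- rec
  }
  list(X = X, termMap = termMap, info = info)
}
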