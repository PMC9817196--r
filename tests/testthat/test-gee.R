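# GEE fitting, robust covariance, QIC, blocking and Wald term tests.

test_that("singleton clusters reproduce the independent binomial GLM", {
  set.seed(100)
  for (i in 1:20) {
    n <- 200 + i
    x1 <- runif(n); x2 <- rnorm(n)
    y <- rbinom(n, 1, plogis(-0.5 + 1.5 * x1 - x2))
    X <- cbind("(Intercept)" = 1, x1 = x1, x2 = x2)
    f <- fitGee(y, X, clusters = seq_len(n))
    g <- glm(y ~ x1 + x2, family = binomial())
    expect_lt(max(abs(coef(f) - unname(coef(g)))), 1e-6)
  }
})

test_that("duplicating every cluster leaves coefficients unchanged", {
  set.seed(101)
  n <- 300
  x <- runif(n)
  y <- rbinom(n, 1, plogis(-1 + 2 * x))
  X <- cbind("(Intercept)" = 1, x = x)
  cl <- rep(1:30, each = 10)
  f1 <- fitGee(y, X, cl)
  f2 <- fitGee(c(y, y), rbind(X, X), c(cl, cl + 30))
  expect_equal(coef(f1), coef(f2), tolerance = 1e-8)
})

test_that("robust covariance matches the sandwich-package cluster
           estimator", {
  set.seed(102)
  n <- 400
  x <- runif(n)
  cl <- rep(1:40, each = 10)
  y <- rbinom(n, 1, plogis(-0.5 + x + 0.5 * rep(rnorm(40), each = 10)))
  X <- cbind("(Intercept)" = 1, x = x)
  f <- fitGee(y, X, cl)
  g <- glm(y ~ x, family = binomial())
  v <- sandwich::vcovCL(g, cluster = cl, type = "HC0", cadjust = FALSE)
  expect_equal(unname(robustCov(f)), unname(v), tolerance = 1e-7)
  # both covariances symmetric PSD
  expect_true(all(eigen(robustCov(f), symmetric = TRUE,
                        only.values = TRUE)$values > -1e-12))
  expect_true(all(eigen(modelCov(f), symmetric = TRUE,
                        only.values = TRUE)$values > 0))
})

test_that("cyclic-hour GEE recovers the true diel peak within an hour", {
  sim <- simDielSeason(n_hours = 8760, seasAmp = 0, dielPeak = 13, seed = 3)
  d <- buildDesign(sim$cov,
                   list(smoothSpec("hour_of_day", "cyclic", period = 24)))
  f <- fitGee(sim$y, d, assignClusters(sim$hours, 24))
  grid <- seq(0, 24, by = 0.05)
  B <- pamgee:::evalBasisInfo(f@designInfo$hour_of_day, grid)
  peak <- grid[which.max(B %*% coef(f)[termMap(f)$hour_of_day])]
  expect_lt(pamgee:::circularDistance(peak, 13, 24), 1)
})

test_that("QIC penalty reduces to 2p when robust equals model-based
           covariance, and matches hand arithmetic on a 12-row fixture", {
  set.seed(103)
  x <- runif(12)
  y <- c(0, 1, 0, 1, 1, 0, 0, 1, 0, 1, 1, 0)
  X <- cbind("(Intercept)" = 1, x = x)
  f <- fitGee(y, X, clusters = rep(1:4, each = 3))
  # trace identity: force robust == model-based
  fEq <- f
  fEq@robustCov <- f@modelCov
  mu <- fitted(f)
  qlHand <- sum(y * log(mu) + (1 - y) * log(1 - mu))
  expect_equal(qic(fEq), -2 * qlHand + 2 * length(coef(f)),
               tolerance = 1e-10)
  # full hand computation with the true robust covariance
  penHand <- 2 * sum(diag(solve(modelCov(f)) %*% robustCov(f)))
  expect_equal(qic(f), -2 * qlHand + penHand, tolerance = 1e-8)
})

test_that("QIC prefers the true model over the null in most replicates", {
  set.seed(104)
  wins <- 0
  for (r in 1:100) {
    n <- 300
    x <- runif(n)
    y <- rbinom(n, 1, plogis(-0.5 + 2 * x))
    cl <- rep(seq_len(n / 5), each = 5)
    qTrue <- qic(fitGee(y, cbind(1, x), cl))
    qNull <- qic(fitGee(y, cbind(rep(1, n)), cl))
    wins <- wins + (qNull >= qTrue)
  }
  expect_gte(wins, 51)
})

test_that("blocking lag is 1 for white-noise residuals and follows the
           theoretical AR(1) crossings", {
  set.seed(105)
  expect_equal(acfBlockLag(rnorm(50000)), 1L)
  ar8 <- as.numeric(arima.sim(list(ar = 0.8), n = 500000))
  expect_equal(acfBlockLag(ar8), 11L)      # first k with 0.8^k < 0.1
  ar5 <- as.numeric(arima.sim(list(ar = 0.5), n = 500000))
  expect_equal(acfBlockLag(ar5), 4L)       # 0.5^3 = .125, 0.5^4 = .0625
  expect_warning(acfBlockLag(sin(1:5000 / 2000), max_lag = 10), "cap")
})

test_that("blockingTimestep runs the GLM residual pathway", {
  sim <- simDielSeason(n_hours = 2000, seed = 6)
  d <- buildDesign(sim$cov,
                   list(smoothSpec("hour_of_day", "cyclic", period = 24)))
  lag <- blockingTimestep(sim$y, d$X)
  expect_gte(lag, 1)
  expect_lt(lag, 14 * 24)
})

test_that("cluster assignment blocks contiguous hours and restarts at
           gaps", {
  hs <- seq(pamT("2015-01-01T00:00:00"), by = 3600, length.out = 48)
  cl <- assignClusters(hs, 24)
  expect_equal(length(unique(cl)), 2)
  expect_equal(as.numeric(table(cl)), c(24, 24))
  expect_equal(length(unique(assignClusters(hs, 1))), 48)
  # a gap splits a block
  hsGap <- hs[-25]
  clGap <- assignClusters(hsGap, 24)
  expect_equal(length(unique(clGap)), 2)
  expect_equal(as.numeric(table(clGap)), c(24, 23))
})

test_that("Wald term tests match the quadratic-form oracle and endpoints", {
  sim <- simDielSeason(n_hours = 1500, seasAmp = 1, seed = 12)
  d <- buildDesign(sim$cov, list(
    smoothSpec("hour_of_day", "cyclic", period = 24),
    smoothSpec("doy_frac", "cyclic", period = 1)))
  f <- fitGee(sim$y, d, assignClusters(sim$hours, 12))
  for (tm in c("hour_of_day", "doy_frac")) {
    t1 <- waldTermTest(f, tm)
    idx <- termMap(f)[[tm]]
    b <- coef(f)[idx]
    chi2 <- drop(t(b) %*% solve(robustCov(f)[idx, idx]) %*% b)
    expect_equal(t1$chi2, chi2, tolerance = 1e-10)
    expect_equal(t1$df, length(idx))
    expect_equal(t1$p_value, pchisq(chi2, length(idx), lower.tail = FALSE))
  }
  expect_error(waldTermTest(f, "year_frac"), "not in model")
  # zero coefficient block -> chi2 0, p 1
  fZero <- f
  fZero@coefficients[termMap(f)$doy_frac] <- 0
  tz <- waldTermTest(fZero, "doy_frac")
  expect_equal(tz$chi2, 0)
  expect_equal(tz$p_value, 1)
  # single coefficient beta = 2 with robust variance 1 -> chi2 4
  fOne <- f
  fOne@termMap <- c(f@termMap, list(single = 2L))
  fOne@coefficients[2] <- 2
  fOne@robustCov[2, 2] <- 1
  t4 <- waldTermTest(fOne, "single")
  expect_equal(t4$chi2, 4)
  expect_equal(t4$p_value, pchisq(4, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_lt(abs(t4$p_value - 0.0455), 1e-3)
})

test_that("with no true effects, term rejection stays near the nominal
           rate", {
  set.seed(106)
  rej <- 0
  nrep <- 150
  for (r in 1:nrep) {
    n <- 600
    cov <- data.frame(hour_of_day = rep(0:23, length.out = n))
    y <- rbinom(n, 1, 0.3)              # independent: dependence length 1
    d <- buildDesign(cov,
                     list(smoothSpec("hour_of_day", "cyclic", period = 24)))
    f <- fitGee(y, d, seq_len(n))
    rej <- rej + (waldTermTest(f, "hour_of_day")$p_value < 0.05)
  }
  expect_lte(rej / nrep, 0.10)
})

test_that("lunar form choice follows QIC with ties to linear", {
  set.seed(107)
  hs <- seq(pamT("2015-01-01T00:00:00"), by = 3600, length.out = 3000)
  lun <- computeEphemeris(hs, 19.6, -156)["lunar_fraction"]
  pickLin <- 0; pickSmo <- 0
  for (r in 1:40) {
    yLin <- rbinom(3000, 1, plogis(-1 + 2.5 * lun$lunar_fraction))
    cLin <- chooseLunarForm(yLin, lun, assignClusters(hs, 24))
    pickLin <- pickLin + (cLin$form == "linear")
    expect_equal(cLin$form,
                 if (cLin$qic_linear <= cLin$qic_smooth) "linear"
                 else "smooth")
    # strongly unimodal response in illumination
    ySmo <- rbinom(3000, 1,
                   plogis(-2.5 + 4 * exp(-((lun$lunar_fraction - 0.5)^2) /
                                           0.02)))
    cSmo <- chooseLunarForm(ySmo, lun, assignClusters(hs, 24))
    pickSmo <- pickSmo + (cSmo$form == "smooth")
  }
  expect_gte(pickLin / 40, 0.8)
  expect_gte(pickSmo / 40, 0.8)
})
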