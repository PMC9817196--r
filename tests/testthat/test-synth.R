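# Synthetic detection-bin generator: rate structure, label-noise
# calibration, determinism, ground truth.

test_that("flat-rate scenario yields uniform detections across hour of day", {
  sc <- flatScenario(occupancy = 0.4, seed = 2,
                     end = "2016-01-01T00:00:00")   # ~105k bins
  b <- simulateClickBins(sc)[[1]]
  tb <- binTable(b)
  expect_gt(nrow(tb), 30000)
  hod <- as.POSIXlt(tb$bin_start, tz = "Etc/GMT+10")$hour
  gof <- chisq.test(tabulate(hod + 1, nbins = 24))
  expect_gt(gof$p.value, 0.01)
})

test_that("label-noise injection calibrates to the stated precision", {
  # same seed with precision 1 gives the true-bin count: the RNG draws for
  # the bout chain and counts precede noise injection
  scTrue <- flatScenario(precision = 1, seed = 7)
  scNoisy <- flatScenario(precision = 0.8, seed = 7)
  nTrue <- nrow(binTable(simulateClickBins(scTrue)[[1]]))
  nLab <- nrow(binTable(simulateClickBins(scNoisy)[[1]]))
  expect_gt(nLab, 100000 * 0.25)      # enough bins for the calibration check
  expect_lt(abs(nTrue / nLab - 0.8), 0.01)
  expect_gt(nLab, nTrue)              # precision < 1 injects extra bins
})

test_that("diel peak at hour 13 puts the empirical modal hour in 12..14", {
  sc <- flatScenario(diel_amplitude = 2, diel_peak_hour = 13,
                     base_rate = 80, occupancy = 0.3, seed = 3)
  tb <- binTable(simulateClickBins(sc)[[1]])
  hod <- as.POSIXlt(tb$bin_start, tz = "Etc/GMT+10")$hour
  modal <- as.integer(names(which.max(table(hod))))
  expect_true(modal %in% 12:14)
})

test_that("simulation is deterministic given scenario seed", {
  sc <- exampleScenario(n_years = 1, seed = 5)
  b1 <- simulateClickBins(sc)
  b2 <- simulateClickBins(sc)
  expect_identical(lapply(b1, binTable), lapply(b2, binTable))
  b3 <- simulateClickBins(exampleScenario(n_years = 1, seed = 6))
  expect_false(identical(lapply(b1, binTable), lapply(b3, binTable)))
})

test_that("invalid scenario fields raise errors naming the field", {
  p <- data.frame(site = "S", type = "T", type_class = "delphinid",
                  base_rate = 100, occupancy = 0.2,
                  presence_persistence = 0, precision = 1)
  d <- data.frame(site = "S", deployment_id = "S-1",
                  start = "2015-01-01T00:00:00", end = "2015-02-01T00:00:00",
                  listen_s = 900, period_s = 900)
  bad <- p; bad$precision <- 1.2
  expect_error(syntheticScenario(bad, d), "precision")
  bad <- p; bad$base_rate <- -5
  expect_error(syntheticScenario(bad, d), "base_rate")
  bad <- p; bad$presence_persistence <- 1
  expect_error(syntheticScenario(bad, d), "presence_persistence")
  dOver <- rbind(d, data.frame(site = "S", deployment_id = "S-2",
                               start = "2015-01-15T00:00:00",
                               end = "2015-03-01T00:00:00",
                               listen_s = 900, period_s = 900))
  expect_error(syntheticScenario(p, dOver), "overlap")
})

test_that("ground truth is constant when all amplitudes are zero", {
  sc <- flatScenario(end = "2015-02-01T00:00:00")
  gt <- groundTruth(sc)
  expect_equal(nrow(gt), 24)
  expect_lt(diff(range(gt$probability)), 1e-9)
  expect_lt(diff(range(gt$expected_minutes)), 1e-9)
  expect_true(all(gt$probability >= 0 & gt$probability <= 1))
  expect_true(all(gt$expected_minutes >= 0 & gt$expected_minutes <= 60))
})

test_that("ground-truth probability is monotone in base rate and peaks at
           the diel peak hour", {
  # base rates kept near the click threshold so hourly probabilities stay
  # off the saturation plateau and the diel argmax is identifiable
  mk <- function(br) flatScenario(base_rate = br, diel_amplitude = 1.5,
                                  diel_peak_hour = 13,
                                  end = "2015-03-01T00:00:00")
  g1 <- groundTruth(mk(12)); g2 <- groundTruth(mk(18))
  expect_true(all(g2$probability >= g1$probability - 1e-12))
  pk <- g1$probability[g1$hour_of_day == 13]
  anti <- g1$probability[g1$hour_of_day == 1]
  expect_gte(pk, anti)
  expect_equal(g1$hour_of_day[which.max(g1$probability)], 13)
})

test_that("bout persistence clusters detections without changing the
           marginal rate much", {
  n1 <- nrow(binTable(simulateClickBins(flatScenario(persistence = 0,
                                                     seed = 11))[[1]]))
  b2 <- binTable(simulateClickBins(flatScenario(persistence = 0.9,
                                                seed = 11))[[1]])
  expect_lt(abs(nrow(b2) / n1 - 1), 0.1)   # same stationary occupancy
  # runs of consecutive bins are longer under persistence
  gaps2 <- diff(as.numeric(b2$bin_start))
  expect_gt(mean(gaps2 == 300), 0.5)
})
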