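# Precision adjustment, bin thresholds, hourly roll-up, duty-cycle loss
# estimation and boosting, consolidation and subsite merging.

test_that("precision adjustment multiplies counts without rounding", {
  b <- binsAt(c(0, 300, 600), counts = c(100, 55, 10))
  out <- adjustCountsByPrecision(b, 0.9)
  expect_equal(binTable(out)$click_count, c(90, 49.5, 9))
  ident <- adjustCountsByPrecision(b, 1)
  expect_equal(binTable(ident)$click_count, c(100, 55, 10))
  ptab <- data.frame(site = "S", type = "T", precision = 0.9)
  out2 <- adjustCountsByPrecision(b, ptab)
  expect_equal(binTable(out2)$click_count, c(90, 49.5, 9))
  expect_error(adjustCountsByPrecision(b, data.frame(site = "X", type = "T",
                                                     precision = 0.9)),
               "no precision entry")
})

test_that("bin retention thresholds are strict and class-specific", {
  b <- binsAt(c(0, 300, 600, 900), counts = c(54, 49.5, 50, 51))
  kept <- binTable(filterBins(b, "delphinid"))$click_count
  expect_equal(kept, c(54, 51))          # 50.0 dropped: strict >
  bk <- binsAt(c(0, 300, 600), counts = c(20, 20.5, 19))
  keptK <- binTable(filterBins(bk, "beaked_kogia"))$click_count
  expect_equal(keptK, 20.5)              # 20.0 dropped at the boundary
  expect_error(filterBins(b, "porpoise"), "type_class")
})

test_that("hourly roll-up credits 5 minutes per retained bin, clipped to
           effort", {
  eff <- effortRec("2015-06-01T00:00:00", "2015-06-01T03:00:00")
  # hour 0: 2 bins; hour 1: 12 bins (saturated); hour 2: none
  b <- binsAt(c(0, 1500, 3600 + (0:11) * 300), counts = 100)
  h <- binsToHourly(filterBins(b, "delphinid"), eff)
  tb <- hourTable(h)
  expect_equal(nrow(tb), 3)
  expect_equal(tb$detection_minutes, c(10, 60, 0))
  expect_equal(tb$recorded_minutes, rep(60, 3))
})

test_that("off-effort hours are flagged and out-of-effort bins dropped with
           a warning", {
  # two deployments with a one-hour gap; one bin falls inside the gap
  eff <- rbind(effortRec("2015-06-01T00:00:00", "2015-06-01T01:00:00"),
               effortRec("2015-06-01T02:00:00", "2015-06-01T03:00:00",
                         dep = "S-2"))
  # site-level bins (not tied to one deployment record)
  b <- binsAt(c(600, 5400), counts = 100, dep = "all")  # 01:30 is in the gap
  expect_warning(h <- binsToHourly(filterBins(b, "delphinid"), eff),
                 "outside any effort")
  tb <- hourTable(h)
  expect_equal(tb$recorded_minutes, c(60, 0, 60))
  expect_equal(tb$detection_minutes, c(5, 0, 0))
  p <- hourlyPresence(h)
  expect_equal(nrow(p), 2)               # off-effort gap hour excluded
  expect_equal(p$presence, c(1, 0))
})

test_that("duty-cycled effort yields partial recorded minutes", {
  eff <- effortRec("2015-06-01T00:00:00", "2015-06-01T02:00:00",
                   listen_s = 300, period_s = 900)
  b <- binsAt(0, counts = 100)
  h <- binsToHourly(filterBins(b, "delphinid"), eff)
  expect_equal(hourTable(h)$recorded_minutes, c(20, 20))
})

test_that("duty-cycle loss matches hand-computed cases", {
  expect_equal(estimateDutyCycleLoss(binsAt(0:11 * 300),
                                     dutyCycle(900, 900))$missed_fraction, 0)
  # detections in every bin, 5 on / 5 off: half lost at every offset
  dense <- binsAt(0:143 * 300)
  expect_equal(estimateDutyCycleLoss(dense,
                                     dutyCycle(300, 600))$missed_fraction,
               0.5, tolerance = 1e-12)
  # a single positive bin under 5/15 survives at 1 of 3 offsets
  single <- binsAt(0)
  expect_equal(estimateDutyCycleLoss(single,
                                     dutyCycle(300, 900))$missed_fraction,
               2 / 3, tolerance = 1e-12)
  expect_error(estimateDutyCycleLoss(binsAt(numeric(0)),
                                     dutyCycle(300, 900)),
               "no continuous reference")
})

test_that("boosting divides by retained fraction, caps at 60 and preserves
           zeros", {
  h <- hourlyDetections("S", "T",
                        pamT(c("2015-06-01T00:00:00", "2015-06-01T01:00:00",
                               "2015-06-01T02:00:00")),
                        detection_minutes = c(15, 0, 45),
                        recorded_minutes = c(20, 20, 20))
  out <- boostCounts(h, 0.5)
  expect_equal(detectionMinutes(out), c(30, 0, 60))
  expect_true(out@boosted)
  expect_error(boostCounts(h, 1), "degenerate")
})

test_that("type consolidation is a union at the bin level", {
  b1 <- binsAt(c(0, 600), counts = 60, type = "A")
  b2 <- binsAt(c(300, 900), counts = 60, type = "B")
  m <- consolidateTypes(list(b1, b2), c(A = "G", B = "G"))
  expect_length(m, 1)
  expect_equal(nrow(binTable(m[[1]])), 4)   # disjoint bins: union = sum
  # overlapping bin counted once
  b3 <- binsAt(c(0, 600), counts = 60, type = "B")
  m2 <- consolidateTypes(list(b1, b3), c(A = "G", B = "G"))
  expect_equal(nrow(binTable(m2[[1]])), 2)
  # a series merged with itself keeps its bin set (idempotent presence)
  m3 <- consolidateTypes(list(b1, b1), c(A = "G"))
  expect_equal(binTable(m3[[1]])$bin_start, binTable(b1)$bin_start)
  expect_error(consolidateTypes(list(b1, b2), c(A = "G")), "no entry")
})

test_that("hourly consolidation sums minutes capped at 60", {
  hs <- pamT(c("2015-06-01T00:00:00", "2015-06-01T01:00:00"))
  h1 <- hourlyDetections("S", "A", hs, c(40, 5), c(60, 60))
  h2 <- hourlyDetections("S", "B", hs, c(40, 5), c(60, 60))
  g <- consolidateTypes(list(h1, h2), c(A = "G", B = "G"))[["G"]]
  expect_equal(detectionMinutes(g), c(60, 10))
})

test_that("subsite merging concatenates and takes the max on overlap", {
  hs1 <- pamT(c("2015-01-01T00:00:00", "2015-01-01T01:00:00"))
  hs2 <- pamT(c("2015-01-01T01:00:00", "2015-01-01T02:00:00"))
  a <- hourlyDetections("M1", "T", hs1, c(10, 20), c(60, 60))
  b <- hourlyDetections("M2", "T", hs2, c(5, 30), c(60, 60))
  m <- mergeSubsites(list(a, b), "M")
  tb <- hourTable(m)
  expect_equal(siteId(m), "M")
  expect_equal(nrow(tb), 3)
  expect_equal(tb$detection_minutes, c(10, 20, 30))   # overlap: max(20, 5)
  same <- mergeSubsites(list(a, a), "M")
  expect_equal(hourTable(same)$detection_minutes, c(10, 20))
})

test_that("consolidate-then-merge equals merge-then-consolidate on
           non-overlapping subsite grids", {
  g1 <- pamT(c("2015-01-01T00:00:00", "2015-01-01T01:00:00"))
  g2 <- pamT(c("2015-02-01T00:00:00", "2015-02-01T01:00:00"))
  mk <- function(site, type, grid, dm)
    hourlyDetections(site, type, grid, dm, rep(60, 2))
  s1a <- mk("M1", "A", g1, c(40, 0)); s1b <- mk("M1", "B", g1, c(30, 5))
  s2a <- mk("M2", "A", g2, c(10, 50)); s2b <- mk("M2", "B", g2, c(0, 20))
  mapping <- c(A = "G", B = "G")
  r1 <- mergeSubsites(list(
    consolidateTypes(list(s1a, s1b), mapping)[["G"]],
    consolidateTypes(list(s2a, s2b), mapping)[["G"]]), "M")
  r2 <- consolidateTypes(list(mergeSubsites(list(s1a, s2a), "M"),
                              mergeSubsites(list(s1b, s2b), "M")),
                         mapping)[["G"]]
  expect_equal(hourTable(r1), hourTable(r2))
})

test_that("boosted duty-cycled deployments recover the continuous mean
           within 10% across persistence and cycle settings", {
  cycles <- list(c(300, 600), c(300, 900), c(1500, 3600))  # 1/2, 1/3, 5/12
  for (pers in c(0, 0.5, 0.9)) for (cy in cycles) {
    sc <- flatScenario(persistence = pers, occupancy = 0.25,
                       diel_amplitude = 1, diel_peak_hour = 4,
                       end = "2015-07-01T00:00:00", seed = 21)
    fb <- filterBins(simulateClickBins(sc)[[1]], "delphinid")
    hCont <- binsToHourly(fb, sc@deployments)
    cyc <- dutyCycle(cy[1], cy[2])
    loss <- estimateDutyCycleLoss(fb, cyc)
    effDC <- sc@deployments; effDC$listen_s <- cy[1]; effDC$period_s <- cy[2]
    hBoost <- boostCounts(binsToHourly(applyDutyCycle(fb, cyc), effDC), loss)
    relErr <- abs(mean(detectionMinutes(hBoost)) -
                    mean(detectionMinutes(hCont))) /
      mean(detectionMinutes(hCont))
    expect_lt(relErr, 0.10)
    # boosting never creates presence
    expect_true(all(detectionMinutes(hBoost)[detectionMinutes(
      binsToHourly(applyDutyCycle(fb, cyc), effDC)) == 0] == 0))
  }
})
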