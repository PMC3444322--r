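sch <- defaultFrameSchedule("H2O")
schO <- defaultFrameSchedule("O2")
schC <- defaultFrameSchedule("CO")
aifH <- aifModel()
aifO2 <- aifModel(amplitude = 25, delay = 15, shape = 2.5, timeToPeak = 10)
aifW <- aifModel(amplitude = 7.5, delay = 40, shape = 2, timeToPeak = 40)
aifCO <- aifModel(amplitude = 30, delay = 20, shape = 1.2,
                  timeToPeak = 150)

test_that("water forward model matches the quadrature convolution oracle", {
  scan <- simulateH2oTac(32, 0.9, aifH, sch[, 1], sch[, 2])
  vals <- as.numeric(activity(scan))
  peak <- max(vals)
  for (fr in c(3, 6, 10, 14, 18, 22, 25)) {
    ref <- oracleH2oFrame(32, 0.9, aifH, sch[fr, 1], sch[fr, 2])
    if (ref > 0.01 * peak) {
      expect_lt(abs(vals[fr] / ref - 1), 1e-3)
    } else {
      expect_lt(abs(vals[fr] - ref), 1e-3 * peak)
    }
  }
})

test_that("water model is linear in the input and vanishes at zero flow", {
  s1 <- simulateH2oTac(40, 0.9, aifH, sch[, 1], sch[, 2])
  a2 <- aifModel(amplitude = 2 * aifH@amplitude)
  s2 <- simulateH2oTac(40, 0.9, a2, sch[, 1], sch[, 2])
  expect_equal(as.numeric(activity(s2)), 2 * as.numeric(activity(s1)),
               tolerance = 1e-10)
  s0 <- simulateH2oTac(0, 0.9, aifH, sch[, 1], sch[, 2])
  expect_equal(as.numeric(activity(s0)), rep(0, 25))
  expect_error(simulateH2oTac(40, 0, aifH, sch[, 1], sch[, 2]), "lambda")
})

test_that("noiseless CBF round trips are exact to 0.1%", {
  for (f in c(32, 55)) {
    scan <- simulateH2oTac(f, 0.9, aifH, sch[, 1], sch[, 2])
    fit <- fitCBF(scan, fitDelay = TRUE)
    expect_true(fit$converged)
    expect_lt(abs(fit$cbf / f - 1), 1e-4)
    expect_lt(abs(fit$lambda / 0.9 - 1), 1e-3)
    expect_lt(abs(fit$delay), 0.05)
  }
})

test_that("an all-zero tissue curve is flagged, not silently fit", {
  scan <- dynamicScan("H2O", sch[, 1], sch[, 2], rep(0, 25),
                      aif = list(blood = aifH))
  expect_warning(fit <- fitCBF(scan), "flagged")
  expect_false(fit$converged)
  expect_true(is.na(fit$cbf))
})

test_that("CBV equilibrium algebra", {
  scan <- dynamicScan("CO", schC[, 1], schC[, 2], rep(0.0272 * 30, 3),
                      aif = list(blood = aifCO))
  expect_equal(computeCBV(scan, bloodActivity = 30), 3.2, tolerance = 1e-12)
  zero <- dynamicScan("CO", schC[, 1], schC[, 2], rep(0, 3),
                      aif = list(blood = aifCO))
  expect_equal(computeCBV(zero, bloodActivity = 30), 0)
  expect_error(computeCBV(scan, bloodActivity = 0), "positive")
})

test_that("simulated CO scans round-trip CBV through the blood curve", {
  scan <- simulateCoTac(3.4, aifCO, schC[, 1], schC[, 2])
  expect_lt(abs(computeCBV(scan) / 3.4 - 1), 1e-6)
})

test_that("zero extraction leaves only water and vascular components", {
  s0 <- simulateO2Tac(0, 32, 3.2, 0.9, aifO2, aifW, schO[, 1], schO[, 2])
  # reference: build the two E-free terms directly
  sWater <- simulateH2oTac(32, 0.9, aifW, schO[, 1], schO[, 2])
  sVasc <- simulateCoTac(3.2, aifO2, schO[, 1], schO[, 2])
  expect_equal(as.numeric(activity(s0)),
               as.numeric(activity(sWater)) + as.numeric(activity(sVasc)),
               tolerance = 1e-9)
})

test_that("noiseless OEF round trips hit the truth to 0.1%", {
  for (e in c(0.45, 0.60)) {
    scan <- simulateO2Tac(e, 32, 3.2, 0.9, aifO2, aifW,
                          schO[, 1], schO[, 2])
    fit <- fitOEF(scan, cbf = 32, cbv = 3.2, lambda = 0.9)
    expect_false(fit$flagged)
    expect_lt(abs(fit$oef / (100 * e) - 1), 1e-5)
  }
  # 0.60 sits above the stage-2 threshold
  scan <- simulateO2Tac(0.60, 32, 3.2, 0.9, aifO2, aifW,
                        schO[, 1], schO[, 2])
  expect_gt(fitOEF(scan, 32, 3.2, 0.9)$oef, 55.7)
})

test_that("missing recirculating-water input is an error", {
  scan <- simulateO2Tac(0.4, 32, 3.2, 0.9, aifO2, aifW,
                        schO[, 1], schO[, 2])
  scan@aif <- list(o2 = aifO2)
  expect_error(fitOEF(scan, 32, 3.2), "recirculating-water")
})

test_that("decay application and correction are inverse operations", {
  scan <- simulateH2oTac(40, 0.9, aifH, sch[, 1], sch[, 2])
  dec <- applyDecay(scan)
  expect_false(dec@decayCorrected)
  expect_true(all(activity(dec) < activity(scan) |
                    activity(scan) == 0))
  back <- correctDecay(dec)
  expect_equal(activity(back), activity(scan), tolerance = 1e-12)
  expect_error(applyDecay(dec), "already")
  expect_error(correctDecay(scan), "already")
})

test_that("uniform phantoms give uniform maps equal to the scalar fit", {
  ph <- simulatePhantomScans(cbf = rep(34, 4), cbv = rep(3.3, 4),
                             oef = rep(48, 4))
  res <- fitParametricMaps(ph$H2O, ph$O2, ph$CO)
  expect_true(all(res$maps$converged))
  expect_lt(max(abs(res$maps$cbf / 34 - 1)), 1e-3)
  expect_lt(max(abs(res$maps$cbv / 3.3 - 1)), 1e-3)
  expect_lt(max(abs(res$maps$oef / 48 - 1)), 1e-2)
  expect_lt(diff(range(res$maps$cbf)), 1e-6)
})

test_that("two-compartment phantom recovers both regions", {
  cbf <- c(rep(40, 3), rep(26, 3))
  cbv <- c(rep(3.2, 3), rep(4.2, 3))
  oef <- c(rep(45, 3), rep(62, 3))
  ph <- simulatePhantomScans(cbf, cbv, oef)
  res <- fitParametricMaps(ph$H2O, ph$O2, ph$CO)
  m <- res$maps
  expect_lt(max(abs(m$cbf - cbf) / cbf), 5e-3)
  expect_lt(max(abs(m$cbv - cbv) / cbv), 5e-3)
  expect_lt(max(abs(m$oef - oef) / oef), 2e-2)
})

test_that("infarct mask removes voxels and can empty the summary", {
  ph <- simulatePhantomScans(cbf = rep(34, 3), cbv = rep(3.3, 3),
                             oef = rep(48, 3))
  res <- fitParametricMaps(ph$H2O, ph$O2, ph$CO,
                           infarctMask = c(TRUE, FALSE, FALSE))
  expect_true(is.na(res$maps$cbf[1]))
  expect_equal(res$roiSummary$nVoxels, 2L)
  all <- fitParametricMaps(ph$H2O, ph$O2, ph$CO,
                           infarctMask = rep(TRUE, 3))
  expect_false(all$roiSummary$available)
  expect_true(is.na(all$roiSummary$cbf))
  expect_error(fitParametricMaps(ph$H2O, ph$O2, ph$CO,
                                 infarctMask = c(TRUE, FALSE)), "mask")
})
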