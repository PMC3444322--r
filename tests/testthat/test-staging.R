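test_that("ranges derive from control mean +/- 1.96 SD", {
  r <- deriveRanges(10, 1, 10, 1, 10, 1)
  expect_equal(r@cbfLower, 8.04)
  expect_equal(r@cbvUpper, 11.96)
  expect_equal(r@oefUpper, 11.96)
  expect_error(deriveRanges(10, 0, 10, 1, 10, 1), "positive")
})

test_that("default ranges are the printed limits", {
  r <- normalRanges()
  expect_equal(c(r@cbfLower, r@cbvUpper, r@oefUpper), c(31.1, 3.9, 55.7))
})

test_that("staging worked examples", {
  expect_equal(classifyStage(28, 3.5, 66), 2L)   # OEF precedence
  expect_equal(classifyStage(35, 3.5, 50), 0L)
  expect_equal(classifyStage(29, 3.5, 50), 1L)
  expect_equal(classifyStage(35, 4.5, 50), 1L)
  expect_error(classifyStage(NA, 3.5, 50), "finite")
})

test_that("values exactly at a bound are normal for that parameter", {
  expect_equal(classifyStage(31.1, 3.9, 55.7), 0L)
})

test_that("classifyStage agrees with the brute-force rule table on a grid", {
  g <- expand.grid(cbf = c(seq(20, 45, by = 1), 31.1, 31.0999, 31.1001),
                   cbv = c(seq(2, 6, by = 0.25), 3.9, 3.8999, 3.9001),
                   oef = c(seq(40, 70, by = 1.5), 55.7, 55.6999, 55.7001))
  got <- classifyStage(g$cbf, g$cbv, g$oef)
  expect_identical(as.integer(got),
                   as.integer(oracleStage(g$cbf, g$cbv, g$oef)))
})

test_that("stage is monotone in CBF and OEF", {
  set.seed(4)
  for (i in 1:100) {
    cbf <- runif(1, 20, 45); cbv <- runif(1, 2, 6); oef <- runif(1, 40, 70)
    s <- classifyStage(cbf, cbv, oef)
    expect_gte(classifyStage(max(cbf - runif(1, 0, 10), 1), cbv, oef), s)
    expect_gte(classifyStage(cbf, cbv, oef + runif(1, 0, 10)), s)
  }
})

test_that("hemispheric ratio and mean transit time arithmetic", {
  expect_equal(hemisphericRatio(28, 32), 0.875)
  expect_equal(hemisphericRatio(30, 30), 1)
  expect_equal(meanTransitTime(3.0, 30), 0.10)
  expect_error(hemisphericRatio(28, 0), "positive")
  expect_error(meanTransitTime(3, 0), "positive")
})

test_that("stageMeasures attaches ratios to ipsilateral rows", {
  m <- data.frame(
    patient_id = rep(c("a", "b"), each = 2),
    side = rep(c("left", "right"), 2),
    role = c("ipsilateral", "contralateral",
             "contralateral", "ipsilateral"),
    cbf = c(28, 32, 40, 36), cbv = c(3.5, 3.2, 3.1, 4.2),
    oef = c(66, 45, 44, 50))
  s <- stageMeasures(m)
  expect_equal(s$stage, c(2L, 0L, 0L, 1L))
  expect_equal(s$cbf_ratio[1], 28 / 32)
  expect_equal(s$oef_ratio[4], 50 / 44)
  expect_equal(s$mtt_ratio[1], (3.5 / 28) / (3.2 / 32))
  expect_true(all(is.na(s$cbf_ratio[c(2, 3)])))
})
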