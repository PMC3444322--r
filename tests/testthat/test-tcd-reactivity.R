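test_that("reactivity is the relative change in mean velocity", {
  rec <- bfvRecording("p1", "left", baseline = rep(50, 10),
                      hypercapnia = rep(60, 10),
                      etco2Before = 40, etco2After = 52,
                      sbpBefore = 150, sbpAfter = 155,
                      dbpBefore = 85, dbpAfter = 88)
  res <- computeReactivity(rec)
  expect_equal(res$reactivity_pct, 20)
  expect_equal(res$category, "impaired")   # boundary inclusive
  expect_equal(res$d_etco2, 12)
  expect_equal(res$d_sbp, 5)
  expect_equal(res$d_dbp, 3)
})

test_that("identical phases give 0% and category 'absent'", {
  rec <- bfvRecording("p1", "right", baseline = c(48, 52, 50),
                      hypercapnia = c(52, 50, 48))
  res <- computeReactivity(rec)
  expect_equal(res$reactivity_pct, 0)
  expect_equal(res$category, "absent")
})

test_that("velocity drop under hypercapnia is steal", {
  # hypercapnic mean at 0.88 x baseline corresponds to -12%
  rec <- bfvRecording("p1", "left", baseline = rep(55, 20),
                      hypercapnia = rep(55 * 0.88, 20))
  res <- computeReactivity(rec)
  expect_equal(res$reactivity_pct, -12)
  expect_equal(res$category, "steal")
})

test_that("zero or negative baseline velocity is an unusable recording", {
  rec <- bfvRecording("p1", "left", baseline = rep(0, 5),
                      hypercapnia = rep(10, 5))
  expect_error(computeReactivity(rec), "unusable")
})

test_that("category rules partition every finite value", {
  expect_equal(classifyReactivity(36), "normal")
  expect_equal(classifyReactivity(20), "impaired")
  r <- seq(-30, 60, by = 0.25)
  cats <- classifyReactivity(r)
  expect_true(all(cats %in% c("normal", "impaired", "absent", "steal")))
  expect_identical(cats == "normal", !isImpaired(r))
  expect_identical(cats[r > 20], rep("normal", sum(r > 20)))
  expect_identical(cats[r < 0], rep("steal", sum(r < 0)))
  expect_identical(cats[r == 0], "absent")
  expect_error(classifyReactivity(NaN), "finite")
})

test_that("the printed discordant reactivity list is 7/7 binary-impaired", {
  vals <- c(-4, 0, 0, 5, 11, 15, 19)
  expect_true(all(isImpaired(vals)))
  cats <- classifyReactivity(vals)
  expect_equal(unname(table(factor(cats, c("steal", "absent", "impaired",
                                           "normal")))[1:3]),
               c(1L, 2L, 4L), ignore_attr = TRUE)
})

test_that("reactivity is invariant to rescaling both phases", {
  set.seed(1)
  for (i in 1:20) {
    b <- runif(15, 30, 80)
    h <- runif(15, 30, 100)
    k <- runif(1, 0.1, 10)
    r1 <- computeReactivity(bfvRecording("p", "left", b, h))$reactivity_pct
    r2 <- computeReactivity(bfvRecording("p", "left", k * b,
                                         k * h))$reactivity_pct
    expect_equal(r2, r1, tolerance = 1e-12)
  }
})

test_that("noiseless recordings recover the true reactivity exactly", {
  coh <- generateCohort(noiselessConfig(6, 17), scans = FALSE)
  tab <- reactivityTable(coh, sides = "both")
  truth <- cohortTruth(coh)
  key <- paste(tab$patient_id, tab$side, sep = ".")
  tkey <- paste(truth$patient_id, truth$side, sep = ".")
  expect_equal(tab$reactivity_pct,
               truth$reactivity_pct[match(key, tkey)],
               tolerance = 1e-9)
})

test_that("reactivityTable restricts to the requested hemisphere", {
  coh <- generateCohort(cohortConfig(nPatients = 4, seed = 2),
                        scans = FALSE)
  ipsi <- reactivityTable(coh)
  expect_equal(nrow(ipsi), 4)
  expect_true(all(ipsi$role == "ipsilateral"))
  both <- reactivityTable(coh, sides = "both")
  expect_equal(nrow(both), 8)
})
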