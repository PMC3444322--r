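test_that("identical seed reproduces the cohort exactly", {
  cfg <- cohortConfig(nPatients = 3, seed = 7)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(cohortTruth(a), cohortTruth(b))
  expect_identical(lapply(cohortRecordings(a), slot, "baseline"),
                   lapply(cohortRecordings(b), slot, "baseline"))
  expect_identical(lapply(cohortScans(a), activity),
                   lapply(cohortScans(b), activity))
  d <- generateCohort(cohortConfig(nPatients = 3, seed = 8))
  expect_false(identical(cohortTruth(a)$cbf, cohortTruth(d)$cbf))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(generateCohort(cohortConfig(nPatients = 2, seed = 1),
                           scans = FALSE))
  expect_identical(before, .Random.seed)
})

test_that("pure stage-0 cohorts stay inside the printed normal box", {
  coh <- generateCohort(noiselessConfig(40, 11, prevalence = c(1, 0, 0)),
                        scans = FALSE)
  ipsi <- subset(cohortTruth(coh), role == "ipsilateral")
  expect_true(all(ipsi$cbf >= 31.1))
  expect_true(all(ipsi$cbv <= 3.9))
  expect_true(all(ipsi$oef <= 55.7))
  expect_true(all(ipsi$true_stage == 0))
})

test_that("pure stage-2 cohorts all exceed the OEF threshold", {
  coh <- generateCohort(noiselessConfig(500, 5, prevalence = c(0, 0, 1)),
                        scans = FALSE)
  ipsi <- subset(cohortTruth(coh), role == "ipsilateral")
  expect_true(all(ipsi$oef > 55.7))
  expect_true(all(ipsi$true_stage == 2))
})

test_that("staging the true values recovers the configured prevalence", {
  n <- 2000
  prev <- c(9, 13, 2) / 24
  coh <- generateCohort(noiselessConfig(n, 21, prevalence = prev),
                        scans = FALSE)
  ipsi <- subset(cohortTruth(coh), role == "ipsilateral")
  staged <- classifyStage(ipsi$cbf, ipsi$cbv, ipsi$oef)
  expect_identical(as.integer(staged), as.integer(ipsi$true_stage))
  for (s in 0:2) {
    # binomial 99% CI around the configured proportion
    half <- qnorm(0.995) * sqrt(prev[s + 1] * (1 - prev[s + 1]) / n)
    expect_lt(abs(mean(staged == s) - prev[s + 1]), half + 1e-12)
  }
})

test_that("stage-0 reactivity distribution has mean - 2 SD at the cut-off", {
  coh <- generateCohort(noiselessConfig(3000, 31, prevalence = c(1, 0, 0)),
                        scans = FALSE)
  r <- subset(cohortTruth(coh), role == "ipsilateral")$reactivity_pct
  expect_lt(abs(mean(r) - 36), 0.5)
  expect_lt(abs(sd(r) - 8), 0.5)
  expect_lt(abs((mean(r) - 2 * sd(r)) - 20), 1.5)
})

test_that("invalid configurations are rejected", {
  expect_error(cohortConfig(nPatients = 0), "positive")
  expect_error(cohortConfig(stagePrevalence = c(0.5, 0.2, 0.2)), "sum to 1")
  expect_error(cohortConfig(tacNoiseModel = "bogus"))
})

test_that("frame noise scale increases TAC perturbation", {
  cfgs <- lapply(c(0.25, 1), function(s)
    cohortConfig(nPatients = 1, seed = 13, tacNoiseScale = s,
                 reactivityNoiseSd = 0))
  ref <- generateCohort(noiselessConfig(1, 13))
  rms <- vapply(cfgs, function(cfg) {
    coh <- generateCohort(cfg)
    nm <- grep("H2O", names(cohortScans(coh)), value = TRUE)[1]
    sqrt(mean((activity(cohortScans(coh)[[nm]]) -
                 activity(cohortScans(ref)[[nm]]))^2))
  }, numeric(1))
  expect_gt(rms[2], rms[1])
  expect_gt(rms[1], 0)
})

test_that("cohort files round-trip through disk", {
  coh <- generateCohort(cohortConfig(nPatients = 2, seed = 3))
  d <- withr::local_tempdir()
  writeCohort(coh, d)
  expect_true(all(file.exists(file.path(d, c("patients.csv", "tacs.csv",
                                             "cohort.json")))))
  back <- readCohort(d)
  expect_equal(cohortTruth(back), cohortTruth(coh),
               ignore_attr = TRUE)
  expect_identical(names(cohortScans(back)) |> sort(),
                   names(cohortScans(coh)) |> sort())
  for (nm in names(cohortScans(coh)))
    expect_equal(activity(cohortScans(back)[[nm]]),
                 activity(cohortScans(coh)[[nm]]), tolerance = 1e-12)
  rec <- cohortRecordings(coh)[[1]]
  rec2 <- cohortRecordings(back)[[paste(rec@patientId, rec@side,
                                        sep = ".")]]
  expect_equal(rec2@baseline, rec@baseline, tolerance = 1e-12)
  cfg2 <- cohortConfigOf(back)
  expect_equal(configToList(cfg2), configToList(cohortConfigOf(coh)))
})
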