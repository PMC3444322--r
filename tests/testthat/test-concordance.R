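test_that("printed study counts reconstruct agreement 12/24 (50%)", {
  # 24 patients: 17 TCD-impaired, 15 PET-compromised, 7 impaired-but-stage-0
  reactivity <- c(rep(10, 10), c(-4, 0, 0, 5, 11, 15, 19), rep(30, 7))
  stage <- c(rep(1, 10),       rep(0, 7),                  rep(1, 5),
             rep(0, 2))
  tab <- crossClassify(reactivity, stage)
  expect_equal(tab@a, 10L)   # concordant compromised
  expect_equal(tab@b, 7L)
  expect_equal(tab@c, 5L)
  expect_equal(tab@d, 2L)
  expect_equal(agreementCount(tab), 12L)
  expect_equal(agreementPct(tab), 50)
})

test_that("all-concordant-normal table has undefined kappa", {
  tab <- crossClassify(rep(30, 6), rep(0, 6))
  expect_equal(agreementPct(tab), 100)
  expect_warning(k <- cohenKappa(tab), "undefined")
  expect_true(is.na(k))
})

test_that("kappa matches the direct (p_o - p_e)/(1 - p_e) formula", {
  tab <- new("ConcordanceTable", a = 10L, b = 7L, c = 5L, d = 2L)
  # independent computation on the 2x2 margins
  n <- 24
  po <- (10 + 2) / n
  pe <- ((10 + 7) * (10 + 5) + (5 + 2) * (7 + 2)) / n^2
  expect_equal(cohenKappa(tab), (po - pe) / (1 - pe), tolerance = 1e-12)
  expect_equal(cohenKappa(tab), -0.116, tolerance = 1e-2)
})

test_that("margins are conserved for arbitrary inputs", {
  set.seed(8)
  for (i in 1:25) {
    n <- sample(4:40, 1)
    r <- runif(n, -20, 50)
    s <- sample(0:2, n, replace = TRUE)
    tab <- crossClassify(r, s)
    expect_equal(tab@a + tab@b, sum(isImpaired(r)))
    expect_equal(tab@a + tab@c, sum(s >= 1))
    expect_equal(tab@a + tab@b + tab@c + tab@d, n)
    expect_gte(agreementPct(tab), 0)
    expect_lte(agreementPct(tab), 100)
    k <- suppressWarnings(cohenKappa(tab))
    if (!is.na(k)) expect_lte(k, 1)
  }
})

test_that("patients present in only one modality are an error", {
  expect_error(crossClassify(c(10, 20), c(1, 0, 0)), "one TCD result")
  expect_error(
    crossClassify(c(10, 20), c(1, 0),
                  patientId = list(tcd = c("a", "b"), pet = c("a", "c"))),
    "only one modality")
})

test_that("group comparison uses the declared test map", {
  d <- data.frame(reactivity_pct = c(rep(10, 8), rep(30, 8)),
                  cbf = c(rnorm(8, 30, 2), rnorm(8, 33, 2)),
                  oef = c(rnorm(8, 48, 3), rnorm(8, 45, 3)))
  out <- compareGroups(d, threshold = 20)
  expect_equal(out$test[out$variable == "cbf"], "t")
  expect_equal(out$test[out$variable == "oef"], "U")
  expect_equal(out$n_low, c(8L, 8L))
})

test_that("identical groups give t = 0 and p = 1", {
  d <- data.frame(reactivity_pct = c(rep(10, 4), rep(30, 4)),
                  cbf = rep(c(28, 30, 32, 34), 2))
  out <- compareGroups(d, threshold = 20, testMap = c(cbf = "t"))
  expect_equal(out$p_value, 1, tolerance = 1e-12)
  expect_equal(out$low_center, out$high_center)
})

test_that("Mann-Whitney p agrees with the exhaustive permutation oracle", {
  cases <- list(
    list(x = c(1.2, 3.4, 5.1), y = c(2.2, 4.9, 6.3, 7.7)),
    list(x = c(10.1, 11.3, 12.8, 13.4), y = c(9.2, 9.9, 10.7, 11.1)),
    list(x = c(0.4, 2.9, 7.7, 8.1, 9.3), y = c(1.1, 1.8, 2.2)))
  for (cs in cases) {
    d <- data.frame(
      reactivity_pct = c(rep(0, length(cs$x)), rep(40, length(cs$y))),
      oef = c(cs$x, cs$y))
    out <- compareGroups(d, threshold = 20, testMap = c(oef = "U"))
    expect_equal(out$p_value, oraclePermU(cs$x, cs$y), tolerance = 1e-10)
  }
})

test_that("correlations: exact cases and the rank-transform oracle", {
  d <- data.frame(patient_id = letters[1:8],
                  reactivity_pct = 1:8,
                  cbf_ratio = 0.5 + 0.05 * (1:8),
                  oef_ratio = c(2.4, 2.2, 1.9, 1.6, 1.1, 0.9, 0.5, 0.2),
                  mtt_ratio = exp(-(1:8) / 3))
  out <- correlateReactivity(d)
  expect_equal(out$estimate[out$variable == "cbf_ratio"], 1)
  expect_equal(out$estimate[out$variable == "oef_ratio"], -1)
  # Spearman equals Pearson on the ranks, exactly
  sp <- out$estimate[out$variable == "oef_ratio"]
  expect_equal(sp, cor(rank(d$reactivity_pct), rank(d$oef_ratio)),
               tolerance = 1e-12)
  set.seed(12)
  d$oef_ratio <- rnorm(8)
  out2 <- correlateReactivity(d)
  expect_equal(out2$estimate[out2$variable == "oef_ratio"],
               cor(rank(d$reactivity_pct), rank(d$oef_ratio)),
               tolerance = 1e-12)
})

test_that("excluding nobody reproduces the full-cohort correlations", {
  set.seed(5)
  d <- data.frame(patient_id = sprintf("p%02d", 1:12),
                  reactivity_pct = rnorm(12, 15, 12),
                  cbf_ratio = rnorm(12, 0.9, 0.1),
                  oef_ratio = rnorm(12, 1.05, 0.08),
                  mtt_ratio = rnorm(12, 1.25, 0.2))
  expect_identical(correlateReactivity(d),
                   correlateReactivity(d, exclude = character()))
  excl <- correlateReactivity(d, exclude = c("p03", "p07", "p11"))
  expect_equal(unique(excl$n), 9L)
  expect_error(correlateReactivity(d[1:4, ],
                                   exclude = c("p01", "p02")), "fewer than 3")
})

test_that("blood-pressure change comparison behaves at the extremes", {
  d <- data.frame(d_sbp = rep(c(0, 5, 10, -5), 4),
                  d_dbp = rep(c(0, 2, 4, -2), 4),
                  agreement = rep(c(TRUE, FALSE), each = 8))
  out <- compareBpChange(d)
  expect_equal(out$p_value, c(1, 1), tolerance = 0.05)
  # strongly shifted groups separate
  set.seed(2)
  d2 <- data.frame(d_sbp = c(rnorm(12, 0, 3), rnorm(12, 40, 3)),
                   d_dbp = c(rnorm(12, 0, 2), rnorm(12, 25, 2)),
                   agreement = rep(c(TRUE, FALSE), each = 12))
  out2 <- compareBpChange(d2)
  expect_lt(max(out2$p_value), 0.01)
  expect_equal(out2$agree_median[1], median(d2$d_sbp[1:12]))
})
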