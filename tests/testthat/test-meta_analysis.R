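test_that("closed forms match the hand-derived worked example", {
  y <- c(0.2, 0, 0.4); v <- c(0.01, 0.01, 0.01)
  dl <- dlTau2(y, v)
  expect_equal(dl$Q, 8, tolerance = 1e-12)
  expect_equal(dl$tau2, 0.03, tolerance = 1e-12)
  re <- poolRandomEffects(y, v, dl$tau2)
  expect_equal(unname(re$weights), rep(25, 3), tolerance = 1e-12)
  expect_equal(re$mu, 0.2, tolerance = 1e-12)
  hk <- hkInference(y, v, dl$tau2, re$mu)
  expect_equal(hk$se, sqrt(1 / 75), tolerance = 1e-12)
  expect_equal(hk$ci, 0.2 + c(-1, 1) * qt(0.975, 2) * sqrt(1 / 75),
               tolerance = 1e-12)
})

test_that("tau2 truncates at zero and Q vanishes for identical effects", {
  dl0 <- dlTau2(c(0.1, 0.1), c(0.02, 0.05))
  expect_identical(dl0$tau2, 0)
  expect_equal(dl0$Q, 0, tolerance = 1e-12)
  # mild spread with large variances: Q < k-1 -> tau2 exactly 0
  dl1 <- dlTau2(c(0.10, 0.11, 0.09), c(1, 1, 1))
  expect_lt(dl1$Q, 2)
  expect_identical(dl1$tau2, 0)
  expect_error(dlTau2(0.1, 0.01), ">=2 studies")
})

test_that("an infinitely imprecise study drops out of the pooled estimate", {
  y <- c(0.2, 0.3, 5); v <- c(0.01, 0.02, 1e9)
  m3 <- poolRandomEffects(y, v, 0)$mu
  m2 <- poolRandomEffects(y[1:2], v[1:2], 0)$mu
  expect_equal(m3, m2, tolerance = 1e-6)
})

test_that("HK inference handles degenerate and near-degenerate input", {
  y <- rep(0.1, 4); v <- rep(0.01, 4)
  m <- metaAnalyze(y, v)
  expect_identical(m@se, 1e-12)
  expect_equal(metaCI(m), c(0.1, 0.1), tolerance = 1e-9)
  expect_lt(metaP(m), 1e-30)
  expect_gte(metaP(m), 1e-300)
  expect_error(hkInference(0.1, 0.01, 0, 0.1), ">=2 studies")

  m95 <- metaAnalyze(c(0.1, 0.3, 0.2), c(0.01, 0.01, 0.02), level = 0.95)
  m99 <- metaAnalyze(c(0.1, 0.3, 0.2), c(0.01, 0.01, 0.02), level = 0.99)
  expect_lt(metaCI(m99)[1], metaCI(m95)[1])
  expect_gt(metaCI(m99)[2], metaCI(m95)[2])

  mfq <- metaAnalyze(y + rnorm(4, 0, 1e-6), v, floorQ = TRUE)
  expect_gte(mfq@se, sqrt(1 / sum(1 / v)))  # floored q >= 1
})

test_that("results agree with a brute-force reference on random instances", {
  withr::local_seed(1234)
  for (i in 1:200) {
    k <- sample(3:10, 1)
    y <- rnorm(k, 0.1, 0.3)
    v <- runif(k, 0.005, 0.2)
    m <- metaAnalyze(y, v)
    b <- bruteMeta(y, v)
    expect_equal(m@tau2, b$tau2, tolerance = 1e-10)
    expect_equal(pooledEffect(m), b$mu, tolerance = 1e-10)
    expect_equal(m@se, b$se, tolerance = 1e-10)
    expect_equal(metaCI(m), b$ci, tolerance = 1e-10)
    expect_true(pooledEffect(m) >= min(y) - 1e-12 &&
                  pooledEffect(m) <= max(y) + 1e-12)
  }
})

test_that("results agree with metafor's DL + Knapp-Hartung", {
  skip_if_not_installed("metafor")
  withr::local_seed(99)
  for (i in 1:25) {
    k <- sample(3:12, 1)
    y <- rnorm(k, 0, 0.4); v <- runif(k, 0.01, 0.3)
    m <- metaAnalyze(y, v)
    f <- suppressWarnings(metafor::rma(yi = y, vi = v, method = "DL",
                                       test = "knha"))
    expect_equal(m@tau2, f$tau2, tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(pooledEffect(m), as.numeric(f$beta), tolerance = 1e-8)
    expect_equal(m@se, f$se, tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(metaP(m), f$pval, tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("variance rescaling scales Q and preserves the FE estimate", {
  withr::local_seed(6)
  y <- rnorm(6); v <- runif(6, 0.01, 0.1)
  for (cc in c(0.5, 2, 10)) {
    expect_equal(dlTau2(y, cc * v)$Q, dlTau2(y, v)$Q / cc,
                 tolerance = 1e-10)
    expect_equal(poolRandomEffects(y, cc * v, 0)$mu,
                 poolRandomEffects(y, v, 0)$mu, tolerance = 1e-10)
  }
})

test_that("contrast pooling excludes ineligible patients, order-invariant", {
  ct <- data.frame(
    patient_id = c("P1", "P2", "P3", "P4"),
    eligible = c(TRUE, TRUE, FALSE, TRUE),
    reason = c("", "", "tail size 5 < 20", ""),
    delta = c(0.2, 0.1, NA, 0.3),
    variance = c(0.01, 0.02, NA, 0.015))
  m <- metaAnalyzeContrasts(ct)
  expect_identical(m@k, 3L)
  expect_identical(m@excluded$patient_id, "P3")
  m2 <- metaAnalyzeContrasts(ct[c(4, 3, 1, 2), ])
  expect_equal(pooledEffect(m2), pooledEffect(m), tolerance = 1e-14)
  expect_equal(metaCI(m2), metaCI(m), tolerance = 1e-14)
  expect_error(metaAnalyzeContrasts(ct[2:3, ]), ">=2 eligible")
})

test_that("correlation pooling uses the covariate-corrected Fisher-z variance", {
  pcs <- data.frame(patient_id = c("A", "B"), r = c(0.5, 0.5),
                    z = atanh(c(0.5, 0.5)), n = c(50L, 50L), c = c(3L, 3L))
  cm <- metaAnalyzeCorrelations(pcs)
  expect_equal(pooledEffect(cm), atanh(0.5), tolerance = 1e-12)
  expect_equal(pooledR(cm), 0.5, tolerance = 1e-12)
  expect_equal(cm@rCI, tanh(metaCI(cm)), tolerance = 1e-14)
  # with the df correction, each study's variance is 1/(50 - 3 - 3)
  expect_equal(unname(cm@weights), rep(44, 2), tolerance = 1e-12)
  cm2 <- metaAnalyzeCorrelations(pcs, dfCorrection = FALSE)
  expect_equal(unname(cm2@weights), rep(47, 2), tolerance = 1e-12)

  null <- data.frame(patient_id = c("A", "B", "C"), r = 0,
                     z = 0, n = 40L, c = 0L)
  cm0 <- metaAnalyzeCorrelations(null)
  expect_equal(pooledR(cm0), 0, tolerance = 1e-12)
  expect_equal(sum(tanh(metaCI(cm0))), 0, tolerance = 1e-9)

  small <- data.frame(patient_id = c("A", "B", "C"), r = 0.2,
                      z = atanh(0.2), n = c(40L, 5L, 40L), c = 3L)
  suppressMessages(cms <- metaAnalyzeCorrelations(small))
  expect_identical(cms@k, 2L)
  expect_identical(cms@excluded$patient_id, "B")
})
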