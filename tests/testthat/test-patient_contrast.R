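test_that("tails are order statistics with deterministic tie-breaks", {
  expr <- setNames(as.numeric(0:9), sprintf("c%02d", 1:10))
  a <- stratifyTails(expr, tailFraction = 0.2, minCells = 2)
  expect_true(a$eligible)
  expect_identical(sort(a$low), c("c01", "c02"))
  expect_identical(sort(a$high), c("c09", "c10"))

  # ties resolved by cell id, lexicographically, locale-independent
  tied <- setNames(rep(0, 10), sprintf("c%02d", 10:1))
  a2 <- stratifyTails(tied, tailFraction = 0.2, minCells = 2)
  expect_identical(a2$low, c("c01", "c02"))

  few <- setNames(1, "c1")
  a3 <- stratifyTails(few, tailFraction = 0.5, minCells = 2)
  expect_false(a3$eligible)
  expect_match(a3$reason, "too few cells")
})

test_that("stratification is invariant to monotone transforms", {
  withr::local_seed(31)
  expr <- setNames(rnorm(157), sprintf("c%03d", 1:157))
  a <- stratifyTails(expr, 0.1, 2)
  b <- stratifyTails(exp(expr), 0.1, 2)
  expect_identical(a$high, b$high)
  expect_identical(a$low, b$low)
})

test_that("delta is the Welch contrast with a variance floor", {
  withr::local_seed(23)
  hi <- sprintf("h%02d", 1:20); lo <- sprintf("l%02d", 1:25)
  # engineer tails with sample mean/variance exactly (0.5, 0.04), (0.3, 0.01)
  scores <- c(setNames(as.numeric(scale(rnorm(20))) * 0.2 + 0.5, hi),
              setNames(as.numeric(scale(rnorm(25))) * 0.1 + 0.3, lo))
  asg <- list(high = hi, low = lo, n = 45, eligible = TRUE, reason = "")
  pc <- computeDelta(scores, asg)
  expect_equal(pc$delta, 0.2, tolerance = 1e-10)
  expect_equal(pc$variance, 0.04 / 20 + 0.01 / 25, tolerance = 1e-10)

  # zero spread in both tails: variance floor kicks in
  flat <- c(setNames(rep(0.5, 20), hi), setNames(rep(0.3, 25), lo))
  pf <- computeDelta(flat, asg, varianceFloor = 1e-8)
  expect_equal(pf$delta, 0.2)
  expect_identical(pf$variance, 1e-8)

  bad <- list(high = character(0), low = character(0), n = 1,
              eligible = FALSE, reason = "too few cells")
  expect_error(computeDelta(scores, bad), "ineligible")
})

test_that("delta is antisymmetric and centers on zero under the null", {
  withr::local_seed(5)
  scores <- setNames(rnorm(100), sprintf("c%03d", 1:100))
  a <- list(high = names(scores)[1:10], low = names(scores)[11:20],
            n = 100, eligible = TRUE, reason = "")
  sw <- list(high = a$low, low = a$high, n = 100, eligible = TRUE,
             reason = "")
  expect_equal(computeDelta(scores, a)$delta,
               -computeDelta(scores, sw)$delta, tolerance = 1e-12)

  deltas <- replicate(1000, {
    s <- rnorm(60)
    mean(s[1:6]) - mean(s[7:12])  # random tails from one distribution
  })
  expect_lt(abs(mean(deltas)), 4 * sd(deltas) / sqrt(1000))
})

test_that("eligibility across a cohort is exactly the floor rule", {
  cfg <- simConfig(nPatients = 8, cellsPerPatient = c(150, 260),
                   nGenes = 150, moduleSize = 5, cellCycleSize = 5,
                   beta = 0, seed = 3)
  sim <- simulateCohort(cfg)
  x <- normalizeCohort(sim$cohort)
  tails <- assignTails(x, sim$truth$driver, tailFraction = 0.10,
                       minCells = 20)
  n <- table(colData(x)$patient_id)
  for (p in names(tails))
    expect_identical(tails[[p]]$eligible,
                     floor(0.10 * n[[p]]) >= 20)
})

test_that("partial correlation reduces to Pearson without covariates", {
  withr::local_seed(8)
  a <- rnorm(60); b <- 0.4 * a + rnorm(60)
  expect_equal(partialCorrelation(a, b)$r, cor(a, b), tolerance = 1e-12)

  # covariates orthogonal to both variables leave the correlation alone
  Z0 <- matrix(rnorm(60 * 2), 60)
  Z <- qr.resid(qr(cbind(1, a, b)), Z0)
  expect_equal(partialCorrelation(a, b, Z)$r, cor(a, b), tolerance = 1e-10)

  # exact-zero correlation maps to z = 0
  bperp <- qr.resid(qr(cbind(1, a)), b)
  pc0 <- partialCorrelation(a, bperp)
  expect_equal(pc0$r, 0, tolerance = 1e-12)
  expect_equal(pc0$z, 0, tolerance = 1e-12)

  expect_error(partialCorrelation(a, b, cbind(a, a)), "rank-deficient")
})

test_that("the Spearman flavor is Pearson on ranks", {
  withr::local_seed(19)
  a <- rexp(40); b <- a^2 + rexp(40)
  expect_equal(partialCorrelation(a, b, method = "spearman")$r,
               cor(a, b, method = "spearman"), tolerance = 1e-12)
  Z <- matrix(rnorm(40), 40)
  expect_equal(partialCorrelation(a, b, Z, method = "spearman")$r,
               partialCorrelation(rank(a), rank(b), Z)$r,
               tolerance = 1e-12)
})

test_that("adjustment removes a library-size-driven association", {
  withr::local_seed(13)
  n <- 2000
  lib <- rnorm(n)
  driver <- 0.8 * lib + rnorm(n)
  score <- 2 * lib + rnorm(n)  # association only through library size
  raw <- partialCorrelation(driver, score)$r
  adj <- partialCorrelation(driver, score, cbind(lib))$r
  expect_gt(raw, 0.3)
  expect_lt(abs(adj), 3 / sqrt(n))
})

test_that("per-patient correlations skip small or degenerate patients", {
  cfg <- simConfig(nPatients = 3, cellsPerPatient = c(60, 80), nGenes = 120,
                   moduleSize = 5, cellCycleSize = 5, beta = 0, seed = 17)
  sim <- simulateCohort(cfg)
  x <- normalizeCohort(sim$cohort)
  sc <- scoreModules(x, sim$signatures, seed = 1,
                     exclude = sim$truth$driver)
  pcs <- patientPartialCorrelations(x, sc[, "module"], sim$truth$driver,
                                    defaultCovariates(x))
  expect_identical(nrow(pcs), 3L)
  expect_true(all(abs(pcs$r) <= 1))
  expect_equal(pcs$z, atanh(pcs$r), tolerance = 1e-9)
  suppressMessages(
    pcs2 <- patientPartialCorrelations(x, sc[, "module"], sim$truth$driver,
                                       minN = 1e6))
  expect_null(pcs2)
})
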