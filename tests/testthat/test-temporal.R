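test_that("Wright-Fisher trajectories conserve copy number and fix absorbed alleles", {
  set.seed(401)
  traj <- simulateWrightFisher(100, nGen = 9, nLoci = 30)
  expect_equal(dim(traj), c(10, 30, 10))
  # every generation, every locus holds exactly ne copies
  expect_true(all(apply(traj, c(1, 2), sum) == 100))
  expect_true(all(traj >= 0))
  # a fixed allele stays fixed (absorbing state)
  fixed <- array(0L, c(1, 1, 2))
  fixed[1, 1, 1] <- 100L
  cnt <- matrix(c(100L, 0L), 1, 2)
  for (g in 1:5) cnt <- halfsibNe:::.wfStep(cnt, 100)
  expect_equal(cnt, matrix(c(100L, 0L), 1, 2))
  # enormous population: frequencies barely move
  big <- simulateWrightFisher(1e7, nGen = 9, nLoci = 5)
  expect_lt(max(abs(big[10, , ] / 1e7 - 0.1)), 0.001)
  expect_error(simulateWrightFisher(100, 9, nAlleles = 10, initFreq = 0.2),
               "must equal 1")
})

test_that("one-generation drift variance matches p(1-p)/ne", {
  set.seed(402)
  ne <- 200
  nrep <- 4000
  p1 <- replicate(nrep, halfsibNe:::.wfStep(matrix(c(60L, 140L), 1, 2), ne)[1, 1] / ne)
  v <- var(p1)
  vTheory <- 0.3 * 0.7 / ne
  seVar <- sqrt((mean((p1 - mean(p1))^4) - v^2) / nrep)
  expect_lt(abs(v - vTheory), 3 * seVar)
})

test_that("temporal sampling is hypergeometric from the stated generations", {
  set.seed(403)
  traj <- simulateWrightFisher(100, nGen = 9, nLoci = 20)
  # sampling everyone returns the population frequencies exactly
  sm <- sampleTemporal(traj, n = 100)
  expect_equal(sm$x, traj[1, , ] / 100)
  expect_equal(sm$y, traj[10, , ] / 100)
  expect_error(sampleTemporal(traj, n = 101), "exceeds")
  # unbiasedness: mean sample frequency tracks the population frequency
  xs <- replicate(2000, sampleTemporal(traj, n = 5)$y[1, 1])
  p <- traj[10, 1, 1] / 100
  expect_lt(abs(mean(xs) - p), 4 * sqrt(p * (1 - p) / 5 / 2000) + 1e-12)
  # variance carries the finite-population factor (N-n)/(N-1)
  vTheory <- p * (1 - p) / 5 * (95 / 99)
  seVar <- sqrt((mean((xs - mean(xs))^4) - var(xs)^2) / 2000)
  expect_lt(abs(var(xs) - vTheory), 4 * seVar)
})

test_that("F statistic matches hand-computed values and edge cases", {
  expect_equal(fStatistic(c(0.5, 0.5), c(0.5, 0.5)), 0)
  # per-allele terms 0.01/0.25 each, mean 0.04
  expect_equal(fStatistic(c(0.5, 0.5), c(0.6, 0.4)), 0.04)
  # shared-fixed allele pairs are excluded entirely
  expect_true(is.na(fStatistic(c(1, 0), c(1, 0))))
  # absent-in-both alleles are dropped from the average
  x <- c(0.5, 0.5, 0)
  y <- c(0.6, 0.4, 0)
  expect_equal(fStatistic(x, y), 0.04)
  # pooled vs locus-wise averaging differ in how loci are weighted when the
  # retained allele counts differ across loci
  xm <- rbind(c(0.5, 0.25, 0.25), c(0.5, 0.5, 0))
  ym <- rbind(c(0.25, 0.5, 0.25), c(1, 0, 0))
  # locus 1 per-allele terms: 0.25, 0.25, 0; locus 2: 1, 1 (third dropped)
  expect_equal(fStatistic(xm, ym, "pooled"), (0.25 + 0.25 + 0 + 1 + 1) / 5)
  expect_equal(fStatistic(xm, ym, "locus"), mean(c(0.5 / 3, 1)))
})

test_that("temporal estimator handles sign and degeneracy as documented", {
  expect_equal(neTemporal(0.1, t = 9, s0 = 50, st = 50), 9 / 0.06)
  # sampling correction exactly cancels F: undefined, flagged as NA
  expect_true(is.na(neTemporal(0.04, t = 9, s0 = 50, st = 50)))
  # correction exceeding F yields a negative estimate, reported as-is
  expect_lt(neTemporal(0.03, t = 9, s0 = 50, st = 50), 0)
  # plan-I census correction shifts the denominator by 1/N
  expect_equal(neTemporal(0.1, 9, 50, 50, censusN = 100),
               9 / (0.1 - 0.04 + 0.01))
  # diploid variant
  expect_equal(neTemporal(0.1, 10, 50, 50, ploidy = "diploid"),
               10 / (2 * (0.1 - 0.02)))
})

test_that("temporal experiments are reproducible and summarized correctly", {
  a <- runTemporalExperiment(100, sampleSize = 5, nReplicates = 30,
                             nLoci = 40, seed = 5)
  b <- runTemporalExperiment(100, sampleSize = 5, nReplicates = 30,
                             nLoci = 40, seed = 5)
  expect_identical(a$replicates, b$replicates)
  expect_equal(a$summary$meanNeTm, mean(a$replicates$neTm))
  expect_equal(a$summary$negativeRate, mean(a$replicates$neTm < 0))
  expect_true(all(a$replicates$status %in% c("ok", "negative", "undefined")))
})

test_that("the estimator recovers the true size at informative sample sizes", {
  # with the correction matched to double-hypergeometric sampling the median
  # is nearly unbiased; the classical plan-I form carries a known upward bias
  matched <- runTemporalExperiment(1000, sampleSize = 300, nReplicates = 400,
                                   correction = "bothEnds", seed = 406)
  expect_lt(abs(matched$summary$medianNeTm - 1000) / 1000, 0.15)
  planI <- runTemporalExperiment(1000, sampleSize = 300, nReplicates = 400,
                                 correction = "planI", seed = 407)
  expect_lt(abs(planI$summary$medianNeTm - 1000) / 1000, 0.20)
  expect_gt(planI$summary$medianNeTm, matched$summary$medianNeTm)
})

test_that("negative estimates become more frequent as true size grows", {
  n1 <- runTemporalExperiment(100, 5, 250, nLoci = 50,
                              seed = 408)$summary$negativeRate
  n2 <- runTemporalExperiment(2000, 5, 250, nLoci = 50,
                              seed = 409)$summary$negativeRate
  expect_gt(n2, n1)
})
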