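test_that("the DMSO baseline is the mean and sample SD of control pairs", {
  b <- dmsoBaseline(c(30, 30, 30))
  expect_equal(b@mean, 30); expect_equal(b@sd, 0)
  b2 <- dmsoBaseline(c(28, 32))
  expect_equal(b2@mean, 30)
  expect_equal(b2@sd, sqrt(8), tolerance = 1e-9)
  expect_error(dmsoBaseline(c(30)), "at least 2")
  # null-plate sampling: mean of n = 32 controls stays within 3 SD/sqrt(32)
  set.seed(20)
  ok <- 0
  for (i in 1:60) {
    e <- rnorm(32, 30, 1.2)
    if (abs(dmsoBaseline(e)@mean - 30) < 3 * 1.2 / sqrt(32)) ok <- ok + 1
  }
  expect_gte(ok, 57)  # >= 95% of seeds
})

test_that("QC gates bound donor intensity in (0.9, 1.1) and background below 1.2x", {
  base <- statBaseline(30, 1, donorMean = 2000, backgroundMean = 200)
  mkWT <- function(dRatio, bgRatio) {
    data.frame(plate_id = "p1", well = c("A01", "A02", "A03", "A04"),
               n_beads = 50,
               mean_intensity = 2000 * dRatio,
               sd_intensity = 100, background = 200 * bgRatio,
               stringsAsFactors = FALSE)
  }
  q <- data.frame(compound_id = "c1", d1 = "A01", da1 = "A02",
                  d2 = "A03", da2 = "A04", stringsAsFactors = FALSE)
  expect_equal(unname(qcGate(q, mkWT(1.05, 1.0), base)), c(TRUE, TRUE))
  expect_equal(unname(qcGate(q, mkWT(1.12, 1.0), base)[1]), FALSE)
  expect_equal(unname(qcGate(q, mkWT(0.88, 1.0), base)[1]), FALSE)
  expect_equal(unname(qcGate(q, mkWT(1.0, 1.25), base)[2]), FALSE)
  # boundaries are exclusive
  expect_equal(unname(qcGate(q, mkWT(1.1, 1.0), base)[1]), FALSE)
  expect_equal(unname(qcGate(q, mkWT(1.0, 1.2), base)[2]), FALSE)
  q2 <- q; q2$da2 <- "H12"
  expect_error(qcGate(q2, mkWT(1, 1), base), "H12")
})

test_that("hits need the averaged and both single values beyond their bands", {
  base <- statBaseline(30, 1)
  cases <- compoundsFromPairs(
    e1 = 30 + c(3.2, 6.0, 2.0, 8.0, -3.2, 3.2),
    e2 = 30 + c(3.8, 1.0, 2.0, -1.8, -3.8, 3.8))
  cases$qc_donor[6] <- FALSE  # QC failure vetoes the last case
  out <- callHits(cases, base)
  expect_identical(out$hit, c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE))
  expect_identical(out$direction,
                   c("increase", "none", "none", "none", "decrease",
                     "none"))
  expect_equal(out$z_score[1], 3.5)
  expect_error(callHits(cases, statBaseline(30, 0)), "degenerate")
})

test_that("Z' matches hand arithmetic and its invariances", {
  expect_equal(zPrime(60, 0, 50, 0), 1)
  expect_equal(zPrime(61.6, 0.6, 51.7, 0.7), 1 - 3 * 1.3 / 9.9,
               tolerance = 1e-12)
  expect_equal(round(zPrime(61.6, 0.6, 51.7, 0.7), 3), 0.606)
  expect_equal(zPrime(59.5, 0.7, 51.7, 0.6), 0.5, tolerance = 1e-12)
  expect_error(zPrime(50, 1, 50, 1), "equal control means")
  # affine invariance: E -> a E + b with a > 0
  set.seed(30)
  for (i in 1:25) {
    mP <- runif(1, 40, 70); mN <- runif(1, 20, 39)
    sP <- runif(1, 0.1, 3); sN <- runif(1, 0.1, 3)
    a <- runif(1, 0.1, 5); b <- runif(1, -20, 20)
    expect_equal(zPrime(a * mP + b, a * sP, a * mN + b, a * sN),
                 zPrime(mP, sP, mN, sN), tolerance = 1e-9)
  }
})

test_that("the minimum separation for a screenable window rounds up to 8%", {
  expect_equal(minControlSeparation(0.7, 0.6, 0.5), 7.8, tolerance = 1e-12)
  expect_identical(ceiling(minControlSeparation(0.7, 0.6, 0.5)), 8)
})

test_that("plate CV and signal-to-background behave as ratios", {
  expect_equal(plateCV(c(30, 30)), 0)
  e <- c(28.8, 31.2)  # mean 30, sd 1.697
  expect_equal(plateCV(e), 100 * sd(e) / 30, tolerance = 1e-12)
  expect_error(plateCV(c(-1, 1)), "zero mean")
  expect_equal(signalToBackground(520, 200), 2.6)
  expect_equal(signalToBackground(200, 200), 1)
  expect_equal(signalToBackground(3 * 520, 3 * 200), 2.6)
  expect_error(signalToBackground(520, 0), "non-positive")
})

test_that("noiseless four-parameter logistic data are recovered exactly", {
  d <- c(5, 10, 15, 20, 30, 40)
  for (p in list(c(2, 7, 12, 1.8), c(30, 36, 8, 1), c(10, 4, 15, 2.5))) {
    r <- p[1] + (p[2] - p[1]) / (1 + (p[3] / d)^p[4])
    fit <- fitDoseResponse(d, r)
    expect_true(fit@converged)
    expect_lt(abs(fit@bottom - p[1]) / max(abs(p[1]), 1), 1e-6)
    expect_lt(abs(fit@top - p[2]) / abs(p[2]), 1e-6)
    expect_lt(abs(fit@ec50 - p[3]) / p[3], 1e-6)
    expect_lt(abs(fit@hill - p[4]) / abs(p[4]), 1e-6)
  }
  expect_false(fitDoseResponse(d, rep(3, 6))@converged)
  expect_error(fitDoseResponse(c(-1, d[-1]), d), "positive")
  expect_error(fitDoseResponse(d[1:3], c(1, 2, 3)), "4 dose")
  # EC50 beyond the top dose is not reported
  r <- 1 + 9 / (1 + (200 / d)^2)
  fit <- fitDoseResponse(d, r)
  expect_true(is.na(fit@ec50))
})

test_that("compound QC removes roughly the artifact-bearing tenth of compounds", {
  # ideal-measurement screen: well intensities taken straight from truth
  lay <- makeScreenLayout(1536)
  cfg <- simulationConfig(seed = 51, beadsPerWell = 2, fieldWidthUm = 120,
                          donorArtifactRate = 0.05,
                          backgroundArtifactRate = 0.05)
  truth <- simulateTruth(lay, cfg)
  tw <- truthWells(truth)
  isD <- tw$role %in% c("D", "DMSO_D")
  wt <- data.frame(plate_id = "p1", well = tw$well, n_beads = 64,
                   mean_intensity = tw$donor_scale / 0.325^2 *
                     ifelse(isD, 1, 1 - tw$true_efret / 100),
                   sd_intensity = 1, background = tw$background,
                   stringsAsFactors = FALSE)
  pairs <- pairFret(wt, lay)
  cmp <- compoundResults(pairs, wt, lay)
  frac <- mean(!(cmp$qc_donor & cmp$qc_background))
  tc <- truthCompounds(truth)
  fracTrue <- mean(tc$donor_mult != 1 | tc$background_mult != 1)
  expect_equal(frac, fracTrue, tolerance = 1e-9)
  expect_gt(frac, 0.05); expect_lt(frac, 0.15)
  # and with no artifact compounds the ideal screen has no QC failures
  cfg0 <- simulationConfig(seed = 52, beadsPerWell = 2, fieldWidthUm = 120,
                           donorArtifactRate = 0,
                           backgroundArtifactRate = 0)
  tw0 <- truthWells(simulateTruth(lay, cfg0))
  isD0 <- tw0$role %in% c("D", "DMSO_D")
  wt0 <- wt
  wt0$mean_intensity <- tw0$donor_scale / 0.325^2 *
    ifelse(isD0, 1, 1 - tw0$true_efret / 100)
  wt0$background <- tw0$background
  cmp0 <- compoundResults(pairFret(wt0, lay), wt0, lay)
  expect_identical(sum(!(cmp0$qc_donor & cmp0$qc_background)), 0L)
})
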