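test_that("flat-field correction is the identity for a uniform field", {
  set.seed(1)
  px <- matrix(runif(100 * 100, 100, 300), 100, 100)
  img <- WellImage(px)
  out <- flatFieldCorrect(img, matrix(1, 100, 100))
  expect_equal(intensityMatrix(out), px, tolerance = 1e-12)
  expect_error(flatFieldCorrect(img, matrix(c(-1, rep(1, 9999)), 100)),
               "positive")
})

test_that("a smooth 20% illumination gradient is estimated and removed", {
  n <- 160
  u <- (col(matrix(0, n, n)) - (n + 1) / 2) / (n / 2)
  v <- (row(matrix(0, n, n)) - (n + 1) / 2) / (n / 2)
  fTrue <- 1 + 0.2 * (0.6 * u - 0.4 * v + 0.3 * u^2)
  fTrue <- fTrue / mean(fTrue)
  # bead-free: background times field
  img <- WellImage(300 * fTrue)
  est <- estimateField(img)
  corr <- flatFieldCorrect(img, est)
  rms <- sqrt(mean((intensityMatrix(corr) - 300)^2)) / 300
  expect_lt(rms, 0.01)
  # ~30% bead coverage: estimate still within 3% RMS
  set.seed(2)
  beads <- matrix(0, n, n)
  for (k in 1:9)
    beads <- beads + 500 * rasterDisk(n, runif(1, 10, 42), runif(1, 10, 42), 17)
  img2 <- WellImage((300 + beads) * fTrue)
  corr2 <- flatFieldCorrect(img2, estimateField(img2))
  bgPix <- beads == 0
  rms2 <- sqrt(mean((intensityMatrix(corr2)[bgPix] - 300)^2)) / 300
  expect_lt(rms2, 0.03)
})

test_that("background is the median of non-bead pixels", {
  img <- WellImage(matrix(180, 80, 80))
  expect_equal(estimateBackground(img), 180)
  set.seed(3)
  n <- 120
  noise <- matrix(rnorm(n * n, 0, 10), n, n)
  img2 <- WellImage(pmax(200 + noise, 0))
  expect_lt(abs(estimateBackground(img2) - 200), 3 * 10 / sqrt(n * n))
  # beads do not bias the estimate
  mask <- rasterDisk(n, 15, 15, 17)
  img3 <- WellImage(pmax(200 + noise + 2000 * mask, 0))
  expect_lt(abs(estimateBackground(img3) - estimateBackground(img2)) /
              estimateBackground(img2), 0.01)
  expect_error(estimateBackground(img3, beadMask = matrix(TRUE, n, n)),
               "10%")
})

test_that("a blank image yields no detections", {
  det <- segmentBeads(WellImage(matrix(150, 100, 100)))
  expect_identical(nrow(det), 0L)
})

test_that("well-separated in-gate disks are all detected and passed", {
  lay <- controlLayout(1)
  cfg <- testConfig(seed = 31, beadsPerWell = 50, fieldWidthUm = 420,
                    beadDiameterSdUm = 0, brightnessCV = 0,
                    readNoiseSD = 0, artifactRate = 0,
                    defocusFraction = 0, illuminationAmplitude = 0)
  sim <- simulatePlate(lay, cfg)
  w <- names(sim$images)[1]
  nTrue <- sum(truthBeads(sim$truth)$well == w)
  det <- segmentBeads(sim$images[[w]])
  expect_identical(sum(det$passed), nTrue)
  expect_true(all(det$circularity[det$passed] > 0.93))
  expect_true(all(det$diameter_um[det$passed] >= 16 &
                    det$diameter_um[det$passed] <= 23))
})

test_that("specks fail the diameter gate and elongated blobs the circularity gate", {
  n <- 300
  img <- 100 +
    500 * rasterDisk(n, 25, 25, 17) +
    500 * rasterDisk(n, 60, 60, 5) +
    500 * rasterEllipse(n, 25, 70, 17, ratio = 3, theta = 0.4)
  det <- segmentBeads(WellImage(img))
  expect_identical(sum(det$passed), 1L)
  near <- function(x, y) which.min((det$x_um - x)^2 + (det$y_um - y)^2)
  expect_true(det$passed[near(25, 25)])
  expect_identical(det$reject_reason[near(60, 60)], "diameter")
  expect_identical(det$reject_reason[near(25, 70)], "circularity")
  # edge-touching objects are excluded
  img2 <- 100 + 500 * rasterDisk(n, 2, 40, 17)
  det2 <- segmentBeads(WellImage(img2))
  expect_identical(det2$reject_reason[1], "edge")
})

test_that("circularity separates disks from squares and ellipses across sizes", {
  for (d in seq(16, 23, by = 1)) {
    cc <- maskCircularity(rasterDisk(140, 22, 22, d))
    expect_gte(cc, 0.93)
    expect_lte(cc, 1.02)
  }
  for (s in c(12, 17, 22))
    expect_lt(maskCircularity(rasterSquare(140, 22, 22, s)), 0.93)
  for (d in c(16, 18, 21)) for (r in c(2, 3))
    expect_lt(maskCircularity(rasterEllipse(200, 30, 30, d, r, 0.3)), 0.93)
})

test_that("per-area quantification matches its closed form", {
  n <- 120
  mask <- rasterDisk(n, 18, 18, 17)
  a <- 0.325^2
  img <- WellImage(0 + 700 * mask)
  expect_equal(quantifyBead(img, mask), 700 / a, tolerance = 1e-12)
  imgB <- WellImage(40 + 700 * mask)
  expect_equal(quantifyBead(imgB, mask, background = 40), 700 / a,
               tolerance = 1e-12)
  expect_error(quantifyBead(img, mask[1:50, 1:50]), "dimensions")
})

test_that("measured per-area intensity is proportional to true brightness", {
  lay <- controlLayout(1)
  cfg <- testConfig(seed = 37, beadsPerWell = 60, fieldWidthUm = 460,
                    brightnessCV = 0.25, defocusFraction = 0,
                    artifactRate = 0)
  sim <- simulatePlate(lay, cfg)
  det <- segmentBeads(sim$images[[1]])
  det <- det[det$passed, ]
  tb <- truthBeads(sim$truth)
  tb <- tb[tb$well == wellName(sim$images[[1]]), ]
  j <- vapply(seq_len(nrow(det)), function(i)
    which.min((tb$x_um - det$x_um[i])^2 + (tb$y_um - det$y_um[i])^2),
    integer(1))
  expect_gt(stats::cor(det$intensity_per_um2, tb$brightness[j]), 0.99)
})

test_that("rescaling an image rescales intensities but not geometry", {
  lay <- controlLayout(1)
  cfg <- testConfig(seed = 41, beadsPerWell = 15, fieldWidthUm = 260)
  sim <- simulatePlate(lay, cfg)
  img <- sim$images[[1]]
  det1 <- segmentBeads(img)
  det2 <- segmentBeads(WellImage(intensityMatrix(img) * 3.5,
                                 pixelSize = pixelSize(img),
                                 wellName = wellName(img)))
  expect_equal(det2$intensity_per_um2, det1$intensity_per_um2 * 3.5,
               tolerance = 1e-9)
  expect_equal(det2$diameter_um, det1$diameter_um)
  expect_equal(det2$circularity, det1$circularity)
})

test_that("well summaries use passed beads and sample SD", {
  det <- data.frame(well = "A01", bead_id = 1:4,
                    x_um = 1:4, y_um = 1:4, area_um2 = 1,
                    diameter_um = 17, perimeter_um = 53,
                    circularity = 1,
                    intensity_per_um2 = c(10, 20, 30, 999),
                    passed = c(TRUE, TRUE, TRUE, FALSE),
                    reject_reason = c(NA, NA, NA, "diameter"))
  img <- WellImage(matrix(100, 80, 80))
  s <- summarizeWell(det, img, background = 100)
  expect_equal(s$n_beads, 3)
  expect_equal(s$mean_intensity, 20)
  expect_equal(s$sd_intensity, 10)
  det$passed <- FALSE
  s0 <- summarizeWell(det, img, background = 100)
  expect_identical(s0$n_beads, 0L)
  expect_true(is.na(s0$mean_intensity))
})

test_that("well-level intensity dispersion reflects the bead brightness CV", {
  lay <- controlLayout(1)
  hits <- 0
  for (seed in 1:8) {
    cfg <- testConfig(seed = 100 + seed, beadsPerWell = 64,
                      fieldWidthUm = 460, brightnessCV = 0.10,
                      defocusFraction = 0, artifactRate = 0)
    sim <- simulatePlate(lay, cfg)
    res <- analyzeWellImage(sim$images[[1]])
    cv <- res$well$sd_intensity / res$well$mean_intensity
    if (cv >= 0.07 && cv <= 0.13) hits <- hits + 1
  }
  expect_gte(hits, 7)
})
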