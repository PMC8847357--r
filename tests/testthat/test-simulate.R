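test_that("identical seeds give bit-identical truth and images", {
  lay <- controlLayout(2)
  cfg <- testConfig(seed = 21, beadsPerWell = 15, fieldWidthUm = 220)
  s1 <- simulatePlate(lay, cfg)
  s2 <- simulatePlate(lay, cfg)
  expect_identical(truthWells(s1$truth), truthWells(s2$truth))
  expect_identical(truthBeads(s1$truth), truthBeads(s2$truth))
  expect_identical(lapply(s1$images, intensityMatrix),
                   lapply(s2$images, intensityMatrix))
  # and the written TIFF bytes are identical
  p1 <- writeWellImage(s1$images[[1]], tempfile(fileext = ".tif"))
  p2 <- writeWellImage(s2$images[[1]], tempfile(fileext = ".tif"))
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("any single well re-renders identically in isolation", {
  lay <- controlLayout(3)
  cfg <- testConfig(seed = 5, beadsPerWell = 10, fieldWidthUm = 200)
  sim <- simulatePlate(lay, cfg)
  w <- names(sim$images)[4]
  again <- renderWellImage(sim$truth, w, cfg)
  expect_identical(intensityMatrix(again),
                   intensityMatrix(sim$images[[w]]))
})

test_that("with no quench and no noise, paired wells carry equal bead signal", {
  lay <- controlLayout(1)
  cfg <- testConfig(seed = 5, beadsPerWell = 20, fieldWidthUm = 280,
                    pairEfretSD = 0, baselineEfret = 0, brightnessCV = 0,
                    readNoiseSD = 0, artifactRate = 0,
                    defocusFraction = 0, illuminationAmplitude = 0)
  sim <- simulatePlate(lay, cfg)
  sig <- vapply(sim$images, function(i)
    sum(intensityMatrix(i)) - cfg@backgroundLevel *
      length(intensityMatrix(i)), numeric(1))
  expect_equal(unname(sig[1]), unname(sig[2]), tolerance = 1e-12)
})

test_that("a rendered 17-um disk covers the analytic pixel area", {
  cfg <- testConfig(seed = 2, fieldWidthUm = 100, readNoiseSD = 0,
                    illuminationAmplitude = 0)
  truth <- new("ScreenTruth", plateId = "p1",
               wells = data.frame(well = "A01", role = "DMSO_D",
                                  compound_id = NA_character_,
                                  pair_id = "dmso01", true_efret = 30,
                                  donor_scale = 320, background = 200,
                                  pop_seed = 1L, well_seed = 1L,
                                  stringsAsFactors = FALSE),
               compounds = data.frame(),
               beads = data.frame(well = "A01", bead_id = 1L,
                                  x_um = 50, y_um = 50,
                                  diameter_um = 17, brightness = 1,
                                  defocused = FALSE, artifact = FALSE,
                                  axis_ratio = 1, angle = 0,
                                  stringsAsFactors = FALSE),
               field = c(1, 0, 0, 0, 0, 0), seed = 2L)
  img <- intensityMatrix(renderWellImage(truth, "A01", cfg))
  # pixels above half the bead amplitude = the disk's footprint
  got <- sum(img > 200 + 320 / 2)
  want <- pi * 8.5^2 / 0.325^2
  expect_lt(abs(got - want) / want, 0.02)
})

test_that("zero beads and zero noise render the background times the field", {
  lay <- controlLayout(1)
  cfg <- testConfig(seed = 3, beadsPerWell = 0, fieldWidthUm = 150,
                    readNoiseSD = 0, artifactRate = 0,
                    illuminationAmplitude = 0.1)
  sim <- simulatePlate(lay, cfg)
  img <- intensityMatrix(sim$images[[1]])
  tw <- truthWells(sim$truth)
  n <- nrow(img)
  f <- beadFRET:::evalFieldMatrix(sim$truth@field, n, n)
  expect_equal(img, round(f * tw$background[1]), tolerance = 1e-12)
})

test_that("rendered artifacts are elongated and fail the circularity gate", {
  # geometry oracle first: an axis-ratio-3 ellipse mask measures < 0.93
  m <- rasterEllipse(240, 39, 39, 17, ratio = 3, theta = 0.6)
  expect_lt(maskCircularity(m), 0.93)
  lay <- controlLayout(1)
  cfg <- testConfig(seed = 13, beadsPerWell = 12, fieldWidthUm = 280,
                    artifactRate = 0.5, defocusFraction = 0)
  sim <- simulatePlate(lay, cfg)
  tb <- truthBeads(sim$truth)
  expect_gte(sum(tb$artifact), 1)
  expect_true(all(tb$axis_ratio[tb$artifact] >= 2))
  det <- segmentBeads(sim$images[[1]])
  art <- tb[tb$artifact & tb$well == wellName(sim$images[[1]]), ]
  for (i in seq_len(nrow(art))) {
    d2 <- (det$x_um - art$x_um[i])^2 + (det$y_um - art$y_um[i])^2
    j <- which.min(d2)
    if (length(j) && d2[j] < 8^2) expect_false(det$passed[j])
  }
})

test_that("bead counts per image track beads/well x imaged fraction", {
  lay <- controlLayout(8)
  cfg <- simulationConfig(seed = 17, beadsPerWell = 100,
                          imagedFraction = 0.19, fieldWidthUm = 300)
  truth <- simulateTruth(lay, cfg)
  counts <- table(factor(truthBeads(truth)$well,
                         levels = truthWells(truth)$well))
  lambda <- 100 * 0.19 * (1 + cfg@artifactRate)
  # 16 wells of Poisson(lambda); mean within 4 sigma
  expect_lt(abs(mean(counts) - lambda), 4 * sqrt(lambda / 16))
})

test_that("spiking hits shifts only the chosen compounds' truth", {
  lay <- makeScreenLayout(96, nCompounds = 6, nDmsoPairs = 4)
  cfg <- testConfig(seed = 23, beadsPerWell = 3, fieldWidthUm = 150)
  truth <- simulateTruth(lay, cfg)
  expect_identical(truthWells(spikeHits(truth, character(0), 5)),
                   truthWells(truth))
  spiked <- spikeHits(truth, c("c002", "c005"), c(6, -6))
  w0 <- truthWells(truth); w1 <- truthWells(spiked)
  moved <- !is.na(w0$compound_id) & w0$compound_id %in% c("c002", "c005")
  expect_equal(w1$true_efret[!moved], w0$true_efret[!moved])
  expect_equal(w1$true_efret[w1$compound_id %in% "c002"],
               w0$true_efret[w0$compound_id %in% "c002"] + 6)
  expect_equal(w1$true_efret[w1$compound_id %in% "c005"],
               w0$true_efret[w0$compound_id %in% "c005"] - 6)
  expect_error(spikeHits(truth, "nope", 5), "nope")
})

test_that("simulated emission spectra peak near 475 nm and quench with E", {
  d <- simulateEmissionSpectrum(1000, 0, "D")
  expect_lte(abs(d@wavelengths[which.max(d@intensities)] - 475), 2)
  da <- simulateEmissionSpectrum(1000, 40, "DA")
  expect_equal(peakIntensity(da) / peakIntensity(d), 0.6,
               tolerance = 1e-9)
  blank <- simulateEmissionSpectrum(1000, 0, "BLANK_D", background = 30)
  expect_true(all(abs(blank@intensities - 30) < 1e-9))
})

test_that("ground-truth tables are written alongside simulated images", {
  lay <- controlLayout(1)
  cfg <- testConfig(seed = 4, beadsPerWell = 5, fieldWidthUm = 150)
  d <- tempfile()
  sim <- simulatePlate(lay, cfg, imageDir = d)
  expect_true(all(file.exists(sim$images)))
  writeScreenTruth(sim$truth, d)
  tw <- read.csv(file.path(d, "truth_wells.csv"))
  expect_identical(nrow(tw), nrow(truthWells(sim$truth)))
  unlink(d, recursive = TRUE)
})
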