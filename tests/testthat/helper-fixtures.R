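# Shared fixtures: small-scale simulation configs and independent
# geometry rasterizers used as oracles for the segmentation code.

PX <- 0.325  # um/pixel used throughout the tests

# Rasterize shapes on a pixel grid, independently of the generator's
# rendering code: hard (unsmoothed) masks from the analytic inequality.
rasterDisk <- function(n, cx, cy, diameterUm, px = PX) {
  x <- (col(matrix(0, n, n)) - 0.5) * px
  y <- (row(matrix(0, n, n)) - 0.5) * px
  (x - cx)^2 + (y - cy)^2 <= (diameterUm / 2)^2
}

rasterEllipse <- function(n, cx, cy, diameterUm, ratio, theta = 0,
                          px = PX) {
  a <- diameterUm / 2 * sqrt(ratio)
  b <- diameterUm / 2 / sqrt(ratio)
  x <- (col(matrix(0, n, n)) - 0.5) * px - cx
  y <- (row(matrix(0, n, n)) - 0.5) * px - cy
  xr <- x * cos(theta) + y * sin(theta)
  yr <- -x * sin(theta) + y * cos(theta)
  (xr / a)^2 + (yr / b)^2 <= 1
}

rasterSquare <- function(n, cx, cy, sideUm, px = PX) {
  x <- (col(matrix(0, n, n)) - 0.5) * px
  y <- (row(matrix(0, n, n)) - 0.5) * px
  abs(x - cx) <= sideUm / 2 & abs(y - cy) <= sideUm / 2
}

maskCircularity <- function(mask, px = PX) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  lab[mask] <- 1L
  area <- sum(mask) * px^2
  per <- croftonPerimeter(lab, px)[1]
  4 * pi * area / per^2
}

# Image from a mask: amplitude on background, as a WellImage
maskImage <- function(mask, amp = 500, bg = 100, px = PX, well = "A01") {
  WellImage(bg + amp * mask, pixelSize = px, wellName = well)
}

# Small, fast simulation settings; noise structure keeps the package
# defaults unless overridden.
testConfig <- function(...) {
  over <- list(...)
  base <- list(beadsPerWell = 30, imagedFraction = 1, fieldWidthUm = 300)
  base[names(over)] <- over
  do.call(simulationConfig, base)
}

controlLayout <- function(nPairs, format = 96, plateId = "p1") {
  makeScreenLayout(format, nCompounds = 0, nDmsoPairs = nPairs,
                   plateId = plateId)
}

# Pool F_D / F_DA over all passed beads of the D / DA wells and compute
# the well-level FRET efficiency.
pooledEfret <- function(beads, layout) {
  w <- layoutWells(layout)
  dWells <- w$well[w$role %in% c("D", "DMSO_D")]
  daWells <- w$well[w$role %in% c("DA", "DMSO_DA")]
  ok <- beads[beads$passed, ]
  fD <- mean(ok$intensity_per_um2[ok$well %in% dWells])
  fDA <- mean(ok$intensity_per_um2[ok$well %in% daWells])
  list(efret = computeEfret(fD, fDA), n = nrow(ok))
}

# Baseline object for statistics-level tests
statBaseline <- function(mean, sd, n = 32L, donorMean = NA_real_,
                         backgroundMean = NA_real_, plateId = "p1") {
  new("DmsoBaseline", plateId = plateId, mean = mean, sd = sd,
      n = as.integer(n), donorMean = donorMean,
      backgroundMean = backgroundMean)
}

# Hit-rule compound table from single-pair E values
compoundsFromPairs <- function(e1, e2, qc = TRUE) {
  data.frame(compound_id = sprintf("c%06d", seq_along(e1)),
             efret_1 = e1, efret_2 = e2,
             efret_avg = averageAdjacentPairs(e1, e2),
             qc_donor = qc, qc_background = qc,
             stringsAsFactors = FALSE)
}
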