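#' Create a simulation configuration
#'
#' Returns a [SimulationConfig-class] populated with the screening-scale
#' defaults: 600 beads dispensed per 1,536-format well with one image
#' covering 19% of the well area (about 114 beads per image), 17 µm mean
#' bead diameter, 0.325 µm pixels, 10% bead-to-bead brightness CV, a 10%
#' smooth illumination field, Gaussian read noise, a 30% baseline FRET
#' for vehicle controls, and 5% each of donor-artifact and
#' background-artifact compounds.
#'
#' @param ... named slot values overriding the defaults (see
#'   [SimulationConfig-class]).
#' @return a validated [SimulationConfig-class].
#' @examples
#' cfg <- simulationConfig(seed = 7, beadsPerWell = 100, imagedFraction = 1)
#' @export
simulationConfig <- function(...) {
  args <- list(...)
  defaults <- list(
    beadsPerWell = 600, imagedFraction = 0.19,
    fieldWidthUm = 660, pixelSizeUm = 0.325,
    beadDiameterMeanUm = 17, beadDiameterSdUm = 1,
    beadDiameterRangeUm = c(14.5, 23), brightnessCV = 0.10,
    defocusFraction = 0.05, defocusSigmaUm = 3,
    artifactRate = 0.05, artifactAxisRatioRange = c(2, 4),
    illuminationAmplitude = 0.10, noiseModel = "gaussian",
    readNoiseSD = 5, poissonScale = 1,
    backgroundLevel = 200, beadAmplitude = 320,
    baselineEfret = 30, pairEfretSD = 0.4,
    donorArtifactRate = 0.05, backgroundArtifactRate = 0.05,
    minSeparationFactor = 1, seed = 1L)
  unknown <- setdiff(names(args), names(defaults))
  if (length(unknown))
    stop("unknown configuration fields: ", paste(unknown, collapse = ", "))
  defaults[names(args)] <- args
  defaults$seed <- as.integer(defaults$seed)
  do.call(new, c(list("SimulationConfig"), defaults))
}

# Deterministic per-well substream seed derived from the master seed and
# the well's row-major index, kept below 2^31.
wellSeed <- function(seed, wellIndex) {
  as.integer((as.double(seed) * 48271 + wellIndex * 7919 + 1) %% 2147483629)
}

truncNorm <- function(n, mean, sd, range) {
  if (sd <= 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  bad <- x < range[1] | x > range[2]
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- x < range[1] | x > range[2]
  }
  x
}

# Random-sequential placement of non-overlapping circles inside the field
# with margin so objects lie fully inside the image.
placeBeads <- function(n, fieldUm, diameters, sepFactor, marginUm) {
  x <- y <- numeric(0)
  placed <- numeric(0)  # radii-equivalent for separation
  tries <- 0L
  maxTries <- 4000L * max(n, 1L)
  i <- 1L
  xs <- ys <- numeric(n)
  while (i <= n && tries < maxTries) {
    tries <- tries + 1L
    m <- marginUm + diameters[i] / 2
    if (2 * m >= fieldUm) break
    cx <- stats::runif(1, m, fieldUm - m)
    cy <- stats::runif(1, m, fieldUm - m)
    if (i > 1L) {
      minSep <- sepFactor * (diameters[seq_len(i - 1L)] + diameters[i]) / 2
      if (any((xs[seq_len(i - 1L)] - cx)^2 +
              (ys[seq_len(i - 1L)] - cy)^2 < minSep^2)) next
    }
    xs[i] <- cx; ys[i] <- cy
    i <- i + 1L
  }
  k <- i - 1L
  list(x = xs[seq_len(k)], y = ys[seq_len(k)], n = k, keep = seq_len(k))
}

#' Simulate the ground truth of one screening plate
#'
#' Draws per-compound effects (optional donor-quench/enhancement and
#' added-background artifact compounds), per-pair true E_FRET values
#' (baseline + compound shift + pair-level variability), and a per-bead
#' population for every D/DA well: centres (random sequential placement
#' with a minimum separation so beads settle as a monolayer), diameters,
#' brightness factors, defocus flags and elongated artifact objects.
#' Everything is driven by the master seed; each well additionally owns a
#' derived substream seed so any single well can be re-rendered in
#' isolation.
#'
#' @param layout a [PlateLayout-class].
#' @param config a [SimulationConfig-class].
#' @return a [ScreenTruth-class].
#' @seealso [renderWellImage()], [spikeHits()], [simulatePlate()]
#' @export
simulateTruth <- function(layout, config) {
  validObject(layout); validObject(config)
  set.seed(config@seed)
  w <- layout@wells
  active <- w[w$role %in% c("D", "DA", "DMSO_D", "DMSO_DA"), , drop = FALSE]
  quartets <- compoundQuartets(layout)

  # compound-level truth
  nC <- nrow(quartets)
  comp <- data.frame(compound_id = as.character(quartets$compound_id),
                     delta_efret = numeric(nC), donor_mult = rep(1, nC),
                     background_mult = rep(1, nC),
                     stringsAsFactors = FALSE)
  if (nC) {
    dA <- stats::runif(nC) < config@donorArtifactRate
    comp$donor_mult[dA] <- sample(c(-1, 1), sum(dA), replace = TRUE) *
      stats::runif(sum(dA), 0.12, 0.30) + 1
    bA <- stats::runif(nC) < config@backgroundArtifactRate
    comp$background_mult[bA] <- stats::runif(sum(bA), 1.25, 2)
  }

  # pair-level true E_FRET
  pairIds <- unique(active$pair_id)
  pairE <- stats::setNames(
    config@baselineEfret + stats::rnorm(length(pairIds), 0,
                                        config@pairEfretSD),
    pairIds)
  pairComp <- stats::setNames(
    active$compound_id[match(pairIds, active$pair_id)], pairIds)
  addE <- stats::setNames(comp$delta_efret, comp$compound_id)
  shift <- ifelse(is.na(pairComp), 0, addE[pairComp])
  pairE <- pmin(pmax(pairE + ifelse(is.na(shift), 0, shift), -99), 99)

  # illumination field shared by the plate (coefficients of 1,u,v,u2,v2,uv)
  g <- stats::runif(5, -1, 1)
  g <- g / max(sum(abs(g)), 1e-9)
  field <- c(1, config@illuminationAmplitude * g)

  idx <- wellNameToIndex(active$well, layout@format)
  wellIdx <- idx[, "row"] * formatDims(layout@format)[2] + idx[, "col"]
  cm <- match(active$compound_id, comp$compound_id)
  dm <- ifelse(is.na(cm), 1, comp$donor_mult[cm])
  bm <- ifelse(is.na(cm), 1, comp$background_mult[cm])
  # the bead population (count, placement, geometry) is drawn from a
  # pair-level substream so the matched D and D+A wells of a pair carry
  # the same dispense; brightness factors and camera noise come from the
  # well-level substream and stay independent between the two wells
  wells <- data.frame(
    well = active$well, role = active$role,
    compound_id = active$compound_id, pair_id = active$pair_id,
    true_efret = unname(pairE[active$pair_id]),
    donor_scale = config@beadAmplitude * dm,
    background = config@backgroundLevel * bm,
    pop_seed = wellSeed(config@seed,
                        match(active$pair_id, pairIds) * 100003),
    well_seed = wellSeed(config@seed, wellIdx),
    stringsAsFactors = FALSE)

  beads <- lapply(seq_len(nrow(wells)), function(i)
    simulateWellBeads(wells$well[i], wells$pop_seed[i],
                      wells$well_seed[i], config))
  beads <- do.call(rbind, beads)

  new("ScreenTruth", plateId = layout@plateId, wells = wells,
      compounds = comp, beads = beads, field = field,
      seed = config@seed)
}

# Bead population of a single well. Geometry (count, placement, sizes,
# artifact shapes, defocus) comes from the pair-shared population
# substream; per-bead brightness from the well-specific substream.
simulateWellBeads <- function(well, popSeed, brightSeed, config) {
  set.seed(popSeed)
  nExp <- config@beadsPerWell * config@imagedFraction
  n <- stats::rpois(1, nExp)
  nArt <- stats::rpois(1, config@artifactRate * nExp)
  m <- n + nArt
  dia <- truncNorm(m, config@beadDiameterMeanUm,
                   config@beadDiameterSdUm, config@beadDiameterRangeUm)
  isArt <- seq_len(m) > n
  ratio <- ifelse(isArt,
                  stats::runif(m, config@artifactAxisRatioRange[1],
                               config@artifactAxisRatioRange[2]), 1)
  defocused <- !isArt & stats::runif(m) < config@defocusFraction
  angle <- stats::runif(m, 0, pi)
  # separation uses each object's rendered footprint: the major axis of
  # elongated artifacts, the blurred skirt of defocused beads
  effDia <- dia * sqrt(ratio) + ifelse(defocused, 4 * config@defocusSigmaUm, 0)
  pos <- placeBeads(m, config@fieldWidthUm, effDia,
                    config@minSeparationFactor, marginUm = 1)
  k <- pos$n
  keep <- pos$keep
  dia <- dia[keep]; isArt <- isArt[keep]; ratio <- ratio[keep]
  defocused <- defocused[keep]; angle <- angle[keep]
  set.seed(brightSeed)
  data.frame(
    well = rep(well, k), bead_id = seq_len(k),
    x_um = pos$x, y_um = pos$y, diameter_um = dia,
    brightness = pmax(stats::rnorm(k, 1, config@brightnessCV), 0.05),
    defocused = defocused, artifact = isArt,
    axis_ratio = ratio, angle = angle,
    stringsAsFactors = FALSE)
}

evalFieldMatrix <- function(coef, nr, nc) {
  u <- (col(matrix(0, nr, nc)) - (nc + 1) / 2) / (nc / 2)
  v <- (row(matrix(0, nr, nc)) - (nr + 1) / 2) / (nr / 2)
  f <- coef[1] + coef[2] * u + coef[3] * v + coef[4] * u^2 +
    coef[5] * v^2 + coef[6] * u * v
  f / mean(f)
}

#' Render the image of one well from simulated ground truth
#'
#' Each in-focus bead is drawn as a uniform disk of its diameter with a
#' soft one-pixel edge; defocused beads use a Gaussian edge profile of the
#' configured blur scale; artifacts are elongated (axis ratio >= 2)
#' soft-edged ellipses of bead-like area. The smooth multiplicative
#' illumination field is applied to signal plus background, then additive
#' Gaussian read noise (or Poisson noise), and pixel values are rounded to
#' integers as a 16-bit camera would.
#'
#' @param truth a [ScreenTruth-class].
#' @param well well name to render.
#' @param config the [SimulationConfig-class] used to build `truth`.
#' @return a [WellImage-class].
#' @export
renderWellImage <- function(truth, well, config) {
  wt <- truth@wells[truth@wells$well == well, , drop = FALSE]
  if (nrow(wt) != 1L) stop("unknown well in truth: ", well)
  beads <- truth@beads[truth@beads$well == well, , drop = FALSE]
  px <- config@pixelSizeUm
  n <- as.integer(round(config@fieldWidthUm / px))
  img <- matrix(0, n, n)

  quench <- if (wt$role %in% c("DA", "DMSO_DA"))
    1 - wt$true_efret / 100 else 1
  for (i in seq_len(nrow(beads))) {
    b <- beads[i, ]
    amp <- wt$donor_scale * b$brightness * quench
    a <- b$diameter_um / 2 * sqrt(b$axis_ratio)
    bb <- b$diameter_um / 2 / sqrt(b$axis_ratio)
    edge <- if (b$defocused) config@defocusSigmaUm else px
    half <- a + 4 * edge
    c0 <- max(1L, floor((b$x_um - half) / px)); c1 <- min(n, ceiling((b$x_um + half) / px))
    r0 <- max(1L, floor((b$y_um - half) / px)); r1 <- min(n, ceiling((b$y_um + half) / px))
    if (c0 > c1 || r0 > r1) next
    xs <- (c0:c1 - 0.5) * px - b$x_um
    ys <- (r0:r1 - 0.5) * px - b$y_um
    X <- matrix(xs, length(ys), length(xs), byrow = TRUE)
    Y <- matrix(ys, length(ys), length(xs))
    xr <- X * cos(b$angle) + Y * sin(b$angle)
    yr <- -X * sin(b$angle) + Y * cos(b$angle)
    rho <- sqrt((xr / a)^2 + (yr / bb)^2)
    signed <- (1 - rho) * bb  # approx. distance to the ellipse edge, um
    cov <- if (b$defocused) stats::pnorm(signed / edge) else
      pmin(pmax(signed / edge + 0.5, 0), 1)
    img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] + amp * cov
  }

  f <- evalFieldMatrix(truth@field, n, n)
  img <- f * (img + wt$background)
  set.seed(wellSeed(wt$well_seed, 1L))
  if (config@noiseModel == "gaussian") {
    if (config@readNoiseSD > 0)
      img <- img + stats::rnorm(length(img), 0, config@readNoiseSD)
  } else {
    img <- stats::rpois(length(img), img / config@poissonScale) *
      config@poissonScale
    img <- matrix(img, n, n)
  }
  img <- pmax(round(img), 0)
  new("WellImage", pixels = img, pixelSize = px, wellName = well,
      channel = "donor")
}

#' Shift the true FRET of selected compounds
#'
#' Adds `deltaE` percentage points to the true E_FRET of every well pair
#' belonging to the listed compounds, leaving all other ground truth
#' untouched. Used to plant known hits in a simulated screen.
#'
#' @param truth a [ScreenTruth-class].
#' @param compounds character vector of compound ids present in the truth.
#' @param deltaE numeric, percentage points; scalar or one per compound.
#' @return the modified [ScreenTruth-class].
#' @export
spikeHits <- function(truth, compounds, deltaE) {
  if (!length(compounds)) return(truth)
  unknown <- setdiff(compounds, truth@compounds$compound_id)
  if (length(unknown))
    stop("unknown compound(s): ", paste(unknown, collapse = ", "))
  deltaE <- rep_len(deltaE, length(compounds))
  comp <- truth@compounds
  wells <- truth@wells
  for (i in seq_along(compounds)) {
    comp$delta_efret[comp$compound_id == compounds[i]] <-
      comp$delta_efret[comp$compound_id == compounds[i]] + deltaE[i]
    sel <- !is.na(wells$compound_id) & wells$compound_id == compounds[i]
    wells$true_efret[sel] <- pmin(pmax(wells$true_efret[sel] + deltaE[i],
                                       -99), 99)
  }
  initialize(truth, wells = wells, compounds = comp)
}

#' Simulate a plate: ground truth plus rendered images
#'
#' Convenience wrapper around [simulateTruth()] and [renderWellImage()].
#' With `imageDir` set, images are written as 16-bit TIFFs named
#' `<plate_id>_<well>.tif` and paths are returned instead of in-memory
#' images (a full 1,536-well plate does not fit in memory at once).
#'
#' @param layout a [PlateLayout-class].
#' @param config a [SimulationConfig-class].
#' @param spikes optional named numeric vector `compound_id -> deltaE`.
#' @param imageDir optional directory for TIFF output.
#' @return list with `truth` ([ScreenTruth-class]) and `images` (named
#'   list of [WellImage-class], or file paths when `imageDir` is given).
#' @export
simulatePlate <- function(layout, config, spikes = NULL, imageDir = NULL) {
  truth <- simulateTruth(layout, config)
  if (!is.null(spikes))
    truth <- spikeHits(truth, names(spikes), unname(spikes))
  wells <- truth@wells$well
  if (is.null(imageDir)) {
    images <- lapply(wells, function(w) renderWellImage(truth, w, config))
    names(images) <- wells
  } else {
    if (!dir.exists(imageDir)) dir.create(imageDir, recursive = TRUE)
    images <- vapply(wells, function(w)
      writeWellImage(renderWellImage(truth, w, config), imageDir,
                     plateId = truth@plateId), character(1))
  }
  list(truth = truth, images = images)
}

#' Write the ground-truth tables of a simulated screen
#'
#' Writes `truth_wells.csv`, `truth_compounds.csv` and `truth_beads.csv`.
#'
#' @param truth a [ScreenTruth-class].
#' @param dir output directory (created if missing).
#' @return the three file paths, invisibly.
#' @export
writeScreenTruth <- function(truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("truth_wells.csv", "truth_compounds.csv",
                            "truth_beads.csv"))
  utils::write.csv(truth@wells, paths[1], row.names = FALSE, quote = FALSE)
  utils::write.csv(truth@compounds, paths[2], row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(truth@beads, paths[3], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Simulate a donor (CFP-like) emission spectrum
#'
#' Emission over 450-600 nm at 1 nm steps with the characteristic CFP
#' double hump (main peak near 475 nm, shoulder near 503 nm). For a
#' donor+acceptor sample the whole spectrum is quenched by the true FRET
#' efficiency; blanks contain background only.
#'
#' @param peak peak amplitude (AU) of the unquenched donor.
#' @param efret true FRET efficiency (percent) quenching the donor.
#' @param kind sample kind ("D", "DA", "BLANK_D", "BLANK_DA").
#' @param background additive offset (AU).
#' @param noiseSD additive Gaussian noise SD (AU).
#' @param rncConcentration sample concentration (nM).
#' @param seed optional RNG seed for the noise.
#' @return an [EmissionSpectrum-class].
#' @export
simulateEmissionSpectrum <- function(peak, efret = 0, kind = "D",
                                     background = 0, noiseSD = 0,
                                     rncConcentration = NA_real_,
                                     seed = NULL) {
  wl <- 450:600
  shape <- exp(-((wl - 475)^2) / (2 * 9^2)) +
    0.55 * exp(-((wl - 503)^2) / (2 * 12^2))
  shape <- shape / max(shape)
  amp <- if (kind %in% c("BLANK_D", "BLANK_DA")) 0 else
    peak * (1 - efret / 100)
  y <- amp * shape + background
  if (noiseSD > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + stats::rnorm(length(wl), 0, noiseSD)
  }
  new("EmissionSpectrum", wavelengths = as.numeric(wl),
      intensities = pmax(y, 0), kind = kind,
      rncConcentration = rncConcentration)
}

#' @rdname ScreenTruth-class
#' @export
setMethod("truthWells", "ScreenTruth", function(object) object@wells)

#' @rdname ScreenTruth-class
#' @export
setMethod("truthCompounds", "ScreenTruth", function(object) object@compounds)

#' @rdname ScreenTruth-class
#' @export
setMethod("truthBeads", "ScreenTruth", function(object) object@beads)

setMethod("show", "ScreenTruth", function(object) {
  cat("ScreenTruth for plate '", object@plateId, "' (seed ", object@seed,
      ")\n  wells: ", nrow(object@wells), ", compounds: ",
      nrow(object@compounds), ", beads: ", nrow(object@beads),
      "\n", sep = "")
  e <- object@wells$true_efret
  if (length(e))
    cat("  true E_FRET: ", round(min(e), 1), " .. ", round(max(e), 1),
        " %\n", sep = "")
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig: ", object@beadsPerWell, " beads/well, ",
      round(100 * object@imagedFraction), "% imaged, field ",
      object@fieldWidthUm, " um at ", object@pixelSizeUm, " um/px\n",
      "  bead ", object@beadDiameterMeanUm, " +/- ",
      object@beadDiameterSdUm, " um, brightness CV ",
      object@brightnessCV, ", noise ", object@noiseModel,
      ", baseline E ", object@baselineEfret, "%, seed ", object@seed,
      "\n", sep = "")
})
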