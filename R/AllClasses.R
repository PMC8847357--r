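#' @import methods
NULL

WELL_ROLES <- c("D", "DA", "BLANK_D", "BLANK_DA", "DMSO_D", "DMSO_DA",
                "BUFFER", "EMPTY")
PLATE_FORMATS <- c(96L, 384L, 1536L)

#' PlateLayout: well roles for one assay plate
#'
#' A `PlateLayout` assigns a role to every addressable well of a 96-, 384-
#' or 1,536-well plate. Compounds are tested in duplicate as paired
#' donor-only (D) and donor+acceptor (DA) wells, so each compound occupies
#' exactly four wells (two D/DA pairs); vehicle-control (DMSO) D/DA pairs
#' provide the per-plate baseline.
#'
#' The `wells` slot holds one row per addressable well with columns
#' `well`, `role`, `compound_id`, `dose_uM`, `pair_id`. Wells not listed in
#' a plate map are `EMPTY`.
#'
#' @slot plateId character plate identifier.
#' @slot format integer, one of 96, 384, 1536.
#' @slot wells data.frame, one row per addressable well (row-major order).
#'
#' @seealso [parsePlateMap()], [makeScreenLayout()], [compoundQuartets()],
#'   [dmsoPairs()]
#' @export
setClass("PlateLayout",
  slots = c(plateId = "character", format = "integer", wells = "data.frame"))

setValidity("PlateLayout", function(object) {
  msg <- character()
  if (length(object@format) != 1L || !object@format %in% PLATE_FORMATS)
    return("format must be one of 96, 384, 1536")
  w <- object@wells
  need <- c("well", "role", "compound_id", "dose_uM", "pair_id")
  if (!all(need %in% names(w)))
    return(paste("wells must have columns:", paste(need, collapse = ", ")))
  expected <- allWellNames(object@format)
  if (nrow(w) != length(expected) || !identical(w$well, expected))
    msg <- c(msg, sprintf(
      "wells must contain all %d wells of the format in row-major order",
      length(expected)))
  bad <- setdiff(unique(w$role), WELL_ROLES)
  if (length(bad))
    msg <- c(msg, paste("unknown roles:", paste(bad, collapse = ", ")))
  cw <- w[w$role %in% c("D", "DA") & !is.na(w$compound_id), , drop = FALSE]
  if (any(w$role %in% c("D", "DA") & is.na(w$compound_id)))
    msg <- c(msg, "compound D/DA wells must carry a compound_id")
  if (any(!w$role %in% c("D", "DA") & !is.na(w$compound_id)))
    msg <- c(msg, "compound_id is only allowed on D/DA wells")
  if (any(!is.na(w$dose_uM) & is.na(w$compound_id)))
    msg <- c(msg, "dose_uM requires a compound_id")
  if (nrow(cw)) {
    splt <- split(cw, cw$compound_id)
    badc <- vapply(splt, function(d) {
      !(nrow(d) == 4L && length(unique(d$well)) == 4L &&
          sum(d$role == "D") == 2L && sum(d$role == "DA") == 2L &&
          length(unique(d$pair_id)) == 2L)
    }, logical(1))
    if (any(badc))
      msg <- c(msg, paste("compounds without exactly 2 D + 2 DA wells",
                          "in 2 pairs:", paste(names(splt)[badc], collapse = ", ")))
    if (object@format == 1536L && length(splt) > 320L)
      msg <- c(msg, "a 1,536-well layout holds at most 320 compounds")
  }
  dm <- w[w$role %in% c("DMSO_D", "DMSO_DA"), , drop = FALSE]
  if (nrow(dm)) {
    if (any(is.na(dm$pair_id)))
      msg <- c(msg, "DMSO wells must carry a pair_id")
    sp <- split(dm, dm$pair_id)
    badp <- vapply(sp, function(d)
      !(nrow(d) == 2L && sum(d$role == "DMSO_D") == 1L &&
          sum(d$role == "DMSO_DA") == 1L), logical(1))
    if (any(badp))
      msg <- c(msg, paste("DMSO pairs without exactly one D and one DA well:",
                          paste(names(sp)[badp], collapse = ", ")))
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' WellImage: a single-channel fluorescence image of one well
#'
#' Pixel intensities are arbitrary fluorescence units (AU), non-negative;
#' `pixelSize` is the physical pixel edge in micrometres (default 0.325 µm
#' for a 20x 0.75 NA high-content configuration). Physical coordinates are
#' measured in µm from the top-left pixel centre; images are 0-based,
#' row-major.
#'
#' @slot pixels numeric matrix of intensities (rows = y, columns = x).
#' @slot pixelSize numeric, µm per pixel edge.
#' @slot wellName character well name (e.g. "A01").
#' @slot channel character, emission channel label.
#' @export
setClass("WellImage",
  slots = c(pixels = "matrix", pixelSize = "numeric",
            wellName = "character", channel = "character"))

setValidity("WellImage", function(object) {
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0) return("pixelSize must be a positive number")
  if (any(dim(object@pixels) < 64L))
    return("image must be at least 64 x 64 pixels")
  if (any(object@pixels < 0)) return("intensities must be non-negative")
  TRUE
})

#' Segmentation and gating parameters for bead detection
#'
#' Defaults reproduce the published gating for 17 µm beads: equivalent
#' diameter in \[16, 23\] µm, circularity > 0.93, and a minimum
#' background-subtracted mean per-area intensity. The seed threshold is
#' background + `thresholdK` robust SDs. Edge-touching objects are
#' excluded because their area and circularity are truncated.
#'
#' `minIntensity` (AU/µm²) defaults to `NA`, meaning 2x the background
#' noise SD expressed per µm² is used, estimated from the image at hand.
#'
#' @slot diameterRange numeric length-2, µm.
#' @slot minCircularity numeric in (0, 1].
#' @slot minIntensity numeric, AU/µm² above background (NA = auto).
#' @slot thresholdK numeric, threshold is background + k * sigma.
#' @slot excludeEdgeTouching logical.
#' @slot splitTouching logical, split touching beads by watershed.
#' @export
setClass("SegmentationParams",
  slots = c(diameterRange = "numeric", minCircularity = "numeric",
            minIntensity = "numeric", thresholdK = "numeric",
            excludeEdgeTouching = "logical", splitTouching = "logical"))

setValidity("SegmentationParams", function(object) {
  if (length(object@diameterRange) != 2L ||
      object@diameterRange[1] >= object@diameterRange[2])
    return("diameterRange must be increasing (low, high)")
  if (object@minCircularity <= 0 || object@minCircularity > 1)
    return("minCircularity must be in (0, 1]")
  if (object@thresholdK <= 0) return("thresholdK must be positive")
  TRUE
})

#' Configuration of the synthetic screen generator
#'
#' Holds every knob of the forward simulator: plate geometry, bead
#' population, optical artifacts, illumination field, noise model, and the
#' statistical structure of the assay (baseline FRET, pair-to-pair
#' variability, compound artifact rates). Defaults emulate the published
#' 1,536-well screening conditions: 600 beads dispensed per well, one
#' image covering 19% of the well, 17 µm nominal bead diameter at
#' 0.325 µm/pixel.
#'
#' @slot beadsPerWell numeric, beads dispensed per well.
#' @slot imagedFraction numeric in (0, 1], fraction of the well imaged.
#' @slot fieldWidthUm numeric, side of the square imaged field (µm).
#' @slot pixelSizeUm numeric, µm per pixel.
#' @slot beadDiameterMeanUm,beadDiameterSdUm numeric, bead diameter
#'   distribution (truncated normal).
#' @slot beadDiameterRangeUm numeric length-2, truncation bounds (µm).
#' @slot brightnessCV numeric, bead-to-bead brightness coefficient of
#'   variation.
#' @slot defocusFraction numeric, fraction of beads rendered out of focus.
#' @slot defocusSigmaUm numeric, Gaussian blur scale of defocused beads.
#' @slot artifactRate numeric, expected non-circular artifacts per bead.
#' @slot artifactAxisRatioRange numeric length-2, artifact elongation.
#' @slot illuminationAmplitude numeric, relative amplitude of the smooth
#'   multiplicative illumination field.
#' @slot noiseModel character, "gaussian" or "poisson".
#' @slot readNoiseSD numeric, additive Gaussian read noise SD (AU).
#' @slot poissonScale numeric, AU per photon-equivalent for "poisson".
#' @slot backgroundLevel numeric, well autofluorescence background (AU).
#' @slot beadAmplitude numeric, mean in-focus donor bead amplitude above
#'   background (AU).
#' @slot baselineEfret numeric, true E_FRET (%) of DMSO-control pairs.
#' @slot pairEfretSD numeric, pair-to-pair SD of true E_FRET (%).
#' @slot donorArtifactRate numeric, fraction of compounds that quench or
#'   enhance donor fluorescence beyond the QC window.
#' @slot backgroundArtifactRate numeric, fraction of compounds that add
#'   background fluorescence beyond the QC window.
#' @slot minSeparationFactor numeric, minimum centre separation as a
#'   multiple of the mean of two bead diameters (1 = non-touching).
#' @slot seed integer master seed; each well derives its own substream.
#' @seealso [simulationConfig()], [simulateTruth()], [renderWellImage()]
#' @export
setClass("SimulationConfig",
  slots = c(beadsPerWell = "numeric", imagedFraction = "numeric",
            fieldWidthUm = "numeric", pixelSizeUm = "numeric",
            beadDiameterMeanUm = "numeric", beadDiameterSdUm = "numeric",
            beadDiameterRangeUm = "numeric", brightnessCV = "numeric",
            defocusFraction = "numeric", defocusSigmaUm = "numeric",
            artifactRate = "numeric", artifactAxisRatioRange = "numeric",
            illuminationAmplitude = "numeric", noiseModel = "character",
            readNoiseSD = "numeric", poissonScale = "numeric",
            backgroundLevel = "numeric", beadAmplitude = "numeric",
            baselineEfret = "numeric", pairEfretSD = "numeric",
            donorArtifactRate = "numeric", backgroundArtifactRate = "numeric",
            minSeparationFactor = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@imagedFraction <= 0 || object@imagedFraction > 1)
    msg <- c(msg, "imagedFraction must be in (0, 1]")
  if (object@beadsPerWell < 0) msg <- c(msg, "beadsPerWell must be >= 0")
  for (s in c("defocusFraction", "donorArtifactRate",
              "backgroundArtifactRate")) {
    v <- slot(object, s)
    if (v < 0 || v > 1) msg <- c(msg, paste(s, "must be in [0, 1]"))
  }
  if (object@artifactRate < 0) msg <- c(msg, "artifactRate must be >= 0")
  for (s in c("fieldWidthUm", "pixelSizeUm", "beadDiameterMeanUm",
              "backgroundLevel", "beadAmplitude", "poissonScale"))
    if (slot(object, s) <= 0) msg <- c(msg, paste(s, "must be positive"))
  if (!object@noiseModel %in% c("gaussian", "poisson"))
    msg <- c(msg, "noiseModel must be 'gaussian' or 'poisson'")
  if (abs(object@baselineEfret) >= 100)
    msg <- c(msg, "baselineEfret must be in (-100, 100)")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Ground truth of a simulated screen
#'
#' Slot `wells`: one row per non-empty well with its role, true E_FRET,
#' donor amplitude, background, compound multipliers and the
#' well-specific RNG seed. Slot `compounds`: true effect per compound
#' (delta E_FRET, donor-scale and background multipliers). Slot `beads`:
#' every rendered object with centre, diameter, brightness factor, defocus
#' and artifact flags. Slot `field` holds the illumination-field
#' coefficients shared by all wells of the plate.
#'
#' @slot plateId character.
#' @slot wells,compounds,beads data.frame ground-truth tables.
#' @slot field numeric, illumination polynomial coefficients.
#' @slot seed integer master seed.
#' @export
setClass("ScreenTruth",
  slots = c(plateId = "character", wells = "data.frame",
            compounds = "data.frame", beads = "data.frame",
            field = "numeric", seed = "integer"))

setValidity("ScreenTruth", function(object) {
  w <- object@wells
  if (nrow(w)) {
    e <- w$true_efret[!is.na(w$true_efret)]
    if (length(e) && any(e <= -100 | e >= 100))
      return("true E_FRET must lie in (-100, 100)")
    if (any(w$background < 0)) return("backgrounds must be >= 0")
  }
  if (nrow(object@beads) && any(object@beads$diameter_um <= 0))
    return("bead diameters must be positive")
  TRUE
})

#' Smooth illumination field model
#'
#' A second-degree polynomial surface in normalized image coordinates,
#' fitted to non-bead pixels and normalized to mean 1 over the field of
#' view.
#'
#' @slot coef numeric length-6 coefficients of (1, u, v, u^2, v^2, uv).
#' @slot dim integer length-2 reference image dimensions.
#' @export
setClass("IlluminationField",
  slots = c(coef = "numeric", dim = "integer"))

#' Fluorometer emission spectrum
#'
#' Donor (CFP) emission spectrum, 450-600 nm at 1 nm steps in the
#' published protocol. `rncConcentration` (nM) carries the
#' scintillation-derived sample concentration used for the
#' concentration-corrected solution FRET calculation.
#'
#' @slot wavelengths numeric, nm, strictly increasing.
#' @slot intensities numeric, AU, non-negative.
#' @slot kind character, one of "D", "DA", "BLANK_D", "BLANK_DA".
#' @slot rncConcentration numeric, nM (NA if unknown).
#' @export
setClass("EmissionSpectrum",
  slots = c(wavelengths = "numeric", intensities = "numeric",
            kind = "character", rncConcentration = "numeric"))

setValidity("EmissionSpectrum", function(object) {
  if (length(object@wavelengths) != length(object@intensities))
    return("wavelengths and intensities must have equal length")
  if (any(diff(object@wavelengths) <= 0))
    return("wavelengths must be strictly increasing")
  if (any(object@intensities < 0))
    return("intensities must be non-negative")
  if (!object@kind %in% c("D", "DA", "BLANK_D", "BLANK_DA"))
    return("kind must be D, DA, BLANK_D or BLANK_DA")
  TRUE
})

#' Per-plate DMSO baseline
#'
#' Mean and sample SD of the vehicle-control pair E_FRET values of one
#' plate (n = 32 pairs in the default 1,536-well layout), plus the mean
#' donor bead intensity and mean background of the control D wells used by
#' the compound QC gates.
#'
#' @slot plateId character.
#' @slot mean,sd numeric, E_FRET percent.
#' @slot n integer, number of control pair values.
#' @slot donorMean numeric, AU/µm².
#' @slot backgroundMean numeric, AU.
#' @export
setClass("DmsoBaseline",
  slots = c(plateId = "character", mean = "numeric", sd = "numeric",
            n = "integer", donorMean = "numeric", backgroundMean = "numeric"))

setValidity("DmsoBaseline", function(object) {
  if (object@n < 2L) return("a baseline needs at least 2 control pairs")
  if (!is.na(object@sd) && object@sd < 0) return("sd must be >= 0")
  TRUE
})

#' Four-parameter logistic dose-response fit
#'
#' response = bottom + (top - bottom) / (1 + (EC50/dose)^hill).
#' `ec50` is reported only when the plateau is sampled (top dose above the
#' fitted EC50); otherwise it is NA and the fit is flagged accordingly.
#'
#' @slot doses numeric, µM, strictly positive.
#' @slot responses numeric, E_FRET percent (or delta vs DMSO).
#' @slot bottom,top,ec50,hill numeric fitted parameters.
#' @slot converged logical.
#' @export
setClass("DoseResponseFit",
  slots = c(doses = "numeric", responses = "numeric", bottom = "numeric",
            top = "numeric", ec50 = "numeric", hill = "numeric",
            converged = "logical"))

setValidity("DoseResponseFit", function(object) {
  if (any(object@doses <= 0)) return("doses must be strictly positive")
  if (isTRUE(object@converged) && !is.na(object@ec50) && object@ec50 <= 0)
    return("EC50 must be positive for a converged fit")
  TRUE
})
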