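#' Default segmentation parameters for 17 µm beads
#'
#' @param diameterRange accepted equivalent-diameter range, µm.
#' @param minCircularity minimum circularity (4*pi*A/P^2).
#' @param minIntensity minimum background-subtracted mean per-area
#'   intensity (AU/µm²); `NA` means 2x the background noise SD per µm².
#' @param thresholdK seed threshold in robust background SDs.
#' @param excludeEdgeTouching drop objects touching the image border.
#' @param splitTouching split touching objects by distance-transform
#'   watershed.
#' @return a [SegmentationParams-class].
#' @export
segmentationParams <- function(diameterRange = c(16, 23),
                               minCircularity = 0.93,
                               minIntensity = NA_real_,
                               thresholdK = 3,
                               excludeEdgeTouching = TRUE,
                               splitTouching = TRUE) {
  new("SegmentationParams", diameterRange = as.numeric(diameterRange),
      minCircularity = minCircularity, minIntensity = minIntensity,
      thresholdK = thresholdK, excludeEdgeTouching = excludeEdgeTouching,
      splitTouching = splitTouching)
}

shiftPad <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Crofton perimeter of every labelled object
#'
#' Estimates object perimeters from boundary intercept counts along the
#' two axis and two diagonal directions (Cauchy-Crofton quadrature with
#' four directions). Unbiased for disks, which is what the circularity
#' gate needs: a rasterized circle measures within ~1% of pi*d.
#'
#' @param labels integer label matrix (0 = background).
#' @param pixelSize µm per pixel.
#' @return numeric vector of perimeters (µm), one per label.
#' @export
croftonPerimeter <- function(labels, pixelSize = 1) {
  K <- max(labels)
  if (K == 0L) return(numeric(0))
  storage.mode(labels) <- "integer"
  trans <- function(b) {
    d <- labels != b
    tabulate(labels[d & labels > 0L], nbins = K) +
      tabulate(b[d & b > 0L], nbins = K)
  }
  nh <- trans(shiftPad(labels, 0L, 1L))
  nv <- trans(shiftPad(labels, 1L, 0L))
  nd1 <- trans(shiftPad(labels, 1L, 1L))
  nd2 <- trans(shiftPad(labels, 1L, -1L))
  (pi / 8) * (nh + nv + (nd1 + nd2) / sqrt(2)) * pixelSize
}

#' Estimate the illumination field from one or more well images
#'
#' Bright (bead) pixels are masked with a robust threshold, each image is
#' normalized by its own background median so wells with different
#' backgrounds pool, and a second-degree polynomial surface in normalized
#' image coordinates is least-squares fitted to the pooled non-bead
#' pixels. The returned field is normalized to mean 1.
#'
#' @param images a [WellImage-class] or list of them (same dimensions).
#' @param subsample fit every `subsample`-th pixel for speed.
#' @return an [IlluminationField-class].
#' @seealso [flatFieldCorrect()], [evaluateField()]
#' @export
estimateField <- function(images, subsample = 4L) {
  if (is(images, "WellImage")) images <- list(images)
  if (!length(images)) stop("at least one image is required")
  dm <- dim(images[[1]]@pixels)
  uu <- vv <- zz <- list()
  for (i in seq_along(images)) {
    px <- images[[i]]@pixels
    if (!identical(dim(px), dm))
      stop("all images must share dimensions")
    med <- stats::median(px)
    sig <- stats::mad(px)
    keep <- px < med + 3 * max(sig, 1e-9)
    ridx <- row(px)[keep]; cidx <- col(px)[keep]
    sel <- seq(1L, length(ridx), by = subsample)
    if (!length(sel)) stop("all pixels are masked as foreground")
    uu[[i]] <- (cidx[sel] - (dm[2] + 1) / 2) / (dm[2] / 2)
    vv[[i]] <- (ridx[sel] - (dm[1] + 1) / 2) / (dm[1] / 2)
    zz[[i]] <- px[keep][sel] / med
  }
  u <- unlist(uu); v <- unlist(vv); z <- unlist(zz)
  fit <- stats::lm.fit(cbind(1, u, v, u^2, v^2, u * v), z)
  new("IlluminationField", coef = unname(fit$coefficients),
      dim = as.integer(dm))
}

#' Evaluate an illumination field as a matrix
#'
#' @param field an [IlluminationField-class], or a numeric matrix passed
#'   through unchanged (after mean-1 normalization).
#' @param dim integer length-2 target dimensions.
#' @return numeric matrix with mean 1.
#' @export
evaluateField <- function(field, dim = NULL) {
  if (is.matrix(field)) {
    f <- field / mean(field)
  } else {
    stopifnot(is(field, "IlluminationField"))
    if (is.null(dim)) dim <- field@dim
    f <- evalFieldMatrix(field@coef, dim[1], dim[2])
  }
  if (any(f <= 0)) stop("illumination field must be strictly positive")
  f
}

#' Flat-field correct a well image
#'
#' Divides the image by the illumination field after rescaling the field
#' to mean 1, so the global intensity scale is preserved. FRET
#' efficiencies are ratios of donor intensities and are therefore
#' invariant to any common rescaling of the corrected images.
#'
#' @param image a [WellImage-class].
#' @param field an [IlluminationField-class] or a strictly positive
#'   matrix of the image's dimensions.
#' @return the corrected [WellImage-class].
#' @export
flatFieldCorrect <- function(image, field) {
  f <- evaluateField(field, dim(image@pixels))
  if (!identical(dim(f), dim(image@pixels)))
    stop("field dimensions do not match the image")
  initialize(image, pixels = pmax(image@pixels / f, 0))
}

#' Estimate the per-pixel background of a well image
#'
#' Median intensity over non-bead pixels. Robust to the bead brightness
#' because beads cover a minority of the field.
#'
#' @param image a [WellImage-class].
#' @param beadMask optional logical matrix marking bead (foreground)
#'   pixels to exclude; by default a robust threshold
#'   (median + 3 * MAD) is used.
#' @return background level, AU.
#' @export
estimateBackground <- function(image, beadMask = NULL) {
  px <- image@pixels
  if (is.null(beadMask)) {
    med <- stats::median(px)
    beadMask <- px > med + 3 * max(stats::mad(px), 1e-9)
  }
  if (!identical(dim(beadMask), dim(px)))
    stop("beadMask dimensions do not match the image")
  free <- !beadMask
  if (mean(free) < 0.10)
    stop("fewer than 10% of pixels are available for background estimation")
  stats::median(px[free])
}

#' Segment and gate beads in a well image
#'
#' Thresholds the image at background + k robust SDs, fills holes, labels
#' connected components (optionally splitting touching components by
#' distance-transform watershed), and measures each component: area,
#' Crofton perimeter, equivalent-circle diameter `2*sqrt(area/pi)`,
#' circularity `4*pi*area/perimeter^2`, and background-subtracted mean
#' intensity per µm². Components failing the diameter, circularity or
#' intensity gates, or touching the image edge, are returned with
#' `passed = FALSE` and a `reject_reason` of `"diameter"`,
#' `"circularity"`, `"intensity"` or `"edge"` (first failing gate in that
#' order of precedence after `"edge"`). Components smaller than a 2 µm
#' equivalent diameter are unresolvable noise specks and are dropped
#' before measurement rather than reported as rejected objects.
#'
#' @param image a (flat-field corrected) [WellImage-class].
#' @param params a [SegmentationParams-class].
#' @return data.frame with one row per detected object: `well`,
#'   `bead_id`, `x_um`, `y_um`, `area_um2`, `diameter_um`,
#'   `perimeter_um`, `circularity`, `intensity_per_um2`, `passed`,
#'   `reject_reason`; attribute `background` carries the background level.
#' @export
segmentBeads <- function(image, params = segmentationParams()) {
  px <- image@pixels
  p <- image@pixelSize
  pixArea <- p^2
  med <- stats::median(px)
  sig <- max(stats::mad(px), 1e-9)
  bg <- med
  mask <- px > bg + params@thresholdK * sig
  empty <- data.frame(well = character(), bead_id = integer(),
                      x_um = numeric(), y_um = numeric(),
                      area_um2 = numeric(), diameter_um = numeric(),
                      perimeter_um = numeric(), circularity = numeric(),
                      intensity_per_um2 = numeric(), passed = logical(),
                      reject_reason = character(),
                      stringsAsFactors = FALSE)
  if (!any(mask)) { attr(empty, "background") <- bg; return(empty) }
  bg <- stats::median(px[!mask])
  m <- EBImage::fillHull(matrix(as.numeric(mask), nrow(px), ncol(px)))
  lab <- if (params@splitTouching)
    EBImage::watershed(EBImage::distmap(m), tolerance = 1) else
      EBImage::bwlabel(m)
  lab <- matrix(as.integer(lab), nrow(px), ncol(px))
  K <- max(lab)
  if (K == 0L) { attr(empty, "background") <- bg; return(empty) }

  npix <- tabulate(lab, nbins = K)
  # components below a 2 um equivalent diameter are unresolvable noise
  # specks (single pixels above threshold), not objects; drop them
  # before measurement rather than reporting them as rejected beads
  minPix <- pi / pixArea   # area of a 2 um diameter disk, in pixels
  if (any(npix < minPix)) {
    keep <- which(npix >= minPix)
    if (!length(keep)) { attr(empty, "background") <- bg; return(empty) }
    map <- integer(K); map[keep] <- seq_along(keep)
    nz <- lab > 0L
    lab[nz] <- map[lab[nz]]
    K <- length(keep)
    npix <- tabulate(lab, nbins = K)
  }
  sumI <- rowsum(px[lab > 0L], lab[lab > 0L])[, 1]
  sumR <- rowsum(row(px)[lab > 0L], lab[lab > 0L])[, 1]
  sumC <- rowsum(col(px)[lab > 0L], lab[lab > 0L])[, 1]
  area <- npix * pixArea
  dia <- 2 * sqrt(area / pi)
  per <- croftonPerimeter(lab, p)
  circ <- 4 * pi * area / per^2
  inten <- (sumI - bg * npix) / area
  edgeLabs <- unique(c(lab[1, ], lab[nrow(px), ], lab[, 1], lab[, ncol(px)]))
  onEdge <- seq_len(K) %in% edgeLabs[edgeLabs > 0L]

  minInt <- params@minIntensity
  if (is.na(minInt)) minInt <- 2 * stats::mad(px[!mask]) / pixArea

  reason <- rep(NA_character_, K)
  reason[inten < minInt] <- "intensity"
  reason[circ < params@minCircularity] <- "circularity"
  reason[dia < params@diameterRange[1] |
           dia > params@diameterRange[2]] <- "diameter"
  if (params@excludeEdgeTouching) reason[onEdge] <- "edge"
  out <- data.frame(
    well = rep(image@wellName, K), bead_id = seq_len(K),
    x_um = (sumC / npix - 0.5) * p, y_um = (sumR / npix - 0.5) * p,
    area_um2 = area, diameter_um = dia, perimeter_um = per,
    circularity = circ, intensity_per_um2 = inten,
    passed = is.na(reason), reject_reason = reason,
    stringsAsFactors = FALSE)
  attr(out, "background") <- bg
  out
}

#' Mean background-subtracted intensity per µm² over a bead mask
#'
#' @param image a [WellImage-class].
#' @param mask logical matrix of the bead's pixels (same dimensions as
#'   the image).
#' @param background per-pixel background level (AU) to subtract.
#' @return AU/µm².
#' @export
quantifyBead <- function(image, mask, background = 0) {
  px <- image@pixels
  if (!identical(dim(mask), dim(px)))
    stop("mask dimensions do not match the image")
  n <- sum(mask)
  if (n == 0L) stop("empty bead mask")
  (sum(px[mask]) - background * n) / (n * image@pixelSize^2)
}

#' Summarize a well from its gated bead detections
#'
#' Mean and sample SD of per-area intensity over passed beads only;
#' `n_beads` counts passed beads. When no bead passes, the mean and SD are
#' `NA` (flagged by `n_beads = 0`).
#'
#' @param detections output of [segmentBeads()].
#' @param image the corresponding [WellImage-class] (used for the
#'   background estimate when `background` is NULL).
#' @param background optional per-pixel background level (AU).
#' @param plateId plate identifier.
#' @return one-row data.frame in the per-well schema
#'   `plate_id,well,n_beads,mean_intensity,sd_intensity,background`.
#' @export
summarizeWell <- function(detections, image, background = NULL,
                          plateId = "plate1") {
  if (is.null(background)) {
    background <- attr(detections, "background")
    if (is.null(background)) background <- estimateBackground(image)
  }
  ok <- detections$passed
  n <- sum(ok)
  data.frame(
    plate_id = plateId,
    well = if (nrow(detections)) detections$well[1] else image@wellName,
    n_beads = n,
    mean_intensity = if (n >= 1L) mean(detections$intensity_per_um2[ok])
      else NA_real_,
    sd_intensity = if (n >= 2L) stats::sd(detections$intensity_per_um2[ok])
      else if (n == 1L) 0 else NA_real_,
    background = background,
    stringsAsFactors = FALSE)
}

#' Analyze one well image: segmentation plus per-well summary
#'
#' @param image a [WellImage-class].
#' @param params a [SegmentationParams-class].
#' @param field optional illumination field applied before segmentation.
#' @param plateId plate identifier.
#' @return list with `beads` (per-bead rows in the result-table schema)
#'   and `well` (one per-well row).
#' @export
analyzeWellImage <- function(image, params = segmentationParams(),
                             field = NULL, plateId = "plate1") {
  if (!is.null(field)) image <- flatFieldCorrect(image, field)
  det <- segmentBeads(image, params)
  wellRow <- summarizeWell(det, image, plateId = plateId)
  beads <- data.frame(
    plate_id = rep(plateId, nrow(det)), well = det$well,
    bead_id = det$bead_id, x_um = det$x_um, y_um = det$y_um,
    diameter_um = det$diameter_um, circularity = det$circularity,
    intensity_per_um2 = det$intensity_per_um2, passed = det$passed,
    reject_reason = det$reject_reason, stringsAsFactors = FALSE)
  list(beads = beads, well = wellRow)
}

#' Analyze a set of well images into per-bead and per-well tables
#'
#' Flat-field estimation is per image by default (`fieldFrom =
#' "each"`): the smooth field is fitted to the image's own non-bead
#' pixels and divided out before segmentation. `fieldFrom = "none"`
#' skips correction; a pre-computed [IlluminationField-class] can also be
#' supplied.
#'
#' @param images list of [WellImage-class] objects, or a directory of
#'   `<plate_id>_<well>.tif` files.
#' @param params a [SegmentationParams-class].
#' @param fieldFrom "each", "none", or an [IlluminationField-class].
#' @param plateId plate identifier.
#' @param pixelSize µm/pixel used when reading images from a directory.
#' @return list with `beads` and `wells` tables ([resultTables] schemas).
#' @export
analyzeWellImages <- function(images, params = segmentationParams(),
                              fieldFrom = "each", plateId = "plate1",
                              pixelSize = 0.325) {
  if (is.character(images) && length(images) == 1L && dir.exists(images)) {
    paths <- list.files(images, pattern = "\\.tiff?$", full.names = TRUE)
    images <- lapply(paths, readWellImage, pixelSize = pixelSize)
  }
  res <- lapply(images, function(img) {
    field <- if (is(fieldFrom, "IlluminationField")) fieldFrom
      else if (identical(fieldFrom, "each")) estimateField(img)
      else NULL
    analyzeWellImage(img, params, field = field, plateId = plateId)
  })
  list(beads = do.call(rbind, lapply(res, `[[`, "beads")),
       wells = do.call(rbind, lapply(res, `[[`, "well")))
}
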