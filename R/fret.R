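#' FRET efficiency by donor quenching
#'
#' E_FRET (%) = (1 - F_DA / F_D) * 100, where F_D is the donor
#' fluorescence in the donor-only sample and F_DA the donor fluorescence
#' in the presence of the acceptor. Values are not clamped: negative
#' efficiencies (donor enhancement, compound artifacts) are reported with
#' their sign. The ratio is invariant to any common rescaling of both
#' intensities.
#'
#' @param fD donor-only intensity (AU or AU/µm²), must be positive.
#' @param fDA donor intensity in the presence of acceptor (same units).
#' @return E_FRET in percent (vectorized).
#' @examples
#' computeEfret(200, 40)   # 80
#' computeEfret(100, 110)  # -10
#' @export
computeEfret <- function(fD, fDA) {
  if (any(!is.finite(fD)) || any(fD <= 0))
    stop("F_D must be positive for E_FRET to be defined")
  (1 - fDA / fD) * 100
}

#' Average two adjacent pair FRET measurements
#'
#' The screen tests every compound in two adjacent D/DA well pairs; the
#' reported value is the arithmetic mean of the two single-pair
#' efficiencies, which halves the measurement variance. Undefined inputs
#' propagate as NA.
#'
#' @param e1,e2 single-pair E_FRET values (percent).
#' @return their mean (vectorized).
#' @export
averageAdjacentPairs <- function(e1, e2) (e1 + e2) / 2

#' Peak emission intensity of a spectrum
#'
#' Mean of the 5 highest emission intensities (the donor peak region,
#' ~475 nm for CFP), robust to single-wavelength noise.
#'
#' @param spectrum an [EmissionSpectrum-class] (>= 5 points).
#' @return peak intensity, AU.
#' @export
peakIntensity <- function(spectrum) {
  y <- spectrum@intensities
  if (length(y) < 5L) stop("spectrum must have at least 5 points")
  mean(sort(y, decreasing = TRUE)[1:5])
}

#' Solution FRET from emission spectra with concentration correction
#'
#' Blank-subtracts the donor peak intensity of the D and D+A samples and
#' divides each by its own radiolabel-derived sample concentration before
#' forming the efficiency, so unequal readthrough yields of the two
#' translation reactions cancel:
#' F_D = (peak(D) - peak(blank_D)) / \[RNC\]_D and likewise for D+A, then
#' E = (1 - F_DA/F_D) * 100.
#'
#' @param d,da [EmissionSpectrum-class] of the donor-only and
#'   donor+acceptor samples; their `rncConcentration` slots (nM) are used
#'   unless `concD`/`concDA` are given.
#' @param blankD,blankDA matched blank (non-fluorescent) spectra.
#' @param concD,concDA optional concentrations (nM) overriding the slots.
#' @return E_FRET in percent.
#' @export
solutionEfret <- function(d, da, blankD, blankDA,
                          concD = NULL, concDA = NULL) {
  if (is.null(concD)) concD <- d@rncConcentration
  if (is.null(concDA)) concDA <- da@rncConcentration
  if (is.na(concD) || is.na(concDA) || concD <= 0 || concDA <= 0)
    stop("positive RNC concentrations are required for both samples")
  fD <- (peakIntensity(d) - peakIntensity(blankD)) / concD
  fDA <- (peakIntensity(da) - peakIntensity(blankDA)) / concDA
  if (fD <= 0)
    stop("blank-corrected donor intensity is not positive")
  computeEfret(fD, fDA)
}

#' Fold change of FRET upon ribosome release
#'
#' Ratio of the released-state to the ribosome-bound efficiency (e.g.
#' RNase digestion releasing the nascent chain). Reported unrounded.
#'
#' @param eBound E_FRET of the ribosome-bound state (percent, > 0).
#' @param eReleased E_FRET after release (percent).
#' @return fold change.
#' @export
releaseFoldChange <- function(eBound, eReleased) {
  if (any(eBound <= 0))
    stop("bound-state E_FRET must be positive for a fold change")
  eReleased / eBound
}

#' Pair donor and donor+acceptor wells and compute E_FRET
#'
#' Joins the per-well table to the layout's D/DA pairs (compound pairs
#' and DMSO control pairs) and computes one efficiency per pair from the
#' mean per-area bead intensities. Pairs whose donor well has no passed
#' beads, or a non-positive mean intensity, get `NA`.
#'
#' @param wellTable per-well table ([resultTables] schema).
#' @param layout the [PlateLayout-class].
#' @return data.frame `plate_id,pair_id,compound_id,role,d_well,da_well,`
#'   `F_D,F_DA,efret` with `role` "compound" or "dmso".
#' @export
pairFret <- function(wellTable, layout) {
  w <- layout@wells
  paired <- w[!is.na(w$pair_id), , drop = FALSE]
  ids <- unique(paired$pair_id)
  rows <- lapply(ids, function(pid) {
    pw <- paired[paired$pair_id == pid, , drop = FALSE]
    dRole <- pw$role %in% c("D", "DMSO_D")
    dWell <- pw$well[dRole]; daWell <- pw$well[!dRole]
    if (length(dWell) != 1L || length(daWell) != 1L)
      stop("pair ", pid, " is not a D/DA pair")
    di <- match(dWell, wellTable$well); dai <- match(daWell, wellTable$well)
    if (is.na(di) || is.na(dai))
      stop("pair ", pid, " references wells missing from the well table")
    fD <- wellTable$mean_intensity[di]
    fDA <- wellTable$mean_intensity[dai]
    ef <- if (is.na(fD) || is.na(fDA) || fD <= 0) NA_real_ else
      computeEfret(fD, fDA)
    data.frame(plate_id = wellTable$plate_id[di], pair_id = pid,
               compound_id = pw$compound_id[1],
               role = if (any(pw$role == "DMSO_D")) "dmso" else "compound",
               d_well = dWell, da_well = daWell,
               F_D = fD, F_DA = fDA, efret = ef,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
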