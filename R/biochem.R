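AVOGADRO <- 6.02214e23

#' RNC concentration from scintillation counting
#'
#' \[RNC\] = (cpm_S - cpm_B) / (CE x SA x vol), in pmol/ml = nM, where
#' cpm_S and cpm_B are the 14C counts per minute of the sample and its
#' matched blank, CE the counting efficiency (0.95 for 14C in the
#' published protocol), SA the specific activity of the radiolabelled
#' lysine in dpm/pmol, and vol the sample volume in ml.
#'
#' @param cpmS,cpmB sample and blank counts/min.
#' @param SA specific activity, dpm/pmol.
#' @param vol sample volume, ml.
#' @param CE counting efficiency, fraction in (0, 1].
#' @return concentration in nM.
#' @examples
#' rncConcentration(1995, 95, SA = 400, vol = 2.5)  # 2 nM
#' @export
rncConcentration <- function(cpmS, cpmB, SA, vol, CE = 0.95) {
  if (CE <= 0 || CE > 1) stop("counting efficiency must be in (0, 1]")
  if (SA <= 0) stop("specific activity must be positive")
  if (vol <= 0) stop("volume must be positive")
  if (any(cpmS < cpmB))
    stop("sample counts below blank counts give a negative concentration")
  (cpmS - cpmB) / (CE * SA * vol)
}

#' Theoretical saturation density of ribosomes on a flat surface
#'
#' Densest packing of circles in the plane applied to the ribosome
#' cross-section: density = eta_h / (pi r^2) with the hexagonal packing
#' coefficient eta_h = pi / (2 sqrt(3)) ~ 0.9069 and ribosome radius
#' r = 12.5 nm (25 nm diameter), giving 1,847.6 ~ 1,850 ribosomes/µm².
#'
#' @param etaH packing coefficient in (0, 1].
#' @param radiusUm ribosome radius in µm (default 0.0125).
#' @return ribosomes per µm².
#' @examples
#' signif(saturationDensity(), 3)  # 1850
#' @export
saturationDensity <- function(etaH = pi / (2 * sqrt(3)),
                              radiusUm = 0.0125) {
  if (etaH <= 0 || etaH > 1) stop("packing coefficient must be in (0, 1]")
  if (radiusUm <= 0) stop("ribosome radius must be positive")
  etaH / (pi * radiusUm^2)
}

#' Bead batch surface geometry
#'
#' Per-bead surface area uses the nominal sphere (pi d^2), ignoring
#' porosity, matching the theoretical-saturation framing of the assay.
#'
#' @param diameterUm nominal bead diameter, µm.
#' @param count number of beads.
#' @return data.frame with `diameter_um`, `count`, `per_bead_area_um2`,
#'   `total_area_um2`, `per_bead_volume_um3`.
#' @export
beadBatch <- function(diameterUm, count) {
  if (any(diameterUm <= 0)) stop("bead diameters must be positive")
  if (any(count < 0)) stop("bead counts must be non-negative")
  data.frame(diameter_um = diameterUm, count = count,
             per_bead_area_um2 = pi * diameterUm^2,
             total_area_um2 = count * pi * diameterUm^2,
             per_bead_volume_um3 = pi / 6 * diameterUm^3)
}

#' Surface density of bound molecules
#'
#' Molecules bound per total calculated bead surface area.
#'
#' @param molecules number of molecules bound.
#' @param batch a [beadBatch()] row (or anything with
#'   `total_area_um2` > 0).
#' @return molecules per µm².
#' @export
surfaceDensity <- function(molecules, batch) {
  area <- sum(batch$total_area_um2)
  if (area <= 0) stop("total bead surface area must be positive")
  molecules / area
}

#' Fraction of theoretical geometric saturation
#'
#' @param density achieved surface density, molecules/µm².
#' @param etaH,radiusUm passed to [saturationDensity()].
#' @return fraction (0.27 means 27% of saturation).
#' @export
saturationFraction <- function(density, etaH = pi / (2 * sqrt(3)),
                               radiusUm = 0.0125) {
  density / saturationDensity(etaH, radiusUm)
}

#' Capture efficiency of a bead-binding reaction
#'
#' RNCs bound divided by RNCs offered in the binding reaction, in
#' percent.
#'
#' @param boundPmol amount bound, pmol (>= 0).
#' @param inputPmol amount in the binding reaction, pmol (> 0).
#' @return percent.
#' @examples
#' captureEfficiency(0.4, 0.8)  # 50
#' @export
captureEfficiency <- function(boundPmol, inputPmol) {
  if (any(inputPmol <= 0)) stop("input amount must be positive")
  if (any(boundPmol < 0)) stop("bound amount must be non-negative")
  if (any(boundPmol > inputPmol))
    stop("bound amount cannot exceed the input amount")
  100 * boundPmol / inputPmol
}

#' Convert an amount of substance to a molecule count
#'
#' @param mol amount in moles (>= 0).
#' @return number of molecules (amount x Avogadro constant).
#' @examples
#' signif(molesToMolecules(0.4e-18), 2)  # 2.4e5 molecules from 0.4 amol
#' @export
molesToMolecules <- function(mol) {
  if (any(mol < 0)) stop("amounts must be non-negative")
  mol * AVOGADRO
}

#' Plan bead batches of equal aggregate surface area
#'
#' For each candidate diameter, the number of beads providing the target
#' aggregate surface area: count = round(target / (pi d^2)). Counts for
#' 17/34/100 µm beads scale as 1 : 1/4 : ~1/34.6.
#'
#' @param targetAreaUm2 target aggregate surface area, µm².
#' @param diametersUm candidate bead diameters, µm.
#' @return data.frame `diameter_um`, `count`.
#' @examples
#' target <- beadBatch(17, 2e5)$total_area_um2
#' planBeadBatches(target, c(17, 34, 100))  # 2e5, 5e4, 5780
#' @export
planBeadBatches <- function(targetAreaUm2, diametersUm) {
  if (any(diametersUm <= 0)) stop("diameters must be positive")
  data.frame(diameter_um = diametersUm,
             count = round(targetAreaUm2 / (pi * diametersUm^2)))
}

#' Effective concentration of bead-bound molecules
#'
#' Treats all molecules bound on a bead's surface as if dissolved in the
#' bead's own spherical volume: c = density x 4 pi R^2 / ((4/3) pi R^3 x
#' N_A) = 3 density / (R N_A), converted to mol/L. At 500 molecules/µm²
#' on 17 µm beads this is ~0.29 µM, roughly a hundredfold above the ~2 nM
#' solution concentration the beads were loaded from.
#'
#' @param densityPerUm2 surface density, molecules/µm².
#' @param beadRadiusUm bead radius, µm.
#' @return effective concentration, mol/L.
#' @export
effectiveBoundConcentration <- function(densityPerUm2, beadRadiusUm) {
  if (any(beadRadiusUm <= 0)) stop("bead radius must be positive")
  if (any(densityPerUm2 < 0)) stop("density must be non-negative")
  # molecules/um^3 -> mol/L: 1 um^-3 = 1e15 L^-1
  (3 * densityPerUm2 / beadRadiusUm) * 1e15 / AVOGADRO
}
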