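---
title: "Solid-support FRET screening: models, parameters and design choices"
author: "beadFRET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Solid-support FRET screening: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beadFRET)
```

# The assay and its readout

beadFRET analyzes screens in which ribosome-bound nascent chain
complexes (RNCs) carrying a CFP donor — with or without an acceptor dye
in the nascent chain — are immobilized on Ni-chelating beads, dispensed
into 96-, 384- or 1,536-well plates, and imaged by single-channel
high-content fluorescence microscopy. Because the acceptor quenches the
donor when the chain is compact, the FRET efficiency is read out from
the donor channel alone:

$$E_\mathrm{FRET}\,(\%) = \left(1 - \frac{F_{DA}}{F_D}\right)\times 100$$

where $F_D$ and $F_{DA}$ are the mean per-area bead fluorescence of a
matched donor-only (D) well and its donor+acceptor (D+A) partner well.
One D/DA well pair yields one efficiency; compounds are tested as two
adjacent pairs (four wells) and reported as the average of the two
measurements, which halves the measurement variance. The ratio is
invariant to any common rescaling of both channels, which is why
instrument-software changes that rescale intensities leave the assay
unchanged — a property the test suite checks explicitly.

Negative efficiencies are reported, not clamped: compounds that enhance
donor fluorescence or decrease FRET are genuine screen outcomes (a
signed scale is required because roughly half of realistic hits decrease
FRET).

# Image analysis

Each well image passes through four stages.

**Flat-field correction.** The microscope's illumination varies smoothly
across the field. `estimateField()` masks bright (bead) pixels with a
robust threshold (median + 3 MAD), normalizes each image by its own
background median, and least-squares fits a second-degree polynomial in
normalized image coordinates to the pooled non-bead pixels.
`flatFieldCorrect()` divides the image by the mean-1-normalized surface,
preserving the global intensity scale. Because the FRET ratio is scale
free, any flat-field algorithm that removes the *shape* of the field
leaves efficiencies unchanged; the tests verify both the ~1% RMS
recovery of a known 20% gradient and the invariance of the final
efficiencies under global rescaling.

**Background.** The per-well background is the median intensity of
non-bead pixels (`estimateBackground()`); at least 10% of pixels must be
available. The median makes the estimate insensitive to bead brightness.

**Segmentation and gating.** `segmentBeads()` thresholds at background +
$k\sigma$ (robust $\sigma$, default $k = 3$), fills holes, labels
connected components, and optionally splits touching components with a
distance-transform watershed. Each component is measured by its area
$A$, perimeter $P$, equivalent-circle diameter $2\sqrt{A/\pi}$ and
circularity $4\pi A / P^2$. Objects pass only if the equivalent diameter
lies in [16, 23] µm (for 17 µm beads), circularity exceeds 0.93, the
background-subtracted mean per-area intensity exceeds a minimum (by
default twice the background noise SD per µm² — the published protocol
applies an unspecified "threshold pixel intensity"; this default
excludes dim debris without inventing a number), and the object does not
touch the image edge (edge objects have truncated area and circularity).
Each rejected object carries a reason (`diameter`, `circularity`,
`intensity`, `edge`).

The perimeter uses the Cauchy–Crofton four-direction intercept
quadrature, which is essentially unbiased for disks: rasterized circles
of 16–23 µm at 0.325 µm/pixel measure circularity 0.99–1.01, so real
beads clear the 0.93 gate with margin, while squares measure ≈0.88,
axis-ratio-2 ellipses ≈0.84 and ratio-3 ellipses ≈0.67 — all rejected.
(Quadrature over four directions slightly underestimates polygon
perimeters, so a square measures above the ideal $\pi/4 \approx 0.785$;
what matters for gating is that every non-circular artifact falls well
below 0.93.) Diameter is the equivalent-circle diameter from area, not a
caliper width: it is robust to boundary noise and consistent with the
16–23 µm gate.

**Quantification.** A bead's intensity is the background-subtracted
pixel sum over its mask divided by the mask area in µm²
(`quantifyBead()`); a well is summarized by the mean and sample SD of
per-area intensity over *passed* beads only (`summarizeWell()`).

# Plate statistics and hit calling

Every plate carries vehicle-control (DMSO) D/DA pairs — 32 pairs in the
default 1,536-well layout. Their pair efficiencies give the per-plate
baseline mean and sample SD (`dmsoBaseline()`; SD uses the $n-1$
denominator throughout, appropriate for small control sets).

Compounds are screened by two gates and one decision rule:

* **Donor QC**: every donor well of the compound must lie strictly
  within (0.9, 1.1) × the DMSO donor mean — a ≥10% quench or
  enhancement of donor fluorescence is a compound artifact, not FRET.
  Gating every well rather than the duplicate mean is the stricter of
  the two readings of the protocol and is the one implemented.
* **Background QC**: the background of all four wells must stay below
  1.2 × the DMSO background mean (added well fluorescence).
* **Hit rule**: the averaged (N = 2) efficiency must deviate from the
  DMSO mean by more than 3 SD *and* both single-pair values by more than
  1.75 SD on the same side. The same-side requirement is implied by the
  rule's purpose: an average pushed outside 3 SD by one wild single is
  an irreproducible artifact. The per-plate SD (not a global SD) defines
  the bands.

The joint rule is strictly stricter than the naive ±3 SD cut
($2\Phi(-3) \approx 0.27\%$); the test suite checks the realized null
rate against an independent Monte-Carlo evaluation of the rule at
$10^5$ simulated compounds. No further multiple-testing correction is
applied, matching screening practice for this rule.

Assay quality uses the standard window statistic
$Z' = 1 - 3(\mathrm{SD}_P + \mathrm{SD}_N)/|\overline{X}_P -
\overline{X}_N|$ (`zPrime()`), the plate CV (`plateCV()`) and
signal-to-background (`signalToBackground()`). With control SDs of 0.7%
and 0.6% E~FRET~, solving the $Z'$ equation shows a control separation
of 7.8% — in practice an 8% FRET window — is needed for $Z' > 0.5$
(`minControlSeparation()`). Published control values of 51.7 ± 0.7 vs
61.6 ± 0.6 give $Z' = 0.606$ by this formula; a printed value of 0.70
for the same controls is not reproducible from those numbers (the ±
values may be SEMs of replicate experiments), so the package exposes the
formula and its inputs and makes no attempt to match 0.70.

# Dose–response fitting

`fitDoseResponse()` fits the four-parameter logistic
$r(d) = \mathrm{bottom} + (\mathrm{top} - \mathrm{bottom}) /
(1 + (\mathrm{EC}_{50}/d)^{h})$ by Levenberg–Marquardt least squares
with data-driven starts (plateaus from the extreme doses, EC50 from
half-maximal interpolation) plus a small deterministic multi-start grid
over Hill slopes and the dose-window centre, keeping the best
sum-of-squares fit. EC50 is bounded to [min dose/10, max dose × 10] and
is reported only when the plateau is sampled (fitted EC50 below the top
dose); flat data are flagged as non-converged. Because the 4PL is
invariant under swapping bottom/top while negating the Hill slope, fits
are canonicalized to a positive Hill with `bottom` the zero-dose
asymptote.

The recovery simulation study in the test suite uses a 6-point 5–40 µM
design with 3 replicates and noise SD equal to 2% of the curve's
dynamic range, with the true EC50 at the geometric centre of the dose
window (14 µM) and Hill 2, so that both plateaus are sampled and the
EC50 is identifiable; under these conditions the fitter recovers the
EC50 within ±25% in well over 90% of runs. This is a designed recovery
study, not a universal guarantee: the same 6-point design cannot
constrain shallow curves (Hill ≈ 1) to ±25% at this noise level, nor an
EC50 lying outside the dose window — with six doses spanning only
5–40 µM, a sub-5-µM EC50 is reported but poorly determined.

# Biochemical calculators

`rncConcentration()` implements the scintillation-counting conversion
$[\mathrm{RNC}] = (\mathrm{cpm}_S - \mathrm{cpm}_B)/(\mathrm{CE}\times
\mathrm{SA}\times\mathrm{vol})$ in pmol/ml = nM, with the ¹⁴C counting
efficiency defaulting to 0.95. The same concentrations normalize
solution FRET measurements (`solutionEfret()`): donor peak intensities
(mean of the 5 highest spectral points near 475 nm) are blank-subtracted
and divided by each sample's concentration before the efficiency is
formed — division by concentration is the only normalization that makes
D and D+A samples comparable at unequal readthrough yields.

Geometry: `saturationDensity()` computes the densest-circle-packing
ceiling $\eta_h/(\pi r^2)$ with $\eta_h = \pi/(2\sqrt 3) \approx 0.9069$
and ribosome radius 12.5 nm, ≈1,848 (1,850 to 3 s.f.) ribosomes/µm².
Bead areas use the nominal sphere $\pi d^2$, deliberately ignoring
agarose porosity — achieved densities are meant to be compared against
the *geometric* ceiling. `effectiveBoundConcentration()` treats all
bound molecules as dissolved in the bead's own spherical volume,
$3\rho/(R N_A)$; at 500 molecules/µm² on 17 µm beads this gives
≈0.29 µM, a ~100-fold concentration over the ~2 nM loading solution.
This volume convention is the only parameter-free choice and is stated
rather than claimed exact: published figures in the 0.16–0.31 µM range
imply a slightly different effective radius.

# The synthetic screen generator

Because raw screen images are instrument-bound, every stage is validated
against `simulateTruth()`/`renderWellImage()`, a forward model with
known ground truth:

* **Beads** are uniform disks with a soft one-pixel edge (the analysis
  uses mean per-area intensity, which is independent of the radial
  profile, so a projected-sphere profile would add nothing but cost);
  diameters are truncated-normal around 17 µm; per-bead brightness has a
  configurable CV (default 10% — bead-to-bead loading variation);
  defocused beads (default 5%) get a Gaussian edge of 3 µm and are
  caught by the diameter gate; artifacts are soft-edged ellipses with
  axis ratio ≥ 2, caught by the circularity gate.
* **Placement** is random-sequential with a minimum separation of one
  effective footprint (beads settle as a monolayer; elongated and
  blurred objects use their rendered extent), so default images contain
  separated objects while a touching-bead mode remains available via
  `minSeparationFactor`.
* **Optics and noise**: a smooth multiplicative second-degree
  illumination field (default ±10%), additive Gaussian read noise
  (default SD 5 AU on a 200 AU background — camera read noise dominates
  at these exposures; Poisson noise is available), and 16-bit integer
  quantization.
* **Statistical structure**: every D/DA pair owns a true efficiency =
  baseline (default 30%) + compound shift + pair-level variability
  (default SD 0.4%); D wells render at donor scale $s$, DA wells at
  $s(1 - E/100)$. A configurable fraction of compounds carries donor
  artifacts (multipliers in 0.70–0.88 or 1.12–1.30) or background
  artifacts (1.25–2×), defaults 5% each, so that roughly a tenth of
  compounds is QC-censored. `spikeHits()` plants true effects.
* **Seeding**: one master seed; each pair owns a population substream
  (so matched D/DA wells carry the same dispense — with noise switched
  off, a zero-efficiency pair renders identical bead signal) and each
  well a brightness/noise substream, making any single well reproducible
  in isolation.

Default scale parameters mirror the screening conditions: 600 beads
dispensed per 1,536-format well, one image covering 19% of the well
(~114 beads/image), 0.325 µm pixels, a 660 µm field consistent with 19%
of a 1,536 well. The tests run the same generator at smaller problem
sizes — wells of 15–60 beads in 220–460 µm fields, chosen so each suite
completes on a laptop while keeping ≥400 gated beads wherever a
criterion is about statistical recovery; these sizes are stated in the
tests themselves.

What passing closure tests does and does not show: the generator shares
the analysis' idealizations (disk-like beads, smooth field, additive
noise). Recovery of truth within 0.5% (noise-free) or 2% (full noise)
demonstrates the pipeline's internal consistency and the correctness of
its estimators under the stated model — not robustness to bead
clumping, spectral bleed-through, focus drift or vendor-specific
flat-field behaviour, none of which the generator emulates.

# Numerical and degenerate-input conventions

Images are 0-based, row-major; physical positions are in µm from the
top-left pixel centre. Sample SDs everywhere. A well with no passed
beads reports `NA` intensity and is flagged by `n_beads = 0`; a pair
with a non-positive donor mean yields `NA` efficiency; a plate whose
DMSO SD is zero refuses to call hits (degenerate plate). Well images are
written as uncompressed 16-bit TIFFs after clamping to [0, 65535] and
rounding, which makes write/read round trips bit-exact and simulated
plates byte-reproducible under a fixed seed. The Avogadro constant is
fixed at 6.02214 × 10²³.

# Known limitations

* The donor QC gate is applied per well (stricter than gating the
  duplicate mean); plates with drifting donor intensity will censor
  more compounds.
* The flat-field model is a global second-degree polynomial; vignetting
  with higher-order structure would leave a residual, though the FRET
  ratio is first-order insensitive to it.
* `effectiveBoundConcentration()` depends on the stated volume
  convention (molecules in the bead's own sphere).
* The generator does not model binding kinetics, acceptor photophysics
  or multi-plane focus selection; it emulates the endpoint images only.
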