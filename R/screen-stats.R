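#' Per-plate DMSO baseline
#'
#' Mean and sample SD (n-1 denominator) of the vehicle-control pair
#' E_FRET values of one plate, plus the mean donor bead intensity and
#' mean background of the control donor wells, which anchor the compound
#' QC gates.
#'
#' @param pairTable output of [pairFret()] (rows with role "dmso" are
#'   used), or a numeric vector of control E values when `wellTable` is
#'   omitted.
#' @param wellTable per-well table (for the donor/background anchors).
#' @param plateId plate identifier.
#' @return a [DmsoBaseline-class].
#' @export
dmsoBaseline <- function(pairTable, wellTable = NULL, plateId = "plate1") {
  if (is.numeric(pairTable)) {
    e <- pairTable[!is.na(pairTable)]
    donorMean <- bgMean <- NA_real_
  } else {
    ctrl <- pairTable[pairTable$role == "dmso" & !is.na(pairTable$efret), ,
                      drop = FALSE]
    e <- ctrl$efret
    plateId <- if (nrow(ctrl)) ctrl$plate_id[1] else plateId
    if (!is.null(wellTable)) {
      di <- match(ctrl$d_well, wellTable$well)
      donorMean <- mean(wellTable$mean_intensity[di], na.rm = TRUE)
      bgMean <- mean(wellTable$background[di], na.rm = TRUE)
    } else donorMean <- bgMean <- NA_real_
  }
  if (length(e) < 2L)
    stop("at least 2 control pair E_FRET values are required")
  new("DmsoBaseline", plateId = plateId, mean = mean(e),
      sd = stats::sd(e), n = length(e), donorMean = donorMean,
      backgroundMean = bgMean)
}

setMethod("show", "DmsoBaseline", function(object) {
  cat("DmsoBaseline '", object@plateId, "': E_FRET ",
      round(object@mean, 2), " +/- ", round(object@sd, 2), " % (n = ",
      object@n, ")\n", sep = "")
  if (!is.na(object@donorMean))
    cat("  donor ", round(object@donorMean, 1), " AU/um2, background ",
        round(object@backgroundMean, 1), " AU\n", sep = "")
})

#' Compound quality-control gates
#'
#' A compound passes the donor gate iff the mean bead intensity of every
#' one of its donor wells lies strictly within
#' `donorRange` x the DMSO donor mean (default 0.9-1.1, i.e. a >= 10%
#' donor quench or enhancement fails). It passes the background gate iff
#' the background of every one of its four wells is below
#' `backgroundFold` x the DMSO background mean (default 1.2).
#'
#' @param quartet one row of [compoundQuartets()] (wells d1, da1, d2,
#'   da2).
#' @param wellTable per-well table.
#' @param baseline a [DmsoBaseline-class].
#' @param donorRange numeric length-2 multiplier window for donor wells.
#' @param backgroundFold background multiplier limit.
#' @return named logical vector `c(qc_donor, qc_background)`.
#' @export
qcGate <- function(quartet, wellTable, baseline,
                   donorRange = c(0.9, 1.1), backgroundFold = 1.2) {
  wells <- c(quartet$d1, quartet$da1, quartet$d2, quartet$da2)
  i <- match(wells, wellTable$well)
  if (any(is.na(i)))
    stop("compound ", quartet$compound_id, " references wells missing ",
         "from the well table: ",
         paste(wells[is.na(i)], collapse = ", "))
  dInt <- wellTable$mean_intensity[i[c(1, 3)]]
  ratios <- dInt / baseline@donorMean
  qcDonor <- all(!is.na(ratios)) &&
    all(ratios > donorRange[1] & ratios < donorRange[2])
  bgR <- wellTable$background[i] / baseline@backgroundMean
  qcBg <- all(!is.na(bgR)) && all(bgR < backgroundFold)
  c(qc_donor = qcDonor, qc_background = qcBg)
}

#' Call hits against the DMSO baseline
#'
#' A compound is a hit iff (1) both QC gates pass, (2) the averaged
#' (N = 2) E_FRET deviates from the plate's DMSO mean by more than
#' `kAvg` x SD, and (3) both single-pair values deviate by more than
#' `kSingle` x SD on the same side. Averaged values outside the 3 SD band
#' whose singles disagree (either inside 1.75 SD or on opposite sides)
#' are rejected as irreproducible.
#'
#' @param compounds data.frame with columns `compound_id`, `efret_1`,
#'   `efret_2`, `efret_avg`, `qc_donor`, `qc_background`.
#' @param baseline a [DmsoBaseline-class] with non-zero SD.
#' @param kAvg SD multiplier for the averaged value (default 3).
#' @param kSingle SD multiplier for each single value (default 1.75).
#' @return the input with columns `z_score`, `hit`, `direction`
#'   ("increase", "decrease" or "none") added/overwritten.
#' @export
callHits <- function(compounds, baseline, kAvg = 3, kSingle = 1.75) {
  if (is.na(baseline@sd) || baseline@sd <= 0)
    stop("degenerate plate: the DMSO baseline SD is zero")
  m <- baseline@mean; s <- baseline@sd
  z <- (compounds$efret_avg - m) / s
  d1 <- compounds$efret_1 - m
  d2 <- compounds$efret_2 - m
  qc <- compounds$qc_donor & compounds$qc_background
  singlesUp <- d1 > kSingle * s & d2 > kSingle * s
  singlesDown <- d1 < -kSingle * s & d2 < -kSingle * s
  hit <- !is.na(z) & qc &
    ((z > kAvg & singlesUp) | (z < -kAvg & singlesDown))
  hit[is.na(hit)] <- FALSE
  compounds$z_score <- z
  compounds$hit <- hit
  compounds$direction <- ifelse(hit, ifelse(z > 0, "increase", "decrease"),
                                "none")
  compounds
}

#' Build the per-compound result table for one plate
#'
#' Collects the two pair efficiencies per compound, evaluates the QC
#' gates, and calls hits against the DMSO baseline.
#'
#' @param pairTable output of [pairFret()].
#' @param wellTable per-well table.
#' @param layout the [PlateLayout-class].
#' @param baseline a [DmsoBaseline-class]; computed from `pairTable` when
#'   NULL.
#' @param donorRange,backgroundFold QC gate parameters (see [qcGate()]).
#' @param kAvg,kSingle hit-rule SD multipliers (see [callHits()]).
#' @return per-compound table in the [resultTables] schema.
#' @export
compoundResults <- function(pairTable, wellTable, layout, baseline = NULL,
                            donorRange = c(0.9, 1.1), backgroundFold = 1.2,
                            kAvg = 3, kSingle = 1.75) {
  if (is.null(baseline))
    baseline <- dmsoBaseline(pairTable, wellTable)
  quartets <- compoundQuartets(layout)
  cp <- pairTable[pairTable$role == "compound", , drop = FALSE]
  rows <- lapply(seq_len(nrow(quartets)), function(i) {
    q <- quartets[i, ]
    pe <- cp[!is.na(cp$compound_id) & cp$compound_id == q$compound_id, ]
    pe <- pe[order(pe$pair_id), ]
    e1 <- if (nrow(pe) >= 1) pe$efret[1] else NA_real_
    e2 <- if (nrow(pe) >= 2) pe$efret[2] else NA_real_
    qc <- qcGate(q, wellTable, baseline, donorRange, backgroundFold)
    data.frame(plate_id = baseline@plateId, compound_id = q$compound_id,
               efret_1 = e1, efret_2 = e2,
               efret_avg = averageAdjacentPairs(e1, e2),
               qc_donor = unname(qc["qc_donor"]),
               qc_background = unname(qc["qc_background"]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- callHits(out, baseline, kAvg = kAvg, kSingle = kSingle)
  out <- out[, COMPOUND_COLS]
  rownames(out) <- NULL
  out
}

#' Z-prime assay window statistic
#'
#' Z' = 1 - 3 (SD_P + SD_N) / |Mean_P - Mean_N|. Z' > 0.5 indicates a
#' screenable assay window. Invariant under any affine transform (with
#' positive scale) of the control values.
#'
#' @param meanP,sdP mean and SD of the positive control (percent E_FRET).
#' @param meanN,sdN mean and SD of the negative control.
#' @return Z' (dimensionless).
#' @examples
#' zPrime(61.6, 0.6, 51.7, 0.7)  # 0.606
#' @export
zPrime <- function(meanP, sdP, meanN, sdN) {
  if (meanP == meanN) stop("Z' is undefined for equal control means")
  1 - 3 * (sdP + sdN) / abs(meanP - meanN)
}

#' Minimum control separation for a target Z'
#'
#' Solves the Z' equation for the control separation:
#' |Mean_P - Mean_N| = 3 (SD_P + SD_N) / (1 - Z'). With control SDs of
#' 0.7 and 0.6 percent the separation needed for Z' > 0.5 is 7.8, i.e. an
#' 8% FRET difference after rounding up to the next whole percent.
#'
#' @param sdP,sdN control standard deviations (percent E_FRET).
#' @param zprime target Z' (default 0.5).
#' @return minimum |Mean_P - Mean_N| in percent E_FRET.
#' @export
minControlSeparation <- function(sdP, sdN, zprime = 0.5) {
  if (zprime >= 1) stop("Z' must be below 1")
  3 * (sdP + sdN) / (1 - zprime)
}

#' Plate coefficient of variation
#'
#' 100 x sample SD / mean of a plate's E_FRET values.
#'
#' @param e numeric vector of E_FRET values (percent), n >= 2.
#' @return CV in percent.
#' @export
plateCV <- function(e) {
  e <- e[!is.na(e)]
  if (length(e) < 2L) stop("CV needs at least 2 values")
  m <- mean(e)
  if (m == 0) stop("CV is undefined for zero mean")
  100 * stats::sd(e) / m
}

#' Signal-to-background ratio
#'
#' Mean donor-well bead intensity divided by mean background. Scale
#' invariant: multiplying all intensities by a constant leaves it
#' unchanged.
#'
#' @param dSignal mean donor bead intensities (scalar or vector).
#' @param background backgrounds (scalar or vector), mean must be > 0.
#' @return dimensionless ratio.
#' @export
signalToBackground <- function(dSignal, background) {
  b <- mean(background, na.rm = TRUE)
  if (!is.finite(b) || b <= 0)
    stop("signal-to-background is undefined for non-positive background")
  mean(dSignal, na.rm = TRUE) / b
}
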