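#' Run a complete simulated screen on one plate
#'
#' End-to-end orchestration of the pipeline: simulate ground truth,
#' render each well image, flat-field correct and segment it, quantify
#' per-area bead intensities, pair D and D+A wells into FRET
#' efficiencies, compute the DMSO baseline, apply the compound QC gates,
#' and call hits. Wells are rendered and analyzed one at a time so a full
#' 1,536-well plate never holds all images in memory. Fully reproducible
#' given the configuration seed.
#'
#' @param layout a [PlateLayout-class].
#' @param config a [SimulationConfig-class].
#' @param params a [SegmentationParams-class].
#' @param spikes optional named numeric vector `compound_id -> deltaE`
#'   planting true hits.
#' @param donorRange,backgroundFold QC gates (see [qcGate()]).
#' @param kAvg,kSingle hit-rule SD multipliers (see [callHits()]).
#' @param outDir optional directory: result tables (and images when
#'   `writeImages`) are written there.
#' @param writeImages write each rendered well as a 16-bit TIFF.
#' @param flatField apply per-image flat-field correction (default TRUE).
#' @param verbose print per-well progress.
#' @return a list of class `screenReport`: `truth`, `beads`, `wells`,
#'   `pairs`, `baseline`, `compounds`, `summary` (see [reportSummary()]),
#'   and `hits` (the hit rows of `compounds`).
#' @examples
#' \dontrun{
#' lay <- makeScreenLayout(96, nCompounds = 4, nDmsoPairs = 8)
#' cfg <- simulationConfig(seed = 1, beadsPerWell = 40, imagedFraction = 1,
#'                         fieldWidthUm = 250)
#' rep <- runScreen(lay, cfg, spikes = c(c001 = 6))
#' rep$hits
#' }
#' @export
runScreen <- function(layout, config, params = segmentationParams(),
                      spikes = NULL, donorRange = c(0.9, 1.1),
                      backgroundFold = 1.2, kAvg = 3, kSingle = 1.75,
                      outDir = NULL, writeImages = FALSE,
                      flatField = TRUE, verbose = FALSE) {
  truth <- simulateTruth(layout, config)
  if (!is.null(spikes))
    truth <- spikeHits(truth, names(spikes), unname(spikes))
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  imgDir <- if (isTRUE(writeImages) && !is.null(outDir))
    file.path(outDir, "images") else NULL
  if (!is.null(imgDir) && !dir.exists(imgDir))
    dir.create(imgDir)

  wellNames <- truth@wells$well
  beadRows <- wellRows <- vector("list", length(wellNames))
  for (i in seq_along(wellNames)) {
    wn <- wellNames[i]
    img <- renderWellImage(truth, wn, config)
    if (!is.null(imgDir)) writeWellImage(img, imgDir, layout@plateId)
    field <- if (flatField) estimateField(img) else NULL
    res <- analyzeWellImage(img, params, field = field,
                            plateId = layout@plateId)
    beadRows[[i]] <- res$beads
    wellRows[[i]] <- res$well
    if (verbose)
      message(sprintf("well %s: %d beads (%d passed)", wn,
                      nrow(res$beads), res$well$n_beads))
  }
  beads <- do.call(rbind, beadRows)
  wells <- do.call(rbind, wellRows)
  rownames(beads) <- rownames(wells) <- NULL
  pairs <- pairFret(wells, layout)
  baseline <- dmsoBaseline(pairs, wells, plateId = layout@plateId)
  compounds <- compoundResults(pairs, wells, layout, baseline,
                               donorRange = donorRange,
                               backgroundFold = backgroundFold,
                               kAvg = kAvg, kSingle = kSingle)
  report <- list(truth = truth, beads = beads, wells = wells,
                 pairs = pairs, baseline = baseline,
                 compounds = compounds,
                 hits = compounds[compounds$hit, , drop = FALSE])
  report$summary <- reportSummary(list(report))
  class(report) <- "screenReport"
  if (!is.null(outDir)) {
    writeResultsTables(beads, wells, compounds, outDir)
    utils::write.csv(pairs, file.path(outDir, "pairs.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(report$summary, file.path(outDir, "summary.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  report
}

#' Summarize one or more analyzed plates
#'
#' One row per plate (DMSO mean/SD, plate CV, signal-to-background,
#' number of QC failures, hits up/down) plus a `TOTAL` row giving the
#' overall compound count and the hit ratio as a percentage.
#'
#' @param reports a `screenReport`, a list of them, or a list of lists
#'   with elements `compounds`, `baseline`, `pairs`, `wells` (the last
#'   two optional).
#' @return data.frame with columns `plate_id`, `dmso_mean`, `dmso_sd`,
#'   `cv_pct`, `s_over_b`, `n_compounds`, `n_qc_failed`, `n_hits_up`,
#'   `n_hits_down`, `hit_ratio_pct`.
#' @export
reportSummary <- function(reports) {
  if (inherits(reports, "screenReport") ||
      (!is.null(names(reports)) && "compounds" %in% names(reports)))
    reports <- list(reports)
  if (!length(reports)) stop("at least one analyzed plate is required")
  rows <- lapply(reports, function(r) {
    cmp <- r$compounds
    bl <- r$baseline
    cv <- if (!is.null(r$pairs)) {
      e <- r$pairs$efret[!is.na(r$pairs$efret)]
      if (length(e) >= 2) plateCV(e) else NA_real_
    } else NA_real_
    sb <- if (!is.null(r$wells) && !is.null(bl) &&
              is.finite(bl@backgroundMean)) {
      dwells <- if (!is.null(r$pairs)) r$pairs$d_well else character()
      dsel <- r$wells$well %in% dwells
      signalToBackground(r$wells$mean_intensity[dsel],
                         r$wells$background[dsel])
    } else NA_real_
    data.frame(
      plate_id = if (!is.null(bl)) bl@plateId else cmp$plate_id[1],
      dmso_mean = if (!is.null(bl)) bl@mean else NA_real_,
      dmso_sd = if (!is.null(bl)) bl@sd else NA_real_,
      cv_pct = cv, s_over_b = sb,
      n_compounds = nrow(cmp),
      n_qc_failed = sum(!(cmp$qc_donor & cmp$qc_background)),
      n_hits_up = sum(cmp$hit & cmp$direction == "increase"),
      n_hits_down = sum(cmp$hit & cmp$direction == "decrease"),
      hit_ratio_pct = if (nrow(cmp))
        100 * sum(cmp$hit) / nrow(cmp) else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  nC <- sum(out$n_compounds)
  total <- data.frame(
    plate_id = "TOTAL", dmso_mean = NA_real_, dmso_sd = NA_real_,
    cv_pct = NA_real_, s_over_b = NA_real_, n_compounds = nC,
    n_qc_failed = sum(out$n_qc_failed),
    n_hits_up = sum(out$n_hits_up), n_hits_down = sum(out$n_hits_down),
    hit_ratio_pct = if (nC > 0)
      100 * (sum(out$n_hits_up) + sum(out$n_hits_down)) / nC else
        NA_real_,
    stringsAsFactors = FALSE)
  rbind(out, total)
}

#' @export
print.screenReport <- function(x, ...) {
  cat("screenReport for plate '", x$baseline@plateId, "'\n", sep = "")
  cat("  wells analyzed: ", nrow(x$wells), "; beads: ", nrow(x$beads),
      " (", sum(x$beads$passed), " passed)\n", sep = "")
  show(x$baseline)
  cat("  compounds: ", nrow(x$compounds), "; QC failed: ",
      sum(!(x$compounds$qc_donor & x$compounds$qc_background)),
      "; hits: ", sum(x$compounds$hit), "\n", sep = "")
  invisible(x)
}
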