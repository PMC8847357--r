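BEAD_COLS <- c("plate_id", "well", "bead_id", "x_um", "y_um",
               "diameter_um", "circularity", "intensity_per_um2",
               "passed", "reject_reason")
WELL_COLS <- c("plate_id", "well", "n_beads", "mean_intensity",
               "sd_intensity", "background")
COMPOUND_COLS <- c("plate_id", "compound_id", "efret_1", "efret_2",
                   "efret_avg", "z_score", "qc_donor", "qc_background",
                   "hit", "direction")

checkSchema <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " table is missing columns: ", paste(miss, collapse = ", "))
  df[, cols, drop = FALSE]
}

#' Read and write pipeline result tables
#'
#' Fixed-schema CSV tables: per-bead
#' (`plate_id,well,bead_id,x_um,y_um,diameter_um,circularity,`
#' `intensity_per_um2,passed,reject_reason`), per-well
#' (`plate_id,well,n_beads,mean_intensity,sd_intensity,background`) and
#' per-compound (`plate_id,compound_id,efret_1,efret_2,efret_avg,`
#' `z_score,qc_donor,qc_background,hit,direction`). Writing then reading
#' restores equal records.
#'
#' @param file CSV path.
#' @param df a table in the corresponding schema.
#' @return readers return a data.frame; writers return `file` invisibly.
#' @name resultTables
NULL

#' @rdname resultTables
#' @export
readBeadTable <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE,
                        colClasses = c(reject_reason = "character"))
  df <- checkSchema(df, BEAD_COLS, "per-bead")
  df$passed <- as.logical(df$passed)
  df
}

#' @rdname resultTables
#' @export
writeBeadTable <- function(df, file) {
  utils::write.csv(checkSchema(df, BEAD_COLS, "per-bead"), file,
                   row.names = FALSE, quote = FALSE, na = "NA")
  invisible(file)
}

#' @rdname resultTables
#' @export
readWellTable <- function(file) {
  checkSchema(utils::read.csv(file, stringsAsFactors = FALSE),
              WELL_COLS, "per-well")
}

#' @rdname resultTables
#' @export
writeWellTable <- function(df, file) {
  utils::write.csv(checkSchema(df, WELL_COLS, "per-well"), file,
                   row.names = FALSE, quote = FALSE, na = "NA")
  invisible(file)
}

#' @rdname resultTables
#' @export
readCompoundTable <- function(file) {
  df <- checkSchema(utils::read.csv(file, stringsAsFactors = FALSE),
                    COMPOUND_COLS, "per-compound")
  df$qc_donor <- as.logical(df$qc_donor)
  df$qc_background <- as.logical(df$qc_background)
  df$hit <- as.logical(df$hit)
  df
}

#' @rdname resultTables
#' @export
writeCompoundTable <- function(df, file) {
  utils::write.csv(checkSchema(df, COMPOUND_COLS, "per-compound"), file,
                   row.names = FALSE, quote = FALSE, na = "NA")
  invisible(file)
}

#' Write the three result tables of one analyzed plate
#'
#' @param beads,wells,compounds tables in the schemas of [resultTables].
#' @param dir output directory (created if missing).
#' @return character vector of the three file paths, invisibly.
#' @export
writeResultsTables <- function(beads, wells, compounds, dir) {
  unknown <- setdiff(unique(beads$well), unique(wells$well))
  if (length(unknown))
    stop("beads reference unknown wells: ", paste(unknown, collapse = ", "))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("beads.csv", "wells.csv", "compounds.csv"))
  writeBeadTable(beads, paths[1])
  writeWellTable(wells, paths[2])
  writeCompoundTable(compounds, paths[3])
  invisible(paths)
}

#' Read and write single-well 16-bit TIFF images
#'
#' One single-channel grayscale file per well, named
#' `<plate_id>_<well>.tif`. Intensities are stored as 16-bit integers;
#' values are clamped to \[0, 65535\] and rounded on write, so a
#' write/read round trip is bit-exact for integer-valued images.
#'
#' @param image a [WellImage-class].
#' @param path TIFF file path (for `writeWellImage`, either a file path or
#'   a directory, in which case the standard name is used).
#' @param plateId plate identifier used to build the file name.
#' @return `readWellImage` returns a [WellImage-class]; `writeWellImage`
#'   the file path, invisibly.
#' @export
writeWellImage <- function(image, path, plateId = "plate1") {
  stopifnot(is(image, "WellImage"))
  if (dir.exists(path))
    path <- file.path(path, sprintf("%s_%s.tif", plateId, image@wellName))
  px <- pmin(pmax(round(image@pixels), 0), 65535)
  tiff::writeTIFF(px / 65535, path, bits.per.sample = 16,
                  compression = "none")
  invisible(path)
}

#' @rdname writeWellImage
#' @param pixelSize µm per pixel of the stored image.
#' @param wellName well name; by default recovered from the file name.
#' @param channel channel label.
#' @export
readWellImage <- function(path, pixelSize = 0.325, wellName = NULL,
                          channel = "donor") {
  if (!file.exists(path)) stop("no such image file: ", path)
  px <- round(tiff::readTIFF(path) * 65535)
  if (is.null(wellName)) {
    wellName <- sub("\\.tiff?$", "", basename(path))
    wellName <- sub("^.*_", "", wellName)
  }
  new("WellImage", pixels = px, pixelSize = pixelSize,
      wellName = wellName, channel = channel)
}

#' @rdname WellImage-class
#' @export
setMethod("intensityMatrix", "WellImage", function(object) object@pixels)

#' @rdname WellImage-class
#' @export
setMethod("pixelSize", "WellImage", function(object) object@pixelSize)

#' @rdname WellImage-class
#' @export
setMethod("wellName", "WellImage", function(object) object@wellName)

setMethod("show", "WellImage", function(object) {
  cat("WellImage '", object@wellName, "' (", object@channel, "): ",
      nrow(object@pixels), " x ", ncol(object@pixels), " px at ",
      object@pixelSize, " um/px; range [",
      round(min(object@pixels), 1), ", ", round(max(object@pixels), 1),
      "] AU\n", sep = "")
})

#' Construct a WellImage
#'
#' @param pixels numeric matrix of non-negative intensities.
#' @param pixelSize µm per pixel edge (default 0.325).
#' @param wellName well name.
#' @param channel channel label.
#' @return a [WellImage-class].
#' @export
WellImage <- function(pixels, pixelSize = 0.325, wellName = "A01",
                      channel = "donor") {
  new("WellImage", pixels = pixels, pixelSize = pixelSize,
      wellName = wellName, channel = channel)
}
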