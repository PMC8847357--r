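formatDims <- function(format) {
  switch(as.character(format),
         "96"   = c(8L, 12L),
         "384"  = c(16L, 24L),
         "1536" = c(32L, 48L),
         stop("unsupported plate format: ", format))
}

rowLetters <- function(format) {
  n <- formatDims(format)[1]
  c(LETTERS, paste0("A", LETTERS))[seq_len(n)]
}

#' All well names of a plate format, row-major
#'
#' @param format 96, 384 or 1536.
#' @return character vector, e.g. `"A01" ... "AF48"` for 1,536.
#' @export
allWellNames <- function(format) {
  d <- formatDims(format)
  rows <- rowLetters(format)
  as.vector(t(outer(rows, seq_len(d[2]),
                    function(r, c) sprintf("%s%02d", r, c))))
}

#' Convert well names to 0-based row/column indices and back
#'
#' Well names use the plate's row letters (A-H, A-P, or A-AF) followed by
#' a 1-based column number; indices are 0-based, row-major. The two
#' functions are mutually inverse over every well of every format.
#'
#' @param name character vector of well names (e.g. "A01", "AF48").
#' @param format 96, 384 or 1536.
#' @return `wellNameToIndex`: integer matrix with columns `row`, `col`
#'   (0-based); `indexToWellName`: character vector.
#' @examples
#' wellNameToIndex("A01", 96)    # 0, 0
#' wellNameToIndex("AF48", 1536) # 31, 47
#' indexToWellName(31, 47, 1536) # "AF48"
#' @export
wellNameToIndex <- function(name, format) {
  d <- formatDims(format)
  m <- regmatches(name, regexec("^([A-Z]{1,2})([0-9]{1,2})$", name))
  bad <- vapply(m, length, integer(1)) != 3L
  rows <- cols <- rep(NA_integer_, length(name))
  if (any(!bad)) {
    rows[!bad] <- match(vapply(m[!bad], `[`, "", 2L), rowLetters(format)) - 1L
    cols[!bad] <- as.integer(vapply(m[!bad], `[`, "", 3L)) - 1L
  }
  bad <- bad | is.na(rows) | is.na(cols) | cols < 0L | cols >= d[2]
  if (any(bad))
    stop("invalid well name(s) for ", format, "-well format: ",
         paste(unique(name[bad]), collapse = ", "))
  cbind(row = rows, col = cols)
}

#' @rdname wellNameToIndex
#' @param row,col 0-based indices.
#' @export
indexToWellName <- function(row, col, format) {
  d <- formatDims(format)
  if (any(row < 0L | row >= d[1] | col < 0L | col >= d[2]))
    stop("row/column index out of range for ", format, "-well format")
  sprintf("%s%02d", rowLetters(format)[row + 1L], col + 1L)
}

emptyWellsTable <- function(format) {
  data.frame(well = allWellNames(format), role = "EMPTY",
             compound_id = NA_character_, dose_uM = NA_real_,
             pair_id = NA_character_, stringsAsFactors = FALSE)
}

#' Construct a PlateLayout from a wells table
#'
#' @param wells data.frame with columns `well`, `role`, `compound_id`,
#'   `dose_uM`, `pair_id`; one row per non-empty well. Unlisted wells
#'   become `EMPTY`.
#' @param format 96, 384 or 1536.
#' @param plateId plate identifier.
#' @return a validated [PlateLayout-class] object.
#' @export
PlateLayout <- function(wells, format, plateId = "plate1") {
  format <- as.integer(format)
  full <- emptyWellsTable(format)
  if (nrow(wells)) {
    dup <- wells$well[duplicated(wells$well)]
    if (length(dup))
      stop("duplicate well rows: ", paste(unique(dup), collapse = ", "))
    wellNameToIndex(wells$well, format)  # validates names
    i <- match(wells$well, full$well)
    for (cc in c("role", "compound_id", "dose_uM", "pair_id"))
      if (cc %in% names(wells)) full[[cc]][i] <- wells[[cc]]
  }
  new("PlateLayout", plateId = plateId, format = format, wells = full)
}

#' Read a plate map CSV into a PlateLayout
#'
#' The plate map dialect is a CSV with columns
#' `well,role,compound_id,dose_uM,pair_id` and one row per non-empty well.
#'
#' @param file path to a CSV file, or a data.frame in the same schema.
#' @param format 96, 384 or 1536.
#' @param plateId plate identifier.
#' @return a validated [PlateLayout-class].
#' @seealso [writePlateMap()]
#' @export
parsePlateMap <- function(file, format, plateId = "plate1") {
  if (!is.data.frame(file) && !file.exists(file))
    stop("no such plate map file: ", file)
  df <- if (is.data.frame(file)) file else
    utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("well", "role", "compound_id", "dose_uM", "pair_id")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("plate map is missing columns: ", paste(miss, collapse = ", "))
  df$compound_id <- as.character(df$compound_id)
  df$pair_id <- as.character(df$pair_id)
  df$compound_id[df$compound_id %in% c("", "NA")] <- NA_character_
  df$pair_id[df$pair_id %in% c("", "NA")] <- NA_character_
  df$dose_uM <- as.numeric(df$dose_uM)
  PlateLayout(df[, need], format = format, plateId = plateId)
}

#' Write a PlateLayout to a plate map CSV
#'
#' Only non-EMPTY wells are written; [parsePlateMap()] restores the
#' identical layout.
#'
#' @param layout a [PlateLayout-class].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writePlateMap <- function(layout, file) {
  w <- layout@wells
  utils::write.csv(w[w$role != "EMPTY", , drop = FALSE], file,
                   row.names = FALSE, quote = FALSE, na = "")
  invisible(file)
}

#' Generate a default screening layout
#'
#' Builds the paired duplicate design used for screening: each compound
#' occupies four adjacent wells in one row (D, DA, D, DA = two pairs),
#' compounds fill the left-hand column block, one column pair of
#' DMSO-control D/DA wells follows, and remaining wells are BUFFER. The
#' 1,536-well default is 320 compounds (columns 1-40) plus 32 DMSO pairs
#' (columns 41-42).
#'
#' @param format 96, 384 or 1536.
#' @param nCompounds number of compounds (default fills the format's
#'   compound block: 16, 80 or 320).
#' @param nDmsoPairs number of DMSO control pairs (default 16, 16 or 32).
#' @param plateId plate identifier.
#' @param compoundIds optional character vector of compound names.
#' @return a [PlateLayout-class].
#' @examples
#' lay <- makeScreenLayout(1536)
#' nrow(compoundQuartets(lay))  # 320
#' nrow(dmsoPairs(lay))         # 32
#' @export
makeScreenLayout <- function(format = 1536,
                             nCompounds = NULL,
                             nDmsoPairs = NULL,
                             plateId = "plate1",
                             compoundIds = NULL) {
  format <- as.integer(format)
  d <- formatDims(format)
  defC <- c("96" = 16L, "384" = 80L, "1536" = 320L)[[as.character(format)]]
  defP <- c("96" = 16L, "384" = 16L, "1536" = 32L)[[as.character(format)]]
  if (is.null(nCompounds)) nCompounds <- defC
  if (is.null(nDmsoPairs)) nDmsoPairs <- defP
  # compounds fill a left-hand block of whole columns, 4 wells each
  perRow <- as.integer(ceiling(nCompounds / d[1]))
  if (perRow * 4L + 2L > d[2])
    stop("too many compounds for format ", format)
  if (is.null(compoundIds))
    compoundIds <- sprintf("c%03d", seq_len(nCompounds))
  stopifnot(length(compoundIds) == nCompounds)
  rows <- rowLetters(format)
  recs <- vector("list", nCompounds + nDmsoPairs)
  for (k in seq_len(nCompounds)) {
    r <- (k - 1L) %/% perRow
    c0 <- ((k - 1L) %% perRow) * 4L
    wells <- indexToWellName(rep(r, 4), c0 + 0:3, format)
    recs[[k]] <- data.frame(
      well = wells, role = c("D", "DA", "D", "DA"),
      compound_id = compoundIds[k], dose_uM = NA_real_,
      pair_id = paste0(compoundIds[k], "_p", c(1, 1, 2, 2)),
      stringsAsFactors = FALSE)
  }
  if (nDmsoPairs > d[1]) {
    cPerRow <- ceiling(nDmsoPairs / d[1])
    if (perRow * 4L + 2L * cPerRow > d[2])
      stop("too many DMSO pairs for format ", format)
  }
  dCol <- perRow * 4L
  for (p in seq_len(nDmsoPairs)) {
    r <- (p - 1L) %% d[1]
    cc <- dCol + 2L * ((p - 1L) %/% d[1])
    recs[[nCompounds + p]] <- data.frame(
      well = indexToWellName(c(r, r), c(cc, cc + 1L), format),
      role = c("DMSO_D", "DMSO_DA"), compound_id = NA_character_,
      dose_uM = NA_real_, pair_id = sprintf("dmso%02d", p),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, recs)
  lay <- PlateLayout(tab, format = format, plateId = plateId)
  w <- lay@wells
  w$role[w$role == "EMPTY"] <- "BUFFER"
  initialize(lay, wells = w)
}

#' @rdname PlateLayout-class
#' @export
setMethod("plateId", "PlateLayout", function(object) object@plateId)

#' @rdname PlateLayout-class
#' @export
setMethod("plateFormat", "PlateLayout", function(object) object@format)

#' @rdname PlateLayout-class
#' @export
setMethod("layoutWells", "PlateLayout", function(object) object@wells)

#' @rdname PlateLayout-class
#' @export
setMethod("compoundQuartets", "PlateLayout", function(object) {
  w <- object@wells
  cw <- w[w$role %in% c("D", "DA") & !is.na(w$compound_id), , drop = FALSE]
  if (!nrow(cw))
    return(data.frame(compound_id = character(), d1 = character(),
                      da1 = character(), d2 = character(),
                      da2 = character(), stringsAsFactors = FALSE))
  res <- lapply(split(cw, cw$compound_id), function(d) {
    pid <- sort(unique(d$pair_id))
    data.frame(compound_id = d$compound_id[1],
               d1  = d$well[d$pair_id == pid[1] & d$role == "D"],
               da1 = d$well[d$pair_id == pid[1] & d$role == "DA"],
               d2  = d$well[d$pair_id == pid[2] & d$role == "D"],
               da2 = d$well[d$pair_id == pid[2] & d$role == "DA"],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
})

#' @rdname PlateLayout-class
#' @export
setMethod("dmsoPairs", "PlateLayout", function(object) {
  w <- object@wells
  dm <- w[w$role %in% c("DMSO_D", "DMSO_DA"), , drop = FALSE]
  if (!nrow(dm))
    return(data.frame(pair_id = character(), d_well = character(),
                      da_well = character(), stringsAsFactors = FALSE))
  res <- lapply(split(dm, dm$pair_id), function(d)
    data.frame(pair_id = d$pair_id[1],
               d_well = d$well[d$role == "DMSO_D"],
               da_well = d$well[d$role == "DMSO_DA"],
               stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
})

setMethod("show", "PlateLayout", function(object) {
  w <- object@wells
  cat("PlateLayout '", object@plateId, "': ", object@format,
      "-well format\n", sep = "")
  cat("  compounds: ", nrow(compoundQuartets(object)),
      " (duplicate D/DA pairs)\n", sep = "")
  cat("  DMSO control pairs: ", nrow(dmsoPairs(object)), "\n", sep = "")
  tb <- table(factor(w$role, levels = WELL_ROLES))
  cat("  roles:", paste(names(tb)[tb > 0], tb[tb > 0], sep = "=",
                        collapse = ", "), "\n")
})
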