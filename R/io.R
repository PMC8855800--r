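#' Read a label mask from disk
#'
#' Reads a single-frame chamber label raster. Supported formats, chosen by
#' extension: 8-bit grayscale PNG (\code{.png}; pixel value = label code),
#' uncompressed single-frame NIfTI-1 (\code{.nii}), and whitespace-delimited
#' integer text grids (\code{.txt}/\code{.tsv}). TIFF is not supported.
#' Unknown nonzero codes are an error, never silently relabeled.
#'
#' @param path file to read.
#' @param labelMap named integer vector of chamber codes
#'   (default \code{defaultLabelMap()}).
#' @param spacing numeric length-2 (row, col) mm/px, or NULL. For NIfTI, NULL
#'   takes the header pixdim; for PNG/text a spacing must be given (use
#'   \code{spacingFromDicom} when only DICOM metadata carries it).
#' @param frameIndex 0-based frame ordinal to record.
#' @return A \linkS4class{LabelMask}.
#' @seealso [writeMask()], [spacingFromDicom()]
#' @export
readMask <- function(path, labelMap = defaultLabelMap(), spacing = NULL,
                     frameIndex = 0L) {
  if (!file.exists(path)) stop("cannot read mask: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- png::readPNG(path)
    if (length(dim(arr)) == 3L) arr <- arr[, , 1]
    grid <- round(arr * 255)
    if (max(abs(arr * 255 - grid)) > 1e-6)
      stop("PNG does not hold integer label codes: ", path)
    storage.mode(grid) <- "integer"
    if (is.null(spacing)) stop("spacing required for PNG masks: ", path)
  } else if (ext == "nii") {
    ni <- .readNifti2D(path)
    grid <- ni$grid
    if (is.null(spacing)) spacing <- ni$spacing
  } else if (ext %in% c("txt", "tsv")) {
    grid <- as.matrix(read.table(path, header = FALSE))
    dimnames(grid) <- NULL
    if (any(grid != round(grid))) stop("non-integer pixel data in ", path)
    storage.mode(grid) <- "integer"
    if (is.null(spacing)) stop("spacing required for text masks: ", path)
  } else {
    stop("unsupported mask format '.", ext, "' (use .png, .nii, .txt)")
  }
  LabelMask(grid, spacing = spacing, labelMap = labelMap,
            frameIndex = frameIndex)
}

#' Write a label mask to disk
#'
#' Inverse of [readMask()]; format chosen by extension (\code{.png},
#' \code{.nii}, \code{.txt}/\code{.tsv}). PNG requires codes <= 255.
#'
#' @param mask a \linkS4class{LabelMask}.
#' @param path destination file.
#' @return \code{path}, invisibly.
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "LabelMask"))
  ext <- tolower(tools::file_ext(path))
  g <- mask@grid
  if (ext == "png") {
    if (max(g) > 255L) stop("PNG masks support label codes up to 255")
    png::writePNG(g / 255, target = path)
  } else if (ext == "nii") {
    .writeNifti2D(g, mask@spacing, path)
  } else if (ext %in% c("txt", "tsv")) {
    write.table(g, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  } else {
    stop("unsupported mask format '.", ext, "'")
  }
  invisible(path)
}

#' Read an ordered cine series from a directory of mask frames
#'
#' Frames are files matching \code{pattern}, taken in lexicographic filename
#' order and assigned frameIndex 0, 1, ...
#'
#' @param dir directory holding one subject's frame files.
#' @param labelMap,spacing passed to [readMask()].
#' @param pattern filename regular expression (default: png/nii/txt).
#' @param subjectId subject identifier (default: the directory name).
#' @return A \linkS4class{CineSeries}.
#' @export
readCineSeries <- function(dir, labelMap = defaultLabelMap(), spacing = NULL,
                           pattern = "\\.(png|nii|txt|tsv)$",
                           subjectId = basename(dir)) {
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  if (!length(files)) stop("no mask frames found in ", dir)
  fr <- lapply(seq_along(files), function(i)
    readMask(files[i], labelMap = labelMap, spacing = spacing,
             frameIndex = i - 1L))
  CineSeries(fr, subjectId = subjectId)
}

#' Write a measurement table to CSV
#'
#' One row per (subject, frame, measurement name). Millimetre values are
#' written with 9 decimals so that a read-back reproduces them to 1e-9.
#' Columns: subject_id, frame_index, phase, name, r1, c1, r2, c2, length_px,
#' length_mm, flags.
#'
#' @param records data.frame of measurements as produced by [measureFrame()]
#'   or [measureSeries()].
#' @param path destination CSV.
#' @return \code{path}, invisibly.
#' @seealso [readMeasurements()]
#' @export
writeMeasurements <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("records must be a nonempty data.frame of measurements")
  cols <- c("subject_id", "frame_index", "phase", "name",
            "r1", "c1", "r2", "c2", "length_px", "length_mm", "flags")
  for (cn in setdiff(cols, names(records))) records[[cn]] <- NA
  out <- records[, cols]
  out$length_mm <- sprintf("%.9f", out$length_mm)
  out$length_px <- ifelse(is.na(out$length_px), "",
                          sprintf("%.9f", out$length_px))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a measurement table written by [writeMeasurements()]
#'
#' @param path CSV file.
#' @return data.frame with numeric length columns.
#' @export
readMeasurements <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$length_mm <- as.numeric(df$length_mm)
  df$length_px <- suppressWarnings(as.numeric(df$length_px))
  df
}

## --- minimal single-frame NIfTI-1 support -------------------------------
## No NIfTI package is installed; only what 2D label masks need is
## implemented: uncompressed .nii, int16 data, dim = (2, nrow, ncol),
## pixdim[2:3] = (row, col) spacing. Package-local axis convention: the
## first (fastest-varying) NIfTI dimension is the grid row.

.readNifti2D <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348)
  sizeof_hdr <- readBin(hdr[1:4], "integer", 1, size = 4, endian = "little")
  endian <- "little"
  if (sizeof_hdr != 348L) {
    sizeof_hdr <- readBin(hdr[1:4], "integer", 1, size = 4, endian = "big")
    if (sizeof_hdr != 348L) stop("not a NIfTI-1 file: ", path)
    endian <- "big"
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("not a NIfTI-1 file: ", path)
  dims <- readBin(hdr[41:56], "integer", 8, size = 2, endian = endian)
  if (dims[1] < 2L) stop("NIfTI mask must be at least 2-dimensional")
  if (dims[1] > 2L && any(dims[4:(dims[1] + 1)] > 1L))
    stop("only single-frame 2D NIfTI masks are supported")
  nr <- dims[2]; nc <- dims[3]
  datatype <- readBin(hdr[71:72], "integer", 1, size = 2, endian = endian)
  pixdim <- readBin(hdr[77:108], "numeric", 8, size = 4, endian = endian)
  vox_offset <- readBin(hdr[109:112], "numeric", 1, size = 4, endian = endian)
  seek(con, where = vox_offset, origin = "start")
  n <- nr * nc
  vals <- switch(as.character(datatype),
    "2"  = readBin(con, "integer", n, size = 1, signed = FALSE, endian = endian),
    "4"  = readBin(con, "integer", n, size = 2, endian = endian),
    "8"  = readBin(con, "integer", n, size = 4, endian = endian),
    "16" = readBin(con, "numeric", n, size = 4, endian = endian),
    stop("unsupported NIfTI datatype ", datatype))
  if (any(vals != round(vals))) stop("non-integer pixel data in ", path)
  grid <- matrix(as.integer(round(vals)), nrow = nr, ncol = nc)
  list(grid = grid, spacing = c(pixdim[2], pixdim[3]))
}

.writeNifti2D <- function(grid, spacing, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(348L, con, size = 4, endian = "little")          # sizeof_hdr
  writeBin(raw(36), con)                                    # unused
  dims <- c(2L, nrow(grid), ncol(grid), 1L, 1L, 1L, 1L, 1L)
  writeBin(dims, con, size = 2, endian = "little")          # dim
  writeBin(raw(14), con)                                    # intent_*
  writeBin(c(4L, 16L), con, size = 2, endian = "little")    # datatype int16, bitpix
  writeBin(0L, con, size = 2, endian = "little")            # slice_start
  pixdim <- c(1, spacing[1], spacing[2], 1, 1, 1, 1, 1)
  writeBin(pixdim, con, size = 4, endian = "little")        # pixdim
  writeBin(352, con, size = 4, endian = "little")           # vox_offset
  writeBin(c(1, 0), con, size = 4, endian = "little")       # scl_slope, scl_inter
  writeBin(raw(224), con)                                   # zero through intent_name
  writeChar("n+1", con, nchars = 3, eos = NULL)             # magic at 344
  writeBin(raw(1), con)
  writeBin(raw(4), con)                                     # extension flag
  writeBin(as.integer(grid), con, size = 2, endian = "little")
  invisible(path)
}
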