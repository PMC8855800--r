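## Minimal DICOM metadata access. No DICOM package exists in the installed
## stack, and only one attribute is ever needed (PixelSpacing, tag
## 0028,0030), so a small parser for little-endian part-10 files is
## implemented here: explicit VR throughout, with an implicit-VR fallback
## per element. Pixel data are never decoded (masks arrive pre-segmented).

.LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

#' Extract pixel spacing from a DICOM file
#'
#' Reads the PixelSpacing attribute (tag 0028,0030) and returns it in the
#' standard's (row spacing, column spacing) order, in mm/px, exactly as
#' stored — no unit rescaling. This supplies the pixel-to-millimetre
#' conversion factor for all downstream measurements.
#'
#' @param path a little-endian DICOM file.
#' @return numeric length-2: (row_mm_per_px, col_mm_per_px), both > 0.
#' @seealso [writeDicomStub()] for generating synthetic carriers of
#'   PixelSpacing in tests and phantoms.
#' @export
#' @examples
#' f <- tempfile(fileext = ".dcm")
#' writeDicomStub(f, spacing = c(1.5, 1.5))
#' spacingFromDicom(f)
spacingFromDicom <- function(path) {
  val <- .dicomFindElement(path, group = 0x0028L, element = 0x0030L)
  if (is.null(val))
    stop("DICOM file has no PixelSpacing attribute (0028,0030): ", path)
  parts <- strsplit(rawToChar(val), "\\", fixed = TRUE)[[1]]
  sp <- suppressWarnings(as.numeric(trimws(parts)))
  if (length(sp) != 2L || anyNA(sp))
    stop("malformed PixelSpacing value in ", path)
  if (any(sp <= 0)) stop("non-positive PixelSpacing in ", path)
  sp
}

.dicomFindElement <- function(path, group, element) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readBin(path, "raw", file.info(path)$size)
  pos <- 1L
  if (length(raw) >= 132L && rawToChar(raw[129:132]) == "DICM") pos <- 133L
  n <- length(raw)
  u16 <- function(i) readBin(raw[i:(i + 1L)], "integer", 1, size = 2,
                             signed = FALSE, endian = "little")
  u32 <- function(i) readBin(raw[i:(i + 3L)], "integer", 1, size = 4,
                             endian = "little")
  while (pos + 7L <= n) {
    g <- u16(pos); e <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    explicit <- grepl("^[A-Z]{2}$", vr)
    if (explicit && vr %in% .LONG_VRS) {
      len <- u32(pos + 8L); data_at <- pos + 12L
    } else if (explicit) {
      len <- u16(pos + 6L); data_at <- pos + 8L
    } else {
      len <- u32(pos + 4L); data_at <- pos + 8L
    }
    if (len < 0L || data_at + len - 1L > n)
      stop("truncated or unparseable DICOM element in ", path)
    if (g == group && e == element)
      return(if (len > 0L) raw[data_at:(data_at + len - 1L)] else raw(0))
    pos <- data_at + len
  }
  NULL
}

#' Write a minimal synthetic DICOM file carrying PixelSpacing
#'
#' Emits a little-endian explicit-VR part-10 stub with the given PixelSpacing
#' (and optionally Rows/Columns). It carries metadata only — no pixel data —
#' and exists so that the DICOM-derived spacing path can be exercised without
#' any scanner export. The output is synthetic and says so in its
#' SeriesDescription.
#'
#' @param path destination file.
#' @param spacing numeric length-2 (row, col) spacing in mm/px; NULL omits
#'   the attribute (for exercising the missing-tag error path).
#' @param dims optional integer length-2 (Rows, Columns).
#' @return \code{path}, invisibly.
#' @export
writeDicomStub <- function(path, spacing = c(1, 1), dims = NULL) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeChar("DICM", con, nchars = 4, eos = NULL)
  wtag <- function(group, element, vr, value) {
    writeBin(as.integer(c(group, element)), con, size = 2, endian = "little")
    writeChar(vr, con, nchars = 2, eos = NULL)
    if (vr %in% .LONG_VRS) {
      writeBin(raw(2), con)
      writeBin(length(value), con, size = 4, endian = "little")
    } else {
      writeBin(length(value), con, size = 2, endian = "little")
    }
    writeBin(value, con)
  }
  str_val <- function(s) {
    v <- charToRaw(s)
    if (length(v) %% 2L) v <- c(v, charToRaw(" "))
    v
  }
  u16_val <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                  endian = "little")
  # minimal file meta group: transfer syntax = explicit VR little endian
  wtag(0x0002, 0x0010, "UI", str_val("1.2.840.10008.1.2.1"))
  wtag(0x0008, 0x0060, "CS", str_val("MR"))
  wtag(0x0008, 0x103E, "LO", str_val("synthetic metadata stub"))
  if (!is.null(dims)) {
    wtag(0x0028, 0x0010, "US", u16_val(dims[1]))
    wtag(0x0028, 0x0011, "US", u16_val(dims[2]))
  }
  if (!is.null(spacing))
    wtag(0x0028, 0x0030, "DS",
         str_val(paste(format(spacing, trim = TRUE), collapse = "\\")))
  invisible(path)
}
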