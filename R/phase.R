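#' Per-frame chamber area series
#'
#' The per-frame chamber size estimate used for phase selection: labeled
#' pixel count x row_mm x col_mm. Single-slice 4-chamber masks carry no
#' through-plane information, so a 2D area stands in for the chamber volume
#' estimate; this assumption is recorded in every phase selection's metadata.
#'
#' @param series a \linkS4class{CineSeries}.
#' @param chamber chamber name.
#' @return numeric vector, one mm^2 value per frame; NA where the chamber is
#'   absent from a frame.
#' @export
chamberAreaSeries <- function(series, chamber) {
  stopifnot(is(series, "CineSeries"))
  code <- .chamberCode(series@frames[[1]], chamber)
  sp <- pixelSpacing(series)
  areas <- vapply(series@frames, function(f) {
    n <- sum(f@grid == code)
    if (n == 0L) NA_real_ else n * sp[1] * sp[2]
  }, numeric(1))
  if (all(is.na(areas)))
    stop("chamber '", chamber, "' is absent from every frame")
  areas
}

#' Select end-systolic and end-diastolic frames
#'
#' With basis LV: end-diastole is the frame of maximal LV area and
#' end-systole the frame of minimal LV area. If the LV is unusable (absent,
#' or under \code{minPixels} pixels, in more than half the frames) the LA is
#' used with the mapping inverted — the atrium fills while the ventricle
#' empties, so the largest LA marks ventricular end-systole and the smallest
#' LA end-diastole; the basis is recorded. Area ties are broken by the
#' earliest frame and flagged "tie". Frames where the basis chamber is
#' absent are skipped.
#'
#' @param series a \linkS4class{CineSeries} with at least 2 frames.
#' @param minPixels LV pixel count under which a frame counts as degenerate
#'   for the fallback rule (default 10).
#' @return A \linkS4class{PhaseSelection}.
#' @export
selectPhases <- function(series, minPixels = 10L) {
  stopifnot(is(series, "CineSeries"))
  if (nFrames(series) < 2L) stop("phase selection needs at least 2 frames")
  lm0 <- labelMap(series)
  flags <- character()
  usable <- function(chamber) {
    if (!chamber %in% names(lm0)) return(NULL)
    code <- unname(lm0[chamber])
    npx <- vapply(series@frames, function(f) sum(f@grid == code), integer(1))
    if (sum(npx < minPixels) > length(npx) / 2) return(NULL)
    tryCatch(chamberAreaSeries(series, chamber), error = function(e) NULL)
  }
  areas <- usable("LV")
  basis <- "LV"
  if (is.null(areas)) {
    areas <- usable("LA")
    basis <- "LA"
    flags <- c(flags, "la_fallback")
    if (is.null(areas)) stop("neither LV nor LA usable for phase selection")
  }
  ok <- which(!is.na(areas))
  imax <- ok[which.max(areas[ok])]   # earliest frame on ties
  imin <- ok[which.min(areas[ok])]
  if (sum(areas[ok] == areas[imax]) > 1L || sum(areas[ok] == areas[imin]) > 1L)
    flags <- c(flags, "tie")
  if (basis == "LV") {
    dia <- imax; sys <- imin
  } else {
    dia <- imin; sys <- imax  # inverted mapping for the atrium
  }
  new("PhaseSelection", systoleIndex = sys - 1L, diastoleIndex = dia - 1L,
      basis = basis, areas = areas, flags = flags)
}
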