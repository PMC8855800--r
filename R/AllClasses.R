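#' @useDynLib cineMorph, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods new validObject is slot
#' @importFrom stats lm coef pnorm rnorm runif rbinom sd
#' @importFrom utils read.csv write.csv read.table write.table
#' @importFrom grDevices chull
NULL

.CHAMBERS <- c("LV", "LA", "RV", "RA")

#' Default chamber label encoding
#'
#' The integer codes used for the four cardiac chambers when none are supplied.
#' The background is always 0.
#'
#' @return Named integer vector mapping chamber names \code{LV}, \code{LA},
#'   \code{RV}, \code{RA} to integer codes 1--4.
#' @export
#' @examples
#' defaultLabelMap()
defaultLabelMap <- function() {
  c(LV = 1L, LA = 2L, RV = 3L, RA = 4L)
}

#' LabelMask: one cine frame of integer chamber labels
#'
#' An S4 container for a single 2D segmentation label raster together with its
#' physical pixel spacing, the chamber-name-to-code association, and the
#' frame's ordinal position in the cardiac cycle. Background is fixed at code
#' 0. All coordinates in this package are (row, col), 1-based in R,
#' pixel-centre convention.
#'
#' @slot grid integer matrix (rows x cols) of label codes; 0 is background.
#' @slot spacing numeric length-2, (row_mm_per_px, col_mm_per_px); both > 0.
#' @slot labelMap named integer vector associating chamber names with codes.
#' @slot frameIndex integer, 0-based ordinal position in the cine cycle.
#'
#' @aliases LabelMask-class
#' @exportClass LabelMask
setClass("LabelMask",
  representation(
    grid = "matrix",
    spacing = "numeric",
    labelMap = "integer",
    frameIndex = "integer"
  )
)

setValidity("LabelMask", function(object) {
  msg <- character()
  g <- object@grid
  if (!is.numeric(g) && !is.integer(g))
    msg <- c(msg, "grid must be an integer matrix")
  if (nrow(g) < 2L || ncol(g) < 2L)
    msg <- c(msg, "grid must be at least 2x2")
  if (length(object@spacing) != 2L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be two strictly positive values (row, col)")
  if (is.null(names(object@labelMap)) || any(!nzchar(names(object@labelMap))))
    msg <- c(msg, "labelMap must be a named integer vector")
  if (anyDuplicated(object@labelMap))
    msg <- c(msg, "labelMap codes must be unique")
  if (any(object@labelMap == 0L))
    msg <- c(msg, "label code 0 is reserved for background")
  present <- unique(as.integer(g))
  present <- present[present != 0L]
  unknown <- setdiff(present, object@labelMap)
  if (length(unknown))
    msg <- c(msg, paste0("grid contains label code(s) absent from labelMap: ",
                         paste(unknown, collapse = ", ")))
  if (length(object@frameIndex) != 1L || is.na(object@frameIndex) ||
      object@frameIndex < 0L)
    msg <- c(msg, "frameIndex must be a single non-negative integer")
  if (length(msg)) msg else TRUE
})

#' Construct a LabelMask
#'
#' @param grid integer matrix of label codes (0 = background).
#' @param spacing numeric length-2 pixel spacing (row, col) in mm/px.
#' @param labelMap named integer vector of chamber codes; defaults to
#'   \code{defaultLabelMap()}.
#' @param frameIndex 0-based frame ordinal.
#' @return A \linkS4class{LabelMask} object.
#' @export
#' @examples
#' m <- LabelMask(matrix(0L, 10, 10), spacing = c(1, 1))
#' m
LabelMask <- function(grid, spacing, labelMap = defaultLabelMap(),
                      frameIndex = 0L) {
  storage.mode(grid) <- "integer"
  new("LabelMask", grid = grid, spacing = as.numeric(spacing),
      labelMap = structure(as.integer(labelMap), names = names(labelMap)),
      frameIndex = as.integer(frameIndex))
}

#' CineSeries: one subject's ordered 4-chamber cine acquisition
#'
#' @slot frames list of \linkS4class{LabelMask}; frameIndex strictly
#'   increasing from 0, identical grid shape, spacing and labelMap.
#' @slot subjectId opaque subject identifier.
#'
#' @aliases CineSeries-class
#' @exportClass CineSeries
setClass("CineSeries",
  representation(frames = "list", subjectId = "character")
)

setValidity("CineSeries", function(object) {
  msg <- character()
  fr <- object@frames
  if (!length(fr)) msg <- c(msg, "a CineSeries needs at least one frame")
  if (!all(vapply(fr, is, logical(1), class2 = "LabelMask")))
    msg <- c(msg, "all frames must be LabelMask objects")
  if (!length(msg)) {
    dims <- vapply(fr, function(f) dim(f@grid), integer(2))
    if (length(fr) > 1L && any(dims != dims[, 1]))
      msg <- c(msg, "all frames must share the grid shape")
    sp <- vapply(fr, function(f) f@spacing, numeric(2))
    if (length(fr) > 1L && any(sp != sp[, 1]))
      msg <- c(msg, "all frames must share the pixel spacing")
    lm0 <- fr[[1]]@labelMap
    same <- vapply(fr, function(f) identical(f@labelMap, lm0), logical(1))
    if (!all(same)) msg <- c(msg, "all frames must share the labelMap")
    idx <- vapply(fr, function(f) f@frameIndex, integer(1))
    if (!identical(idx, seq_along(fr) - 1L))
      msg <- c(msg, "frameIndex must run 0, 1, ... over the frames")
  }
  if (length(object@subjectId) != 1L)
    msg <- c(msg, "subjectId must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct a CineSeries
#'
#' @param frames list of \linkS4class{LabelMask} objects (frameIndex is
#'   renumbered 0..n-1 in list order).
#' @param subjectId subject identifier string.
#' @return A \linkS4class{CineSeries}.
#' @export
CineSeries <- function(frames, subjectId = "subject") {
  frames <- lapply(seq_along(frames), function(i) {
    f <- frames[[i]]
    f@frameIndex <- i - 1L
    f
  })
  new("CineSeries", frames = frames, subjectId = as.character(subjectId))
}

#' MedialPath: the skeleton's longest geodesic path through a chamber
#'
#' @slot points integer matrix (n x 2) of (row, col) path coordinates,
#'   consecutive points 8-adjacent, all inside the chamber region.
#' @slot chamber chamber name.
#' @slot basePoint,apexPoint numeric length-2 (row, col) of the designated
#'   endpoints, or NA before \code{classifyBaseApex} has run.
#' @slot flags character vector of warning flags ("degenerate", "tie").
#'
#' @aliases MedialPath-class
#' @exportClass MedialPath
setClass("MedialPath",
  representation(points = "matrix", chamber = "character",
                 basePoint = "numeric", apexPoint = "numeric",
                 flags = "character")
)

setValidity("MedialPath", function(object) {
  msg <- character()
  p <- object@points
  if (ncol(p) != 2L || nrow(p) < 2L)
    msg <- c(msg, "points must be an n x 2 matrix with n >= 2")
  if (nrow(p) >= 2L) {
    d <- abs(diff(p))
    if (!("degenerate" %in% object@flags) && any(pmax(d[, 1], d[, 2]) > 1L))
      msg <- c(msg, "consecutive path points must be 8-adjacent")
  }
  if (length(msg)) msg else TRUE
})

#' InterfaceSegment: the pixel band where two chambers meet
#'
#' Houses an atrioventricular annulus (LA-LV: mitral; RA-RV: tricuspid) or a
#' septum (LV-RV, LA-RA). Pixels carry one of the two chamber labels and lie
#' within the Chebyshev adjacency radius of the other chamber's region.
#'
#' @slot pixels integer matrix (n x 2) of (row, col) interface positions.
#' @slot chamberA,chamberB the two chamber names.
#' @slot endpoint1,endpoint2 numeric length-2 (row, col): the pixel pair at
#'   maximal mm-scaled Euclidean distance.
#' @slot valve "mitral_annulus", "tricuspid_annulus", or "none".
#' @slot flags character warning flags ("degenerate").
#'
#' @aliases InterfaceSegment-class
#' @exportClass InterfaceSegment
setClass("InterfaceSegment",
  representation(pixels = "matrix", chamberA = "character",
                 chamberB = "character", endpoint1 = "numeric",
                 endpoint2 = "numeric", valve = "character",
                 flags = "character")
)

setValidity("InterfaceSegment", function(object) {
  msg <- character()
  if (ncol(object@pixels) != 2L || nrow(object@pixels) < 1L)
    msg <- c(msg, "pixels must be a nonempty n x 2 matrix")
  for (ep in list(object@endpoint1, object@endpoint2)) {
    hit <- object@pixels[, 1] == ep[1] & object@pixels[, 2] == ep[2]
    if (!any(hit)) msg <- c(msg, "endpoints must be members of pixels")
  }
  if (length(msg)) msg else TRUE
})

#' PhaseSelection: end-systolic and end-diastolic frame choice
#'
#' @slot systoleIndex,diastoleIndex 0-based frame ordinals.
#' @slot basis "LV" or "LA" (the chamber whose area series was used).
#' @slot areas per-frame basis-chamber areas in mm^2 (NA where absent).
#' @slot flags character warning flags ("tie", "la_fallback").
#'
#' @aliases PhaseSelection-class
#' @exportClass PhaseSelection
setClass("PhaseSelection",
  representation(systoleIndex = "integer", diastoleIndex = "integer",
                 basis = "character", areas = "numeric", flags = "character")
)

setValidity("PhaseSelection", function(object) {
  msg <- character()
  n <- length(object@areas)
  for (i in c(object@systoleIndex, object@diastoleIndex))
    if (i < 0L || i >= n) msg <- c(msg, "phase indices must lie in the series")
  if (!object@basis %in% c("LV", "LA"))
    msg <- c(msg, "basis must be LV or LA")
  if (length(msg)) msg else TRUE
})
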