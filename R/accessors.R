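#' @name accessors
#' @title Accessors for cineMorph S4 objects
#' @description Slot accessors: prefer these over direct \code{@} access.
#' @param x a cineMorph S4 object.
#' @param i frame selector for \code{getFrame}.
NULL

#' @rdname accessors
#' @export
setGeneric("maskGrid", function(x) standardGeneric("maskGrid"))
#' @rdname accessors
#' @export
setMethod("maskGrid", "LabelMask", function(x) x@grid)

#' @rdname accessors
#' @export
setGeneric("pixelSpacing", function(x) standardGeneric("pixelSpacing"))
#' @rdname accessors
#' @export
setMethod("pixelSpacing", "LabelMask", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("pixelSpacing", "CineSeries", function(x) x@frames[[1]]@spacing)

#' @rdname accessors
#' @export
setGeneric("labelMap", function(x) standardGeneric("labelMap"))
#' @rdname accessors
#' @export
setMethod("labelMap", "LabelMask", function(x) x@labelMap)
#' @rdname accessors
#' @export
setMethod("labelMap", "CineSeries", function(x) x@frames[[1]]@labelMap)

#' @rdname accessors
#' @export
setGeneric("frameIndex", function(x) standardGeneric("frameIndex"))
#' @rdname accessors
#' @export
setMethod("frameIndex", "LabelMask", function(x) x@frameIndex)

#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @rdname accessors
#' @export
setMethod("frames", "CineSeries", function(x) x@frames)

#' @rdname accessors
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))
#' @rdname accessors
#' @export
setMethod("getFrame", "CineSeries", function(x, i) x@frames[[i + 1L]])

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setMethod("nFrames", "CineSeries", function(x) length(x@frames))

#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setMethod("subjectId", "CineSeries", function(x) x@subjectId)

#' @rdname accessors
#' @export
setGeneric("pathPoints", function(x) standardGeneric("pathPoints"))
#' @rdname accessors
#' @export
setMethod("pathPoints", "MedialPath", function(x) x@points)

#' @rdname accessors
#' @export
setGeneric("basePoint", function(x) standardGeneric("basePoint"))
#' @rdname accessors
#' @export
setMethod("basePoint", "MedialPath", function(x) x@basePoint)

#' @rdname accessors
#' @export
setGeneric("apexPoint", function(x) standardGeneric("apexPoint"))
#' @rdname accessors
#' @export
setMethod("apexPoint", "MedialPath", function(x) x@apexPoint)

#' @rdname accessors
#' @export
setGeneric("interfacePixels", function(x) standardGeneric("interfacePixels"))
#' @rdname accessors
#' @export
setMethod("interfacePixels", "InterfaceSegment", function(x) x@pixels)

#' @rdname accessors
#' @export
setGeneric("interfaceEndpoints", function(x) standardGeneric("interfaceEndpoints"))
#' @rdname accessors
#' @export
setMethod("interfaceEndpoints", "InterfaceSegment",
          function(x) rbind(x@endpoint1, x@endpoint2, deparse.level = 0))

#' @rdname accessors
#' @export
setGeneric("valveName", function(x) standardGeneric("valveName"))
#' @rdname accessors
#' @export
setMethod("valveName", "InterfaceSegment", function(x) x@valve)

#' @rdname accessors
#' @export
setGeneric("qcFlags", function(x) standardGeneric("qcFlags"))
#' @rdname accessors
#' @export
setMethod("qcFlags", "MedialPath", function(x) x@flags)
#' @rdname accessors
#' @export
setMethod("qcFlags", "InterfaceSegment", function(x) x@flags)
#' @rdname accessors
#' @export
setMethod("qcFlags", "PhaseSelection", function(x) x@flags)

#' @rdname accessors
#' @export
setGeneric("systoleIndex", function(x) standardGeneric("systoleIndex"))
#' @rdname accessors
#' @export
setMethod("systoleIndex", "PhaseSelection", function(x) x@systoleIndex)

#' @rdname accessors
#' @export
setGeneric("diastoleIndex", function(x) standardGeneric("diastoleIndex"))
#' @rdname accessors
#' @export
setMethod("diastoleIndex", "PhaseSelection", function(x) x@diastoleIndex)

#' @rdname accessors
#' @export
setGeneric("phaseBasis", function(x) standardGeneric("phaseBasis"))
#' @rdname accessors
#' @export
setMethod("phaseBasis", "PhaseSelection", function(x) x@basis)

#' @rdname accessors
#' @export
setGeneric("phaseAreas", function(x) standardGeneric("phaseAreas"))
#' @rdname accessors
#' @export
setMethod("phaseAreas", "PhaseSelection", function(x) x@areas)

setMethod("show", "LabelMask", function(object) {
  g <- object@grid
  counts <- vapply(object@labelMap, function(code) sum(g == code), integer(1))
  cat(sprintf("LabelMask %dx%d px, spacing (%.4g, %.4g) mm/px, frame %d\n",
              nrow(g), ncol(g), object@spacing[1], object@spacing[2],
              object@frameIndex))
  cat("  chamber px:", paste(sprintf("%s=%d", names(counts), counts),
                             collapse = " "), "\n")
})

setMethod("show", "CineSeries", function(object) {
  f1 <- object@frames[[1]]
  cat(sprintf("CineSeries '%s': %d frames of %dx%d px, spacing (%.4g, %.4g) mm/px\n",
              object@subjectId, length(object@frames), nrow(f1@grid),
              ncol(f1@grid), f1@spacing[1], f1@spacing[2]))
})

setMethod("show", "MedialPath", function(object) {
  cat(sprintf("MedialPath through %s: %d points", object@chamber,
              nrow(object@points)))
  if (!anyNA(object@basePoint))
    cat(sprintf(", base (%d,%d), apex (%d,%d)", object@basePoint[1],
                object@basePoint[2], object@apexPoint[1], object@apexPoint[2]))
  if (length(object@flags)) cat(" [", paste(object@flags, collapse = ","), "]")
  cat("\n")
})

setMethod("show", "InterfaceSegment", function(object) {
  cat(sprintf("InterfaceSegment %s-%s (%s): %d px, endpoints (%d,%d)-(%d,%d)",
              object@chamberA, object@chamberB, object@valve,
              nrow(object@pixels), object@endpoint1[1], object@endpoint1[2],
              object@endpoint2[1], object@endpoint2[2]))
  if (length(object@flags)) cat(" [", paste(object@flags, collapse = ","), "]")
  cat("\n")
})

setMethod("show", "PhaseSelection", function(object) {
  cat(sprintf("PhaseSelection (basis %s): systole frame %d, diastole frame %d\n",
              object@basis, object@systoleIndex, object@diastoleIndex))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ","), "\n")
})
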