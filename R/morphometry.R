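#' Clean a label mask before measurement
#'
#' Robustness pre-pass applied before any geometry: per chamber label, keeps
#' only the largest 8-connected component (ties broken in favour of the
#' component containing the first pixel in column-major scan order) and
#' assigns fully enclosed background holes to the enclosing chamber. Other
#' labels are untouched; empty labels pass through empty. Idempotent.
#'
#' @param mask a \linkS4class{LabelMask}.
#' @return A cleaned \linkS4class{LabelMask}.
#' @export
cleanMask <- function(mask) {
  stopifnot(is(mask, "LabelMask"))
  g <- mask@grid
  for (code in mask@labelMap) {
    fg <- g == code
    if (!any(fg)) next
    lab <- cpp_label_components(fg)
    if (max(lab) > 1L) {
      sizes <- tabulate(lab[lab > 0L])
      keep <- which.max(sizes)  # first max in scan order on ties
      g[fg & lab != keep] <- 0L
    }
    fg <- g == code
    reach <- cpp_reachable_background(fg)
    holes <- !fg & !reach & g == 0L
    g[holes] <- code
  }
  out <- mask
  out@grid <- g
  out
}

.chamberCode <- function(mask, chamber) {
  code <- mask@labelMap[chamber]
  if (is.na(code)) stop("chamber '", chamber, "' not in labelMap")
  unname(code)
}

.chamberPixels <- function(mask, chamber) {
  which(mask@grid == .chamberCode(mask, chamber), arr.ind = TRUE)
}

#' Medial axis path of a chamber
#'
#' Skeletonizes the chamber's binary region (Zhang-Suen thinning, preserving
#' 8-connectivity) and returns the longest geodesic path between skeleton
#' endpoints, found by a double farthest-point BFS sweep on the skeleton's
#' 8-adjacency graph. This path approximates the chamber's long axis; its
#' endpoints are the candidates for the base and apex.
#'
#' @param mask a \linkS4class{LabelMask} (run [cleanMask()] first so the
#'   region is single-component).
#' @param chamber chamber name ("LV", "LA", "RV", "RA").
#' @return A \linkS4class{MedialPath}. If the skeleton degenerates to a
#'   single pixel the path is that pixel duplicated, flagged "degenerate".
#' @export
medialAxisPath <- function(mask, chamber) {
  stopifnot(is(mask, "LabelMask"))
  fg <- mask@grid == .chamberCode(mask, chamber)
  if (!any(fg)) stop("chamber '", chamber, "' is empty")
  sk <- cpp_thin(fg)
  flags <- character()
  if (sum(sk) == 1L) {
    p <- which(sk, arr.ind = TRUE)
    pts <- rbind(p, p)
    flags <- "degenerate"
    warning("skeleton of ", chamber, " degenerates to a single pixel")
  } else {
    pts <- cpp_longest_geodesic(sk)
    # Thinning retracts a skeleton from the boundary by half the local
    # region width, which would park the base/apex mid-chamber on blocky
    # regions; extend both path ends geodesically to the region boundary.
    pts <- .extendToBoundary(pts, fg)
  }
  new("MedialPath", points = pts, chamber = chamber,
      basePoint = c(NA_real_, NA_real_), apexPoint = c(NA_real_, NA_real_),
      flags = flags)
}

# Greedy geodesic extension of a path end within the region: step to the
# in-region 8-neighbour that most increases Euclidean distance from the
# opposite path end, until no step increases it. Distance strictly
# increases, so this terminates.
.extendOneEnd <- function(pts, fg, fromEnd) {
  n <- nrow(pts)
  tip <- if (fromEnd == 1L) pts[1, ] else pts[n, ]
  other <- if (fromEnd == 1L) pts[n, ] else pts[1, ]
  add <- NULL
  repeat {
    best <- sum((tip - other)^2); bestp <- NULL
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      r <- tip[1] + dr; c <- tip[2] + dc
      if (r < 1L || r > nrow(fg) || c < 1L || c > ncol(fg) || !fg[r, c]) next
      d2 <- sum((c(r, c) - other)^2)
      if (d2 > best) { best <- d2; bestp <- c(r, c) }
    }
    if (is.null(bestp)) break
    add <- rbind(add, bestp)
    tip <- bestp
  }
  if (is.null(add)) return(pts)
  if (fromEnd == 1L) rbind(add[rev(seq_len(nrow(add))), , drop = FALSE], pts)
  else rbind(pts, add)
}

.extendToBoundary <- function(pts, fg) {
  pts <- .extendOneEnd(pts, fg, 1L)
  pts <- .extendOneEnd(pts, fg, 2L)
  dimnames(pts) <- NULL
  pts
}

#' Designate the base and apex of a medial path
#'
#' Of the path's two endpoints, the one nearer (Euclidean, mm-scaled) to the
#' paired chamber across the atrioventricular valve is the base; the other is
#' the apex. For an atrium the base faces its ventricle; for a ventricle the
#' apex faces away from its atrium. Exact distance ties are resolved by
#' row-major order of the endpoint coordinates and flagged "tie".
#'
#' @param path a \linkS4class{MedialPath}.
#' @param mask the \linkS4class{LabelMask} the path came from.
#' @param pairedChamber the chamber across the AV valve (e.g. "LV" when
#'   \code{path} runs through "LA").
#' @return The path with \code{basePoint}/\code{apexPoint} set.
#' @export
classifyBaseApex <- function(path, mask, pairedChamber) {
  stopifnot(is(path, "MedialPath"), is(mask, "LabelMask"))
  other <- .chamberPixels(mask, pairedChamber)
  if (nrow(other) == 0L) stop("paired chamber '", pairedChamber, "' is empty")
  sp <- mask@spacing
  ep <- rbind(path@points[1, ], path@points[nrow(path@points), ])
  d2min <- vapply(1:2, function(i) {
    dr <- (other[, 1] - ep[i, 1]) * sp[1]
    dc <- (other[, 2] - ep[i, 2]) * sp[2]
    min(dr * dr + dc * dc)
  }, numeric(1))
  if (d2min[1] == d2min[2]) {
    # tie: row-major order (smaller row, then smaller col) becomes the base
    first <- order(ep[, 1], ep[, 2])[1]
    path@flags <- union(path@flags, "tie")
  } else {
    first <- which.min(d2min)
  }
  path@basePoint <- as.numeric(ep[first, ])
  path@apexPoint <- as.numeric(ep[3L - first, ])
  path
}

.valveFor <- function(a, b) {
  pair <- paste(sort(c(a, b)), collapse = "-")
  switch(pair,
         "LA-LV" = "mitral_annulus",
         "RA-RV" = "tricuspid_annulus",
         "none")
}

# Chebyshev dilation of a logical matrix by `r` pixels (r small).
.dilateCheb <- function(fg, r) {
  if (r == 0L) return(fg)
  nr <- nrow(fg); nc <- ncol(fg)
  out <- fg
  for (k in seq_len(r)) {
    g <- out
    out <- g
    out[-1, ] <- out[-1, ] | g[-nr, ]
    out[-nr, ] <- out[-nr, ] | g[-1, ]
    out[, -1] <- out[, -1] | g[, -nc]
    out[, -nc] <- out[, -nc] | g[, -1]
    out[-1, -1] <- out[-1, -1] | g[-nr, -nc]
    out[-1, -nc] <- out[-1, -nc] | g[-nr, -1]
    out[-nr, -1] <- out[-nr, -1] | g[-1, -nc]
    out[-nr, -nc] <- out[-nr, -nc] | g[-1, -1]
  }
  out
}

# Farthest pixel pair under mm scaling. Uses convex hull + exhaustive search
# over hull vertices (any farthest pair is a hull-vertex pair); ties broken
# by lexicographic order of the ordered coordinate pair.
.farthestPair <- function(px, spacing) {
  n <- nrow(px)
  if (n == 1L) return(list(p1 = px[1, ], p2 = px[1, ], d = 0))
  y <- px[, 1] * spacing[1]
  x <- px[, 2] * spacing[2]
  idx <- seq_len(n)
  if (n > 3L) {
    h <- unique(c(chull(x, y)))
    # chull drops interior points; degenerate (collinear) sets keep extremes
    if (length(h) >= 2L) idx <- h
  }
  best <- -1; b1 <- 0L; b2 <- 0L
  for (i in idx) {
    d2 <- (y[idx] - y[i])^2 + (x[idx] - x[i])^2
    dm <- max(d2)
    cand <- idx[d2 == dm]
    for (j in cand) {
      a <- i; b <- j
      if (px[b, 1] < px[a, 1] || (px[b, 1] == px[a, 1] && px[b, 2] < px[a, 2])) {
        tmp <- a; a <- b; b <- tmp
      }
      if (dm > best ||
          (dm == best && (px[a, 1] < px[b1, 1] ||
            (px[a, 1] == px[b1, 1] && (px[a, 2] < px[b1, 2] ||
              (px[a, 2] == px[b1, 2] && (px[b, 1] < px[b2, 1] ||
                (px[b, 1] == px[b2, 1] && px[b, 2] < px[b2, 2])))))))) {
        best <- dm; b1 <- a; b2 <- b
      }
    }
  }
  list(p1 = as.numeric(px[b1, ]), p2 = as.numeric(px[b2, ]), d = sqrt(best))
}

#' Locate the interface between two chambers
#'
#' The interface is the band of pixels carrying one of the two chamber labels
#' that lie within \code{adjacencyRadius} (Chebyshev distance) of the other
#' chamber's region. For an atrium-ventricle pair this band marks the
#' atrioventricular annulus. The interface endpoints are the pixel pair at
#' maximal mm-scaled Euclidean distance (ties broken by lexicographic
#' coordinate order).
#'
#' @param mask a \linkS4class{LabelMask}.
#' @param chamberA,chamberB the two chamber names.
#' @param adjacencyRadius Chebyshev adjacency radius in px (default 1,
#'   i.e. 8-connectivity).
#' @return An \linkS4class{InterfaceSegment}; a single-pixel interface is
#'   returned with coincident endpoints and flag "degenerate".
#' @export
avInterface <- function(mask, chamberA, chamberB, adjacencyRadius = 1L) {
  stopifnot(is(mask, "LabelMask"), adjacencyRadius >= 1L)
  fgA <- mask@grid == .chamberCode(mask, chamberA)
  fgB <- mask@grid == .chamberCode(mask, chamberB)
  if (!any(fgA)) stop("chamber '", chamberA, "' is empty")
  if (!any(fgB)) stop("chamber '", chamberB, "' is empty")
  near <- (fgA & .dilateCheb(fgB, adjacencyRadius)) |
          (fgB & .dilateCheb(fgA, adjacencyRadius))
  px <- which(near, arr.ind = TRUE)
  dimnames(px) <- NULL
  if (nrow(px) == 0L)
    stop("chambers '", chamberA, "' and '", chamberB,
         "' are not adjacent at radius ", adjacencyRadius)
  fp <- .farthestPair(px, mask@spacing)
  flags <- if (fp$d == 0) "degenerate" else character()
  new("InterfaceSegment", pixels = px, chamberA = chamberA,
      chamberB = chamberB, endpoint1 = fp$p1, endpoint2 = fp$p2,
      valve = .valveFor(chamberA, chamberB), flags = flags)
}

.mmDist <- function(p1, p2, spacing) {
  sqrt(((p1[1] - p2[1]) * spacing[1])^2 + ((p1[2] - p2[2]) * spacing[2])^2)
}

.measurementRow <- function(name, p1, p2, length_mm, spacing, frameIndex,
                            phase = "unassigned", flags = "") {
  iso <- spacing[1] == spacing[2]
  data.frame(
    name = name, r1 = p1[1], c1 = p1[2], r2 = p2[1], c2 = p2[2],
    length_px = if (iso) length_mm / spacing[1] else NA_real_,
    length_mm = length_mm, frame_index = as.integer(frameIndex),
    phase = phase, flags = flags, stringsAsFactors = FALSE)
}

#' Annular diameter from an interface
#'
#' The annular diameter is the chord between the interface endpoints:
#' \code{sqrt((drow x row_mm)^2 + (dcol x col_mm)^2)}. The measurement name
#' follows the interface's valve identity. Pixel lengths are reported only
#' under isotropic spacing; millimetre lengths always come from
#' anisotropically scaled coordinate deltas.
#'
#' @param interface an \linkS4class{InterfaceSegment}.
#' @param spacing numeric length-2 (row, col) mm/px.
#' @param frameIndex frame ordinal recorded in the measurement.
#' @return One-row data.frame (a linear measurement record).
#' @export
annulusDiameter <- function(interface, spacing, frameIndex = 0L) {
  stopifnot(is(interface, "InterfaceSegment"))
  d <- .mmDist(interface@endpoint1, interface@endpoint2, spacing)
  flags <- if (d == 0) "degenerate" else ""
  .measurementRow(interface@valve, interface@endpoint1, interface@endpoint2,
                  d, spacing, frameIndex, flags = flags)
}

# Reduce an interface band to a single-pixel path and chain it by greedy
# nearest-neighbour from one extremal endpoint; returns the mm arc length.
.chainArcLength <- function(px, spacing, start, maxStepPx = 2) {
  n <- nrow(px)
  if (n == 1L) return(list(len = 0, ok = TRUE))
  y <- px[, 1] * spacing[1]
  x <- px[, 2] * spacing[2]
  used <- logical(n)
  d0 <- (px[, 1] - start[1])^2 + (px[, 2] - start[2])^2
  cur <- which.min(d0)
  used[cur] <- TRUE
  total <- 0
  for (step in seq_len(n - 1L)) {
    d2 <- (y - y[cur])^2 + (x - x[cur])^2
    d2[used] <- Inf
    nxt <- which.min(d2)
    stepPx <- max(abs(px[nxt, 1] - px[cur, 1]), abs(px[nxt, 2] - px[cur, 2]))
    if (stepPx > maxStepPx) return(list(len = total, ok = FALSE))
    total <- total + sqrt(d2[nxt])
    used[nxt] <- TRUE
    cur <- nxt
  }
  list(len = total, ok = TRUE)
}

#' Septal arc length between two chambers
#'
#' Measures the interventricular (LV-RV) or atrial (LA-RA) septum as the arc
#' length along the chamber interface. The full interface band is two pixels
#' thick for abutting chambers, so the path is taken along one side of it:
#' the pixels of \code{chamberA} facing \code{chamberB} (thinned if the
#' adjacency radius makes that side thick), chained by nearest-neighbour from
#' one extremal endpoint, summing the mm-scaled steps. Arc length, not the
#' endpoint chord, because a septum is curved and a chord would
#' systematically underestimate it. If chaining fails (disconnected
#' interface) the endpoint chord is returned, flagged "chord_fallback".
#'
#' @param mask a \linkS4class{LabelMask}.
#' @param chamberA,chamberB the septal chamber pair ("LV","RV" or "LA","RA").
#' @param spacing numeric length-2 mm/px; defaults to the mask's spacing.
#' @param adjacencyRadius Chebyshev adjacency radius in px.
#' @return One-row data.frame (a linear measurement record) named
#'   \code{interventricular_septum} or \code{atrial_septum}.
#' @export
septalLength <- function(mask, chamberA, chamberB,
                         spacing = pixelSpacing(mask), adjacencyRadius = 1L) {
  pair <- paste(sort(c(chamberA, chamberB)), collapse = "-")
  name <- switch(pair, "LV-RV" = "interventricular_septum",
                 "LA-RA" = "atrial_septum",
                 stop("septal pair must be LV-RV or LA-RA, got ", pair))
  iface <- avInterface(mask, chamberA, chamberB, adjacencyRadius)
  # one side of the band: chamberA pixels facing chamberB
  codeA <- .chamberCode(mask, chamberA)
  side <- matrix(FALSE, nrow(mask@grid), ncol(mask@grid))
  side[iface@pixels] <- TRUE
  side <- side & (mask@grid == codeA)
  if (!any(side)) side[iface@pixels] <- TRUE  # radius-r oddity: keep band
  if (adjacencyRadius > 1L) side <- cpp_thin(side)
  px <- which(side, arr.ind = TRUE)
  dimnames(px) <- NULL
  res <- .chainArcLength(px, spacing, iface@endpoint1,
                         maxStepPx = 2 * adjacencyRadius + 1)
  if (res$ok) {
    len <- res$len
    flags <- if (len == 0) "degenerate" else ""
  } else {
    len <- .mmDist(iface@endpoint1, iface@endpoint2, spacing)
    flags <- "chord_fallback"
  }
  .measurementRow(name, iface@endpoint1, iface@endpoint2, len, spacing,
                  frameIndex(mask), flags = flags)
}

#' Measure one 4-chamber frame
#'
#' The frame-level measuring function: cleans the mask, then measures the
#' mitral (LA-LV) and tricuspid (RA-RV) annular diameters, the
#' interventricular (LV-RV) and atrial (LA-RA) septal lengths, and each
#' chamber's area (pixel count x row_mm x col_mm). Measurements whose
#' chambers are missing are absent from the result, never zero-filled.
#' When \code{orientationQC} is on, frames where an atrial medial-axis base
#' point lies more than \code{adjacencyRadius + 2} px from its annular
#' interface are flagged "base_far_from_interface".
#'
#' @param mask a \linkS4class{LabelMask} (at least the LA-LV pair should be
#'   present for the mitral measurement).
#' @param adjacencyRadius Chebyshev adjacency radius in px.
#' @param orientationQC run the medial-axis base/apex orientation check
#'   (default TRUE; switch off for speed in bulk runs).
#' @return list with \code{measurements} (data.frame of linear measurements)
#'   and \code{areas} (named numeric, mm^2, absent chambers dropped).
#' @export
measureFrame <- function(mask, adjacencyRadius = 1L, orientationQC = TRUE) {
  stopifnot(is(mask, "LabelMask"))
  mask <- cleanMask(mask)
  g <- mask@grid
  sp <- mask@spacing
  present <- names(mask@labelMap)[vapply(mask@labelMap,
                                         function(code) any(g == code),
                                         logical(1))]
  if (!length(present)) stop("no chambers present in mask")
  rows <- list()
  pairs <- list(c("LA", "LV"), c("RA", "RV"))
  for (p in pairs) {
    if (!all(p %in% present)) next
    iface <- tryCatch(avInterface(mask, p[1], p[2], adjacencyRadius),
                      error = function(e) NULL)
    if (is.null(iface)) next
    m <- annulusDiameter(iface, sp, frameIndex(mask))
    if (orientationQC) {
      qc <- tryCatch({
        path <- classifyBaseApex(medialAxisPath(mask, p[1]), mask, p[2])
        bp <- path@basePoint
        dpx <- min(pmax(abs(iface@pixels[, 1] - bp[1]),
                        abs(iface@pixels[, 2] - bp[2])))
        dpx > adjacencyRadius + 2
      }, warning = function(w) FALSE, error = function(e) NA)
      if (isTRUE(qc))
        m$flags <- paste0(m$flags,
                          ifelse(nzchar(m$flags), ";", ""),
                          "base_far_from_interface")
    }
    rows[[length(rows) + 1L]] <- m
  }
  septa <- list(c("LV", "RV"), c("LA", "RA"))
  for (p in septa) {
    if (!all(p %in% present)) next
    m <- tryCatch(septalLength(mask, p[1], p[2], sp, adjacencyRadius),
                  error = function(e) NULL)
    if (!is.null(m)) rows[[length(rows) + 1L]] <- m
  }
  meas <- if (length(rows)) do.call(rbind, rows) else
    .measurementRow("none", c(NA, NA), c(NA, NA), NA_real_, sp, 0L)[0, ]
  areas <- vapply(present, function(ch)
    sum(g == mask@labelMap[ch]) * sp[1] * sp[2], numeric(1))
  list(measurements = meas, areas = areas)
}
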