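# Independent oracles and tiny mask builders used across the suite.

# Build a LabelMask from rectangular chamber blocks.
# blocks: named list, e.g. list(LA = list(rows = 1:10, cols = 6:35))
rectMask <- function(nr, nc, blocks, spacing = c(1, 1),
                     labelMap = defaultLabelMap(), frameIndex = 0L) {
  g <- matrix(0L, nr, nc)
  for (ch in names(blocks))
    g[blocks[[ch]]$rows, blocks[[ch]]$cols] <- labelMap[[ch]]
  LabelMask(g, spacing = spacing, labelMap = labelMap,
            frameIndex = frameIndex)
}

# Brute-force farthest pixel pair under mm scaling: full O(n^2) distance
# matrix, ties broken by lexicographic order of the ordered coordinate pair.
bruteFarthestPair <- function(px, spacing) {
  n <- nrow(px)
  if (n == 1L) return(list(p1 = px[1, ], p2 = px[1, ], d = 0))
  y <- px[, 1] * spacing[1]
  x <- px[, 2] * spacing[2]
  D <- (outer(y, y, "-"))^2 + (outer(x, x, "-"))^2
  dm <- max(D)
  idx <- which(D == dm, arr.ind = TRUE)
  best <- NULL
  for (k in seq_len(nrow(idx))) {
    a <- px[idx[k, 1], ]; b <- px[idx[k, 2], ]
    if (b[1] < a[1] || (b[1] == a[1] && b[2] < a[2])) { tmp <- a; a <- b; b <- tmp }
    key <- c(a, b)
    if (is.null(best) || .lexLess(key, best)) best <- key
  }
  list(p1 = best[1:2], p2 = best[3:4], d = sqrt(dm))
}

.lexLess <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

# Brute-force interface pixels: labeled pixels of either chamber within
# Chebyshev radius r of the other chamber's pixels.
bruteInterface <- function(mask, a, b, r = 1L) {
  lm0 <- labelMap(mask); g <- maskGrid(mask)
  pa <- which(g == lm0[[a]], arr.ind = TRUE)
  pb <- which(g == lm0[[b]], arr.ind = TRUE)
  near <- function(p, set) any(pmax(abs(set[, 1] - p[1]),
                                    abs(set[, 2] - p[2])) <= r)
  keep_a <- pa[apply(pa, 1, near, set = pb), , drop = FALSE]
  keep_b <- pb[apply(pb, 1, near, set = pa), , drop = FALSE]
  px <- rbind(keep_a, keep_b)
  dimnames(px) <- NULL
  px[order(px[, 1], px[, 2]), , drop = FALSE]
}

# Connected-component sizes via igraph (independent of the package's C code).
igraphComponentSizes <- function(fg) {
  px <- which(fg, arr.ind = TRUE)
  if (nrow(px) == 0L) return(integer())
  n <- nrow(px)
  edges <- NULL
  for (i in seq_len(n)) {
    d <- pmax(abs(px[, 1] - px[i, 1]), abs(px[, 2] - px[i, 2]))
    js <- which(d == 1L & seq_len(n) > i)
    if (length(js)) edges <- rbind(edges, cbind(i, js))
  }
  gr <- igraph::graph_from_edgelist(edges, directed = FALSE)
  gr <- igraph::add_vertices(gr, max(0, n - igraph::vcount(gr)))
  sort(igraph::components(gr)$csize, decreasing = TRUE)
}

# All-pairs geodesic diameter (in steps) of a pixel set via igraph.
igraphGeodesicDiameter <- function(fg) {
  px <- which(fg, arr.ind = TRUE)
  n <- nrow(px)
  edges <- NULL
  for (i in seq_len(n)) {
    d <- pmax(abs(px[, 1] - px[i, 1]), abs(px[, 2] - px[i, 2]))
    js <- which(d == 1L & seq_len(n) > i)
    if (length(js)) edges <- rbind(edges, cbind(i, js))
  }
  gr <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::diameter(gr, directed = FALSE, unconnected = FALSE)
}

# Random connected blob grown from a seed pixel (for property tests).
randomBlob <- function(nr, nc, npix, seed) {
  set.seed(seed)
  fg <- matrix(FALSE, nr, nc)
  r <- sample(3:(nr - 2), 1); c <- sample(3:(nc - 2), 1)
  fg[r, c] <- TRUE
  frontier <- matrix(c(r, c), 1)
  while (sum(fg) < npix) {
    i <- sample(nrow(frontier), 1)
    p <- frontier[i, ]
    dr <- sample(-1:1, 1); dc <- sample(-1:1, 1)
    r2 <- min(max(p[1] + dr, 2), nr - 1)
    c2 <- min(max(p[2] + dc, 2), nc - 1)
    if (!fg[r2, c2]) {
      fg[r2, c2] <- TRUE
      frontier <- rbind(frontier, c(r2, c2))
    }
  }
  fg
}

# The standard two-chamber stack used in several tests: LA above LV.
laOverLv <- function(spacing = c(1, 1)) {
  rectMask(20, 40, list(LA = list(rows = 1:10, cols = 6:35),
                        LV = list(rows = 11:20, cols = 6:35)),
           spacing = spacing)
}
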