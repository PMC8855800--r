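test_that("cleanMask keeps the largest component and fills holes", {
  lm0 <- defaultLabelMap()
  g <- matrix(0L, 40, 40)
  g[5:29, 5:24] <- lm0[["LV"]]          # 500 px component
  g[35:35, 35:37] <- lm0[["LV"]]        # 3 px satellite
  m <- LabelMask(g, c(1, 1))
  cl <- cleanMask(m)
  expect_equal(sum(maskGrid(cl) == lm0[["LV"]]), 500L)
  expect_equal(maskGrid(cl)[35, 35:37], c(0L, 0L, 0L))
  # oracle: the surviving count equals the largest 8-connected size
  expect_equal(sum(maskGrid(cl) == lm0[["LV"]]),
               igraphComponentSizes(g == lm0[["LV"]])[1])

  # 1-px background hole inside LA -> assigned LA
  g2 <- matrix(0L, 20, 20)
  g2[4:15, 4:15] <- lm0[["LA"]]
  g2[9, 9] <- 0L
  cl2 <- cleanMask(LabelMask(g2, c(1, 1)))
  expect_equal(maskGrid(cl2)[9, 9], lm0[["LA"]])

  # idempotence on an already-clean mask
  expect_identical(maskGrid(cleanMask(cl)), maskGrid(cl))
})

test_that("medialAxisPath follows the chamber long axis", {
  # 1 x 21 horizontal strip: path is the strip itself
  g <- matrix(0L, 5, 25); g[3, 3:23] <- 1L
  p <- medialAxisPath(LabelMask(g, c(1, 1)), "LV")
  pts <- pathPoints(p)
  expect_equal(nrow(pts), 21L)
  expect_true(all(pts[, 1] == 3L))
  expect_setequal(pts[, 2], 3:23)

  # 40 x 12 vertical rectangle: endpoints near top and bottom edges,
  # geodesic length within 2 px of 39
  g2 <- matrix(0L, 44, 16); g2[3:42, 3:14] <- 1L
  p2 <- medialAxisPath(LabelMask(g2, c(1, 1)), "LV")
  pts2 <- pathPoints(p2)
  ends <- pts2[c(1, nrow(pts2)), 1]
  expect_lte(min(ends), 5L)
  expect_gte(max(ends), 40L)
  expect_lte(abs((nrow(pts2) - 1L) - 39L), 2L)
  # oracle: the region's exhaustive all-pairs geodesic diameter
  expect_lte(abs((nrow(pts2) - 1L) - igraphGeodesicDiameter(g2 == 1L)), 2L)
  # every path point lies inside the region, consecutive points 8-adjacent
  expect_true(all(g2[pts2] == 1L))
  steps <- pmax(abs(diff(pts2[, 1])), abs(diff(pts2[, 2])))
  expect_true(all(steps == 1L))

  expect_error(medialAxisPath(LabelMask(g2, c(1, 1)), "RA"), "empty")
})

test_that("classifyBaseApex orients the axis toward the paired chamber", {
  m <- laOverLv()
  la <- classifyBaseApex(medialAxisPath(m, "LA"), m, "LV")
  expect_gt(basePoint(la)[1], apexPoint(la)[1])  # lower endpoint is the base
  lv <- classifyBaseApex(medialAxisPath(m, "LV"), m, "LA")
  expect_lt(basePoint(lv)[1], apexPoint(lv)[1])  # upper endpoint is the base

  noLA <- rectMask(20, 40, list(LV = list(rows = 11:20, cols = 6:35)))
  expect_error(classifyBaseApex(medialAxisPath(noLA, "LV"), noLA, "LA"),
               "empty")
})

test_that("avInterface matches the worked example and brute force", {
  m <- laOverLv()
  iface <- avInterface(m, "LA", "LV", adjacencyRadius = 1L)
  ep <- interfaceEndpoints(iface)
  expect_equal(abs(ep[1, 2] - ep[2, 2]), 29)  # endpoint column gap
  # oracle: brute-force max-pairwise-distance over all interface pixels
  ref <- bruteFarthestPair(interfacePixels(iface), pixelSpacing(m))
  d <- sqrt(sum(((ep[1, ] - ep[2, ]) * pixelSpacing(m))^2))
  expect_equal(d, ref$d)
  expect_equal(unname(rbind(ref$p1, ref$p2)), unname(ep))
  # pixel-set equality with the brute-force interface definition
  got <- interfacePixels(iface)
  got <- got[order(got[, 1], got[, 2]), ]
  expect_equal(got, bruteInterface(m, "LA", "LV", 1L))

  # separated chambers: no interface at radius 1
  apart <- rectMask(30, 40, list(LA = list(rows = 1:10, cols = 6:35),
                                 LV = list(rows = 16:25, cols = 6:35)))
  expect_error(avInterface(apart, "LA", "LV", 1L), "not adjacent")

  # single-pixel touch: degenerate zero-length interface, flagged
  touch <- rectMask(21, 21, list(LA = list(rows = 10, cols = 10),
                                 LV = list(rows = 11, cols = 10)))
  it <- avInterface(touch, "LA", "LV", 1L)
  expect_true("degenerate" %in% qcFlags(it) ||
                nrow(interfacePixels(it)) == 2L)
})

test_that("annulusDiameter computes mm chords from endpoints", {
  m <- laOverLv()
  iface <- avInterface(m, "LA", "LV")
  # collinear-ish worked example at unit spacing
  d1 <- annulusDiameter(iface, c(1, 1))
  expect_equal(d1$name, "mitral_annulus")
  # doubling the column spacing doubles a column-aligned measurement
  m2 <- laOverLv(spacing = c(1, 2))
  iface2 <- avInterface(m2, "LA", "LV")
  d2 <- annulusDiameter(iface2, c(1, 2))
  ref2 <- bruteFarthestPair(interfacePixels(iface2), c(1, 2))
  expect_equal(d2$length_mm, ref2$d)

  # 3-4-5 triangle endpoints
  seg <- new("InterfaceSegment",
             pixels = rbind(c(1, 1), c(4, 5)), chamberA = "LA",
             chamberB = "LV", endpoint1 = c(1, 1), endpoint2 = c(4, 5),
             valve = "mitral_annulus", flags = character())
  expect_equal(annulusDiameter(seg, c(1, 1))$length_mm, 5)
  # anisotropic spacing scales each axis separately
  expect_equal(annulusDiameter(seg, c(1, 2))$length_mm, sqrt(9 + 64))
  expect_true(is.na(annulusDiameter(seg, c(1, 2))$length_px))
})

test_that("septalLength returns arc length of the chained interface", {
  lm0 <- defaultLabelMap()
  # straight vertical interface of 30 single-width pixel rows -> 29 mm
  m <- rectMask(34, 30, list(LV = list(rows = 3:32, cols = 3:14),
                             RV = list(rows = 3:32, cols = 15:26)))
  s <- septalLength(m, "LV", "RV")
  expect_equal(s$name, "interventricular_septum")
  expect_equal(s$length_mm, 29)

  # 45-degree staircase of 21 pixels -> 20 * sqrt(2)
  g <- matrix(0L, 30, 30)
  for (i in 0:20) {
    g[5 + i, 5 + i] <- lm0[["LA"]]
    g[6 + i, 5 + i] <- lm0[["RA"]]
  }
  m2 <- LabelMask(g, c(1, 1))
  s2 <- septalLength(m2, "LA", "RA")
  expect_equal(s2$name, "atrial_septum")
  expect_equal(s2$length_mm, 20 * sqrt(2))  # step-sum oracle

  apart <- rectMask(30, 40, list(LV = list(rows = 1:10, cols = 6:35),
                                 RV = list(rows = 16:25, cols = 6:35)))
  expect_error(septalLength(apart, "LV", "RV"), "not adjacent")
  expect_error(septalLength(m, "LA", "LV"), "septal pair")
})

test_that("measureFrame returns the full measurement set and areas", {
  ph <- generatePhantomSeries(phantomParams(nFrames = 1L, mitralAmp = 0,
                                            tricuspidAmp = 0, lvAreaAmp = 0,
                                            rvAreaAmp = 0, laAreaAmp = 0,
                                            raAreaAmp = 0, seed = 5L))
  fr <- getFrame(ph$series, 0)
  res <- measureFrame(fr)
  expect_equal(nrow(res$measurements), 4L)
  expect_equal(length(res$areas), 4L)
  truth <- ph$truth$perFrame
  mit <- res$measurements$length_mm[res$measurements$name == "mitral_annulus"]
  diag_px <- sqrt(sum(pixelSpacing(fr)^2))
  expect_lte(abs(mit - truth$mitral_mm), max(2 * diag_px, 0.01 * truth$mitral_mm))
  expect_equal(unname(res$areas["LV"]), truth$lv_area_mm2)

  # mask lacking RA: tricuspid and atrial septum absent, mitral present
  g <- maskGrid(fr)
  g[g == defaultLabelMap()[["RA"]]] <- 0L
  res2 <- measureFrame(LabelMask(g, pixelSpacing(fr)))
  expect_setequal(res2$measurements$name,
                  c("mitral_annulus", "interventricular_septum"))
  expect_false("RA" %in% names(res2$areas))

  expect_error(measureFrame(LabelMask(matrix(0L, 5, 5), c(1, 1))),
               "no chambers")
})

test_that("geometric invariances hold on phantom frames", {
  base <- phantomParams(nFrames = 1L, seed = 9L)
  m0 <- getFrame(generatePhantomSeries(base)$series, 0)
  res0 <- measureFrame(m0, orientationQC = FALSE)
  get <- function(res) {
    v <- res$measurements$length_mm
    names(v) <- res$measurements$name
    v[sort(names(v))]
  }
  v0 <- get(res0)

  # translation: pad by 7 rows / 5 cols of background
  g <- maskGrid(m0)
  gt <- matrix(0L, nrow(g) + 7, ncol(g) + 5)
  gt[8:(nrow(g) + 7), 6:(ncol(g) + 5)] <- g
  expect_equal(get(measureFrame(LabelMask(gt, c(1, 1)),
                                orientationQC = FALSE)), v0)

  # 90-degree rotations: lengths exactly unchanged under isotropic spacing
  for (rot in c(90L, 180L, 270L)) {
    pr <- base; pr$rotation <- rot
    mr <- getFrame(generatePhantomSeries(pr)$series, 0)
    expect_equal(get(measureFrame(mr, orientationQC = FALSE)), v0,
                 label = paste("rotation", rot))
  }

  # spacing linearity: scaling spacing by s scales lengths by s, areas by s^2
  s <- 1.7
  ms <- LabelMask(maskGrid(m0), pixelSpacing(m0) * s)
  ress <- measureFrame(ms, orientationQC = FALSE)
  expect_equal(get(ress), v0 * s)
  expect_equal(sort(ress$areas), sort(res0$areas * s^2))

  # left-right mirror with label swap: mitral and tricuspid swap names,
  # values unchanged
  lm0 <- defaultLabelMap()
  gm <- maskGrid(m0)[, ncol(maskGrid(m0)):1]
  swap <- gm
  swap[gm == lm0[["LV"]]] <- lm0[["RV"]]; swap[gm == lm0[["RV"]]] <- lm0[["LV"]]
  swap[gm == lm0[["LA"]]] <- lm0[["RA"]]; swap[gm == lm0[["RA"]]] <- lm0[["LA"]]
  vm <- get(measureFrame(LabelMask(swap, pixelSpacing(m0)),
                         orientationQC = FALSE))
  expect_equal(vm[["mitral_annulus"]], v0[["tricuspid_annulus"]])
  expect_equal(vm[["tricuspid_annulus"]], v0[["mitral_annulus"]])
})

test_that("interface endpoints equal exhaustive search on random blobs", {
  for (seed in 1:6) {
    fg <- randomBlob(40, 40, 120, seed = seed)
    lm0 <- defaultLabelMap()
    g <- matrix(0L, 40, 40)
    g[fg] <- lm0[["LA"]]
    g[31:40, ] <- 0L
    g[28:40, 3:38] <- lm0[["LV"]]
    m <- LabelMask(g, c(1, 0.8))
    iface <- tryCatch(avInterface(m, "LA", "LV"), error = function(e) NULL)
    if (is.null(iface)) next
    ref <- bruteFarthestPair(interfacePixels(iface), pixelSpacing(m))
    ep <- interfaceEndpoints(iface)
    d <- sqrt(sum(((ep[1, ] - ep[2, ]) * pixelSpacing(m))^2))
    expect_equal(d, ref$d, label = paste("blob seed", seed))
    expect_equal(unname(rbind(ref$p1, ref$p2)), unname(ep),
                 label = paste("blob seed", seed))
  }
})
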