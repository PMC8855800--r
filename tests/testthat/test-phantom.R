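test_that("phantom generation is deterministic and truth-consistent", {
  p <- phantomParams(seed = 13L, boundaryNoiseSd = 0.5)
  a <- generatePhantomSeries(p)
  b <- generatePhantomSeries(p)
  expect_identical(lapply(frames(a$series), maskGrid),
                   lapply(frames(b$series), maskGrid))
  expect_identical(a$truth$perFrame, b$truth$perFrame)

  # truth areas equal labeled-pixel counts x spacing product (noise-free)
  pn <- phantomParams(seed = 13L)
  ph <- generatePhantomSeries(pn)
  sp <- pixelSpacing(ph$series)
  for (t in c(0L, 7L, 15L)) {
    g <- maskGrid(getFrame(ph$series, t))
    tr <- ph$truth$perFrame[t + 1L, ]
    expect_equal(sum(g == defaultLabelMap()[["LV"]]) * sp[1] * sp[2],
                 tr$lv_area_mm2)
    expect_equal(sum(g == defaultLabelMap()[["RA"]]) * sp[1] * sp[2],
                 tr$ra_area_mm2)
  }
})

test_that("default phantoms put the larger annulus at LV-area minimum", {
  ph <- generatePhantomSeries(phantomParams(seed = 4L))
  tr <- ph$truth$perFrame
  expect_gt(tr$mitral_mm[which.min(tr$lv_area_mm2)],
            tr$mitral_mm[which.max(tr$lv_area_mm2)])
})

test_that("static single-frame phantom equals the configured means", {
  ph <- generatePhantomSeries(phantomParams(
    nFrames = 1L, mitralAmp = 0, tricuspidAmp = 0, lvAreaAmp = 0,
    rvAreaAmp = 0, laAreaAmp = 0, raAreaAmp = 0, seed = 1L))
  tr <- ph$truth$perFrame
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$mitral_mm, 32)
  expect_equal(tr$tricuspid_mm, 33)
})

test_that("phantom truth matches brute-force measurement on noise-free frames", {
  for (seed in c(3L, 17L)) {
    ph <- generatePhantomSeries(phantomParams(seed = seed, nFrames = 4L))
    sp <- pixelSpacing(ph$series)
    diag_px <- sqrt(sum(sp^2))
    for (t in 0:3) {
      m <- getFrame(ph$series, t)
      iface <- avInterface(m, "LA", "LV")
      ref <- bruteFarthestPair(interfacePixels(iface), sp)
      expect_lte(abs(ref$d - ph$truth$perFrame$mitral_mm[t + 1L]), diag_px)
    }
  }
})

test_that("infeasible phantom geometry is rejected", {
  expect_error(generatePhantomSeries(phantomParams(gridShape = c(40L, 40L))),
               "infeasible")
})

test_that("perturbMask is seeded, band-limited, and identity at sd 0", {
  ph <- generatePhantomSeries(phantomParams(nFrames = 1L, seed = 6L))
  m <- getFrame(ph$series, 0)
  expect_identical(maskGrid(perturbMask(m, 0)), maskGrid(m))

  a <- perturbMask(m, 1.0, seed = 99L)
  b <- perturbMask(m, 1.0, seed = 99L)
  expect_identical(maskGrid(a), maskGrid(b))
  expect_false(identical(maskGrid(a), maskGrid(m)))

  # distance-transform oracle: pixels beyond the +/- ceil(2 sd) band from
  # every label boundary are unchanged
  sd <- 1.0
  band <- ceiling(2 * sd)
  g <- maskGrid(m)
  changed <- which(maskGrid(a) != g, arr.ind = TRUE)
  bnd <- which(vapply(seq_len(nrow(g) * ncol(g)), function(i) {
    r <- (i - 1) %% nrow(g) + 1; c <- (i - 1) %/% nrow(g) + 1
    nb <- g[max(1, r - 1):min(nrow(g), r + 1),
            max(1, c - 1):min(ncol(g), c + 1)]
    any(nb != g[r, c])
  }, logical(1)))
  bc <- cbind((bnd - 1) %% nrow(g) + 1, (bnd - 1) %/% nrow(g) + 1)
  for (i in seq_len(nrow(changed))) {
    dmin <- min(pmax(abs(bc[, 1] - changed[i, 1]),
                     abs(bc[, 2] - changed[i, 2])))
    expect_lte(dmin, band)
  }
})

test_that("generateCohort seeds, injects outliers, and encodes bias", {
  a <- generateCohort(200, seed = 5L)
  b <- generateCohort(200, seed = 5L)
  expect_identical(a$records, b$records)
  expect_true(all(a$records$bsa > 0))

  # outlier_fraction 0.05, n = 1000: downstream k = 3 flagging finds them
  # in binomial-tolerance numbers
  co <- generateCohort(1000, outlierFraction = 0.05, seed = 8L)
  fl <- zscoreFlags(co$records$mitral_systole_mm, k = 3)
  n_inj <- sum(co$records$injected_outlier)
  expect_lt(abs(n_inj - 50), 4 * sqrt(1000 * 0.05 * 0.95))
  # all injected gross outliers are flagged; few clean subjects are
  expect_true(all(fl$excluded[co$records$injected_outlier]))
  expect_lt(sum(fl$excluded & !co$records$injected_outlier), 10)

  # bias b = 0.023 with zero noise: mean percentage difference is exactly b
  cb <- generateCohort(500, manualPairs = TRUE, nManual = 100,
                       manualBias = 0.023, manualNoiseSd = 0, seed = 9L)
  expect_equal(nrow(cb$pairs), 100L)
  rep <- compareToManual(cb$pairs$auto_mm, cb$pairs$manual_mm)
  expect_equal(rep$mean_pct_diff, 0.023, tolerance = 1e-12)
})

test_that("writePhantom writes frames, truth, and a DICOM spacing stub", {
  dir <- file.path(tempdir(), "ph_out")
  unlink(dir, recursive = TRUE)
  p <- phantomParams(nFrames = 3L, seed = 2L)
  ph <- writePhantom(dir, p, format = "png")
  expect_length(list.files(dir, pattern = "frame\\d+\\.png"), 3L)
  tr <- read.csv(file.path(dir, "truth.csv"))
  expect_equal(tr$mitral_mm, ph$truth$perFrame$mitral_mm)
  expect_equal(spacingFromDicom(file.path(dir, "metadata.dcm")),
               pixelSpacing(ph$series))
  # round trip through the files reproduces the masks bit-identically
  s2 <- readCineSeries(dir, spacing = pixelSpacing(ph$series))
  expect_identical(lapply(frames(s2), maskGrid),
                   lapply(frames(ph$series), maskGrid))
})
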