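#' Phantom generator parameters
#'
#' Parameters of the synthetic 4-chamber cine phantom. Chambers are
#' rasterized axis-aligned rectangles in 4-chamber topology — atria above,
#' ventricles below, the LA-LV and RA-RV pairs abutting along straight
#' horizontal annular segments and the LV-RV / LA-RA pairs along vertical
#' septal segments — so every interface length is exactly controllable.
#' Chamber sizes and annular diameters follow sinusoids over the cycle.
#' Defaults emulate an adult 4-chamber acquisition: mitral 32 +/- 3 mm and
#' tricuspid 33 +/- 3 mm (so systolic diameters exceed diastolic ones), LV
#' area 3200 +/- 800 mm^2 maximal at frame 0 (cine cycles start at
#' end-diastole), atrial areas counter-phased with the ventricles, 20 frames
#' per cycle, 1 mm/px on a 224 x 224 grid.
#'
#' @param gridShape integer length-2 (rows, cols) in px.
#' @param spacing numeric length-2 (row, col) mm/px.
#' @param nFrames frames per cardiac cycle (>= 1).
#' @param mitralMean,mitralAmp mean and cyclic amplitude of the mitral
#'   annular diameter, mm.
#' @param tricuspidMean,tricuspidAmp tricuspid analogues, mm.
#' @param lvAreaMean,lvAreaAmp,rvAreaMean,rvAreaAmp ventricular area
#'   sinusoids, mm^2 (maximal at frame 0).
#' @param laAreaMean,laAreaAmp,raAreaMean,raAreaAmp atrial area sinusoids,
#'   mm^2 (counter-phased: maximal at ventricular end-systole).
#' @param phaseOffset phase (radians) of the annular cycle relative to the
#'   ventricular area cycle; the default pi makes the annulus largest when
#'   the LV area is smallest, i.e. systolic measurements exceed diastolic.
#' @param boundaryNoiseSd segmentation-jitter SD in px applied by
#'   [perturbMask()] to every frame (0 = noise-free).
#' @param rotation global rotation of the generated frames, one of
#'   0, 90, 180, 270 degrees.
#' @param labelMap chamber label encoding.
#' @param seed integer seed making the series fully reproducible.
#' @return list of class \code{phantomParams}.
#' @seealso [generatePhantomSeries()]
#' @export
phantomParams <- function(gridShape = c(224L, 224L), spacing = c(1, 1),
                          nFrames = 20L,
                          mitralMean = 32, mitralAmp = 3,
                          tricuspidMean = 33, tricuspidAmp = 3,
                          lvAreaMean = 3200, lvAreaAmp = 800,
                          rvAreaMean = 3000, rvAreaAmp = 700,
                          laAreaMean = 2000, laAreaAmp = 500,
                          raAreaMean = 1800, raAreaAmp = 450,
                          phaseOffset = pi, boundaryNoiseSd = 0,
                          rotation = 0L, labelMap = defaultLabelMap(),
                          seed = 1L) {
  p <- list(gridShape = as.integer(gridShape), spacing = as.numeric(spacing),
            nFrames = as.integer(nFrames),
            mitralMean = mitralMean, mitralAmp = mitralAmp,
            tricuspidMean = tricuspidMean, tricuspidAmp = tricuspidAmp,
            lvAreaMean = lvAreaMean, lvAreaAmp = lvAreaAmp,
            rvAreaMean = rvAreaMean, rvAreaAmp = rvAreaAmp,
            laAreaMean = laAreaMean, laAreaAmp = laAreaAmp,
            raAreaMean = raAreaMean, raAreaAmp = raAreaAmp,
            phaseOffset = phaseOffset, boundaryNoiseSd = boundaryNoiseSd,
            rotation = as.integer(rotation), labelMap = labelMap,
            seed = as.integer(seed))
  stopifnot(p$nFrames >= 1L, p$boundaryNoiseSd >= 0,
            p$mitralAmp >= 0, p$tricuspidAmp >= 0,
            all(p$spacing > 0), p$rotation %in% c(0L, 90L, 180L, 270L),
            p$mitralAmp < p$mitralMean, p$tricuspidAmp < p$tricuspidMean)
  class(p) <- "phantomParams"
  p
}

# Sinusoidal generating functions sampled at frame t (0-based).
.phantomSignals <- function(p, t) {
  th <- 2 * pi * t / p$nFrames
  list(
    mitral = p$mitralMean + p$mitralAmp * cos(th + p$phaseOffset),
    tricuspid = p$tricuspidMean + p$tricuspidAmp * cos(th + p$phaseOffset),
    lvArea = p$lvAreaMean + p$lvAreaAmp * cos(th),
    rvArea = p$rvAreaMean + p$rvAreaAmp * cos(th),
    laArea = p$laAreaMean - p$laAreaAmp * cos(th),
    raArea = p$raAreaMean - p$raAreaAmp * cos(th))
}

.rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])

#' Generate a synthetic 4-chamber cine series with exact ground truth
#'
#' Builds \code{nFrames} label masks per [phantomParams()] and the matching
#' per-frame ground truth. Annular-diameter truth is the continuous
#' generating sinusoid; chamber-area truth is the rasterized pixel count
#' times the spacing product (exact on noise-free frames); septal truth is
#' the analytic arc length of the straight rasterized band. Identical
#' parameters and seed give bit-identical output.
#'
#' @param params a [phantomParams()] list.
#' @param subjectId subject identifier for the series.
#' @return list with \code{series} (a \linkS4class{CineSeries}) and
#'   \code{truth} (list: \code{perFrame} data.frame, \code{params},
#'   \code{seed}).
#' @export
generatePhantomSeries <- function(params = phantomParams(),
                                  subjectId = "phantom") {
  p <- params
  R <- p$gridShape[1]; C <- p$gridShape[2]
  sr <- p$spacing[1]; sc <- p$spacing[2]
  cmid <- as.integer(round(C * 0.5))
  rav <- as.integer(round(R * 0.45))
  padPx <- max(2L, as.integer(round(8 / sc)))
  oldseed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(p$seed)
  on.exit(if (!is.null(oldseed))
    assign(".Random.seed", oldseed, envir = globalenv()))

  frames <- vector("list", p$nFrames)
  tf <- vector("list", p$nFrames)
  for (t in seq_len(p$nFrames) - 1L) {
    sig <- .phantomSignals(p, t)
    wLA <- max(2L, as.integer(round(sig$mitral / sc)))
    wRA <- max(2L, as.integer(round(sig$tricuspid / sc)))
    wLV <- wLA + padPx
    wRV <- wRA + padPx
    hpx <- function(area, w) max(2L, as.integer(round(area / (w * sc) / sr)))
    hLV <- hpx(sig$lvArea, wLV); hRV <- hpx(sig$rvArea, wRV)
    hLA <- hpx(sig$laArea, wLA); hRA <- hpx(sig$raArea, wRA)
    if (rav - max(hLA, hRA) < 2L || rav + max(hLV, hRV) - 1L > R - 1L ||
        cmid - max(wLA, wLV) + 1L < 2L || cmid + max(wRA, wRV) > C - 1L)
      stop("phantom geometry infeasible for grid size ", R, "x", C)
    g <- matrix(0L, R, C)
    lmap <- p$labelMap
    g[(rav - hLA):(rav - 1L), (cmid - wLA + 1L):cmid] <- lmap[["LA"]]
    g[(rav - hRA):(rav - 1L), (cmid + 1L):(cmid + wRA)] <- lmap[["RA"]]
    g[rav:(rav + hLV - 1L), (cmid - wLV + 1L):cmid] <- lmap[["LV"]]
    g[rav:(rav + hRV - 1L), (cmid + 1L):(cmid + wRV)] <- lmap[["RV"]]
    sp <- p$spacing
    if (p$rotation != 0L) {
      for (k in seq_len(p$rotation / 90L)) g <- .rot90cw(g)
      if (p$rotation %in% c(90L, 270L)) sp <- rev(sp)
    }
    m <- LabelMask(g, spacing = sp, labelMap = p$labelMap, frameIndex = t)
    if (p$boundaryNoiseSd > 0)
      m <- perturbMask(m, p$boundaryNoiseSd, seed = NULL)
    frames[[t + 1L]] <- m
    tf[[t + 1L]] <- data.frame(
      frame_index = t,
      mitral_mm = sig$mitral, tricuspid_mm = sig$tricuspid,
      ivs_mm = (min(hLV, hRV) - 1L) * sr,
      as_mm = (min(hLA, hRA) - 1L) * sr,
      lv_area_mm2 = hLV * wLV * sr * sc,
      rv_area_mm2 = hRV * wRV * sr * sc,
      la_area_mm2 = hLA * wLA * sr * sc,
      ra_area_mm2 = hRA * wRA * sr * sc)
  }
  list(series = CineSeries(frames, subjectId = subjectId),
       truth = list(perFrame = do.call(rbind, tf), params = p,
                    seed = p$seed))
}

#' Perturb a mask with boundary segmentation jitter
#'
#' Emulates segmentation noise: pixels within a band of +/- ceiling(2 * sd)
#' px (Chebyshev) around chamber boundaries toggle, with probability
#' \code{2 * (1 - pnorm(d / sd))} at band distance d, to the most frequent
#' differing label among their 8 neighbours (ties to the smallest code).
#' Interior pixels and background far from every boundary are untouched.
#' Fully determined by (mask, sd, seed); \code{sd = 0} is the identity.
#'
#' @param mask a \linkS4class{LabelMask}.
#' @param sd boundary noise SD in px (>= 0).
#' @param seed integer seed, or NULL to draw from the current RNG stream.
#' @return The perturbed \linkS4class{LabelMask}.
#' @export
perturbMask <- function(mask, sd, seed = NULL) {
  stopifnot(is(mask, "LabelMask"), sd >= 0)
  if (sd == 0) return(mask)
  if (!is.null(seed)) {
    oldseed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit(if (!is.null(oldseed))
      assign(".Random.seed", oldseed, envir = globalenv()))
  }
  g <- mask@grid
  nr <- nrow(g); nc <- ncol(g)
  # boundary seed: pixels with a differing 8-neighbour
  diffn <- matrix(FALSE, nr, nc)
  shifts <- expand.grid(dr = -1:1, dc = -1:1)
  shifts <- shifts[!(shifts$dr == 0 & shifts$dc == 0), ]
  for (s in seq_len(nrow(shifts))) {
    dr <- shifts$dr[s]; dc <- shifts$dc[s]
    r1 <- max(1, 1 + dr):min(nr, nr + dr)
    r0 <- r1 - dr
    c1 <- max(1, 1 + dc):min(nc, nc + dc)
    c0 <- c1 - dc
    diffn[r0, c0] <- diffn[r0, c0] | (g[r0, c0] != g[r1, c1])
  }
  band <- as.integer(ceiling(2 * sd))
  dist <- matrix(Inf, nr, nc)
  cur <- diffn
  for (d in seq_len(band)) {
    dist[cur & !is.finite(dist)] <- d
    cur <- .dilateCheb(cur, 1L)
  }
  inband <- is.finite(dist)
  idx <- which(inband)
  prob <- 2 * (1 - pnorm(dist[idx] / sd))
  toggle <- idx[runif(length(idx)) < prob]
  if (length(toggle)) {
    coords <- arrayInd(toggle, dim(g))
    newval <- integer(length(toggle))
    for (i in seq_along(toggle)) {
      r <- coords[i, 1]; cc <- coords[i, 2]
      nbv <- g[max(1, r - 1):min(nr, r + 1), max(1, cc - 1):min(nc, cc + 1)]
      nbv <- nbv[nbv != g[r, cc]]
      if (!length(nbv)) { newval[i] <- g[r, cc]; next }
      tab <- table(nbv)
      best <- names(tab)[tab == max(tab)]
      newval[i] <- as.integer(min(as.integer(best)))
    }
    g[toggle] <- newval
  }
  out <- mask
  out@grid <- g
  out
}

#' Simulate a measurement cohort with optional outliers and manual pairs
#'
#' Draws per-subject systolic and diastolic mitral diameters from normal
#' distributions, injects a fraction of gross outliers (shifted by at least
#' 6 SD), and draws anthropometric covariates (age, sex, height, weight,
#' hence BSA) at values typical of an adult imaging cohort. Optionally emits
#' paired "manual" measurements as \code{auto / (1 + bias)} with
#' multiplicative noise, so that [compareToManual()] recovers \code{bias}
#' exactly in the noise-free case. Fully determined by the seed.
#'
#' @param nSubjects number of subjects (>= 2).
#' @param systoleMean,systoleSd,diastoleMean,diastoleSd diameter
#'   distributions in mm (defaults 35 +/- 3 systole, 29 +/- 3 diastole:
#'   systolic larger, matching the measured population ordering).
#' @param outlierFraction fraction of subjects whose diameters are replaced
#'   by gross outliers (>= 6 SD away).
#' @param manualPairs also emit automated/manual pairs for \code{nManual}
#'   subjects.
#' @param nManual number of manual-annotation pairs (default 100).
#' @param manualBias multiplicative bias b: manual = auto / (1 + b).
#' @param manualNoiseSd SD of the multiplicative manual noise.
#' @param seed integer seed.
#' @return list with \code{records} (one row per subject) and \code{pairs}
#'   (NULL unless \code{manualPairs}).
#' @export
generateCohort <- function(nSubjects, systoleMean = 35, systoleSd = 3,
                           diastoleMean = 29, diastoleSd = 3,
                           outlierFraction = 0, manualPairs = FALSE,
                           nManual = 100L, manualBias = 0,
                           manualNoiseSd = 0, seed = 1L) {
  stopifnot(nSubjects >= 2L, systoleSd > 0, diastoleSd > 0,
            outlierFraction >= 0, outlierFraction <= 1)
  oldseed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(oldseed))
    assign(".Random.seed", oldseed, envir = globalenv()))
  sys_mm <- rnorm(nSubjects, systoleMean, systoleSd)
  dia_mm <- rnorm(nSubjects, diastoleMean, diastoleSd)
  n_out <- rbinom(1, nSubjects, outlierFraction)
  is_outlier <- rep(FALSE, nSubjects)
  if (n_out > 0) {
    pick <- sample.int(nSubjects, n_out)
    is_outlier[pick] <- TRUE
    sgn <- sample(c(-1, 1), n_out, replace = TRUE)
    mag <- 6 + runif(n_out, 0, 2)
    sys_mm[pick] <- systoleMean + sgn * mag * systoleSd
    dia_mm[pick] <- diastoleMean + sgn * mag * diastoleSd
  }
  sex <- rbinom(nSubjects, 1, 0.5)
  age <- round(rnorm(nSubjects, 64, 7.5), 1)
  height <- round(ifelse(sex == 1, rnorm(nSubjects, 176, 7),
                         rnorm(nSubjects, 163, 6)), 1)
  weight <- round(ifelse(sex == 1, rnorm(nSubjects, 84, 12),
                         rnorm(nSubjects, 70, 11)), 1)
  height <- pmax(height, 120); weight <- pmax(weight, 35)
  records <- data.frame(
    subject_id = sprintf("S%05d", seq_len(nSubjects)),
    mitral_systole_mm = sys_mm, mitral_diastole_mm = dia_mm,
    age = age, sex = sex, height = height, weight = weight,
    bsa = bsa(height, weight), injected_outlier = is_outlier,
    stringsAsFactors = FALSE)
  pairs <- NULL
  if (manualPairs) {
    nManual <- min(nManual, nSubjects)
    pick <- sample.int(nSubjects, nManual)
    phase <- sample(c("systole", "diastole"), nManual, replace = TRUE)
    auto <- ifelse(phase == "systole", sys_mm[pick], dia_mm[pick])
    manual <- auto / (1 + manualBias)
    if (manualNoiseSd > 0)
      manual <- manual * (1 + rnorm(nManual, 0, manualNoiseSd))
    pairs <- data.frame(
      subject_id = records$subject_id[pick], phase = phase,
      auto_mm = auto, manual_mm = manual,
      age = age[pick], bsa = records$bsa[pick], sex = sex[pick],
      plane_deviation = rnorm(nManual), stringsAsFactors = FALSE)
  }
  list(records = records, pairs = pairs)
}

#' Write a phantom series to disk
#'
#' Writes one mask file per frame (PNG, NIfTI, or text grid), a
#' \code{truth.csv} ground-truth table, and optionally a synthetic DICOM
#' metadata stub carrying the PixelSpacing.
#'
#' @param dir destination directory (created if needed).
#' @param params a [phantomParams()] list.
#' @param format "png", "nii", or "txt".
#' @param dicomStub also write \code{metadata.dcm} with the spacing.
#' @param subjectId subject identifier.
#' @return the phantom list from [generatePhantomSeries()], invisibly.
#' @export
writePhantom <- function(dir, params = phantomParams(), format = "png",
                         dicomStub = TRUE, subjectId = basename(dir)) {
  ph <- generatePhantomSeries(params, subjectId = subjectId)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (f in frames(ph$series)) {
    writeMask(f, file.path(dir, sprintf("frame%03d.%s", f@frameIndex, format)))
  }
  write.csv(ph$truth$perFrame, file.path(dir, "truth.csv"), row.names = FALSE)
  if (dicomStub)
    writeDicomStub(file.path(dir, "metadata.dcm"),
                   spacing = pixelSpacing(ph$series))
  invisible(ph)
}
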