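# cineMorph

Automated morphometry of the atrioventricular valve annuli from 4-chamber
cine cardiac-MRI segmentation masks.

## What it does and for whom

Population imaging studies segment the four cardiac chambers (LV, LA, RV,
RA) on the 4-chamber cine view at scale, but the segmentation masks are not
yet phenotypes. `cineMorph` turns per-frame chamber label masks into linear
anatomical measurements suitable for downstream epidemiology and genetic
association analyses:

- **mitral annulus diameter** (LA–LV junction) and **tricuspid annulus
  diameter** (RA–RV junction),
- **interventricular** and **atrial septal lengths**,
- per-chamber **areas**, used to select the **end-systolic** and
  **end-diastolic** frames of the cine cycle.

It is aimed at researchers extracting imaging-derived phenotypes from
biobank-scale cine acquisitions, and at anyone validating such a pipeline:
a built-in phantom generator produces synthetic 4-chamber cine series with
exact ground truth, so the whole measurement chain is testable without any
patient data.

## The measurement model

For a frame with label grid *M* and pixel spacing *(s_r, s_c)* mm/px:

1. **Cleaning** — per chamber, keep the largest 8-connected component and
   fill enclosed background holes.
2. **Chamber long axis** — skeletonize each chamber (Zhang–Suen thinning),
   take the longest geodesic path on the skeleton (double farthest-point
   BFS), and extend it to the chamber boundary. The path endpoint nearer the
   paired chamber across the valve is the **base**, the other the **apex**
   (used for orientation QC).
3. **Annulus localization** — the interface between an atrium and its
   ventricle is the set of pixels of either chamber within a Chebyshev
   adjacency radius (default 1 px) of the other. The **annular diameter** is
   the chord between the two interface pixels at maximal mm-scaled distance:
   `d = sqrt((Δrow·s_r)² + (Δcol·s_c)²)`.
4. **Septal lengths** — arc length along one side of the LV–RV (or LA–RA)
   interface, chained pixel to pixel.
5. **Phase selection** — end-diastole = frame of maximal LV area,
   end-systole = frame of minimal LV area (2D areas stand in for volume
   estimates; LA fallback with inverted mapping when the LV is unusable).
6. **QC and validation** — z-score outlier exclusion per measure
   (|z| > k, default k = 3, sample SD), Mosteller BSA
   `√(height·weight/3600)`, and an automated-vs-manual error model: mean
   difference, mean percentage difference `(auto − manual)/manual`, and OLS
   of the percentage difference on age, BSA, sex, imaging-plane deviation
   and cardiac phase.

## Worked example

```r
library(cineMorph)

ph  <- generatePhantomSeries(phantomParams(seed = 7))   # 20-frame phantom
res <- measureAtPhases(ph$series)                       # select + measure
res$measurements[, c("name", "frame_index", "phase", "length_mm")]
```

```
                     name frame_index    phase length_mm
1          mitral_annulus          10  systole  35.01428
2       tricuspid_annulus          10  systole  36.01389
3 interventricular_septum          10  systole  50.00000
4           atrial_septum          10  systole  60.00000
5          mitral_annulus           0 diastole  29.01724
6       tricuspid_annulus           0 diastole  30.01666
7 interventricular_septum           0 diastole  95.00000
8           atrial_septum           0 diastole  43.00000
```

The phantom's generating mitral diameter is 35 mm at end-systole (frame 10,
the LV-area minimum) and 29 mm at end-diastole (frame 0): the pipeline
recovers both to within a fraction of a pixel, and reproduces the expected
ordering — the mitral annulus is larger in systole than in diastole.
Ground truth for every frame is in `ph$truth$perFrame`.

Batch runs over directories of mask files (PNG / NIfTI / text grids, one
subdirectory per subject, spacing from a flag or from DICOM PixelSpacing)
go through `runMeasure()` or the CLI:

```sh
Rscript inst/cli/cinemorph.R phantom --out ph1 --seed 3 --n-frames 6
Rscript inst/cli/cinemorph.R measure --masks . --spacing 1,1 --out meas
Rscript inst/cli/cinemorph.R qc --measurements meas/measurements.csv --out qc
```

## Acceptance script

`scripts/acceptance.R` regenerates the accuracy benchmark from scratch: it
builds 100 seeded phantoms (mean mitral diameters uniform in 25–40 mm,
0.5 mm/px spacing, boundary segmentation noise of SD 0.5 px, 20 frames per
cycle), runs the full pipeline (cleaning, interface detection, phase
selection), and scores the phase-selected diastolic mitral diameter against
the exact generating truth. It writes the mean relative error (%) and mean
absolute error (mm) as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
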