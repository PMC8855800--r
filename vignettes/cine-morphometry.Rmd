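---
title: "Annulus morphometry from 4-chamber cine masks: methods and design"
author: "cineMorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annulus morphometry from 4-chamber cine masks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cineMorph)
```

## The problem

Deep-learning segmentation of the 4-chamber cine view yields, per frame, an
integer label mask of the left ventricle (LV), left atrium (LA), right
ventricle (RV) and right atrium (RA). Clinically meaningful phenotypes —
the mitral and tricuspid annular diameters, septal lengths, chamber areas —
still have to be *measured* from those masks, frame by frame, and anchored
to a consistent point of the cardiac cycle. `cineMorph` implements that
measuring function, the cycle-phase selection, the pixel-to-millimetre
conversion, and the quality-control and validation statistics around it.

This vignette explains the model and its assumptions, the tunable
parameters, what the synthetic phantom generator does and does not emulate,
and the numerical choices made where the design was genuinely open.

## The measuring function

### Cleaning

Segmentation output can contain satellite islands and interior holes.
`cleanMask()` retains, per chamber label, only the largest 8-connected
component, and assigns fully enclosed background holes to the enclosing
chamber. The pass is idempotent and label-local: it never relabels one
chamber's pixels to another chamber.

### Chamber long axis, base and apex

`medialAxisPath()` skeletonizes the chamber's binary region with
Zhang–Suen thinning (which preserves 8-connectivity) and extracts the
longest geodesic path on the skeleton's adjacency graph by the standard
double farthest-point BFS sweep, ties broken lexicographically.

One numerical subtlety: iterative thinning erodes a region uniformly, so
the skeleton of a blocky region stops about half the local width short of
the boundary. The long-axis endpoints would then sit mid-chamber rather
than at the chamber's extremities. The path is therefore *extended to the
boundary*: from each end, the path greedily steps to the in-region
neighbour that most increases the Euclidean distance from the opposite end,
until no step increases it. The distance strictly increases at each step,
so the extension terminates; the result stays inside the region and remains
8-connected.

`classifyBaseApex()` designates, of the two path endpoints, the one nearer
(mm-scaled Euclidean distance) to the paired chamber across the
atrioventricular valve as the **base**, the other as the **apex**. Exact
ties are resolved by row-major coordinate order and flagged.

### Annulus localization and diameter

The annulus of an atrioventricular valve lies where the atrium and the
ventricle meet. `avInterface()` defines that interface as the pixels
*carrying one of the two chamber labels* that lie within a Chebyshev
adjacency radius (default 1 px, i.e. 8-connectivity) of the other chamber's
region. Restricting the band to labeled pixels — rather than including
background positions near both chambers — keeps the interface within the
anatomy and makes the worked geometry exact.

The **annular diameter** is the chord between the two interface pixels at
maximal mm-scaled Euclidean distance,

$$ d = \sqrt{(\Delta r \cdot s_r)^2 + (\Delta c \cdot s_c)^2}, $$

with anisotropic spacing carried through per axis (never a mean spacing
times a pixel count; pixel lengths are only reported when spacing is
isotropic). The maximal pair is found over the convex hull of the interface
pixels; a brute-force all-pairs search is used as the independent oracle in
the test suite, and the two agree exactly on every tested interface. Ties
are broken by lexicographic coordinate order so results are deterministic.

The base/apex construct is used for orientation QC only: frames where an
atrial base point lies more than `adjacencyRadius + 2` px from its annular
interface are flagged, not altered. The interface chord is the diameter
because the interface is the construct from which a diameter can be read
directly; how the long-axis step and the interface step combine into one
number is otherwise underdetermined, and this package fixes the convention
explicitly.

### Septal lengths

A septum is curved, so its length is measured as an **arc length**, not an
endpoint chord (a chord would systematically underestimate). For abutting
chambers the radius-1 interface band is two pixels thick (one pixel on each
side), and chaining the full band would zig-zag across it. The septal path
is therefore taken along *one side* of the band — the pixels of the first
chamber of the pair (LV for LV–RV, LA for LA–RA) facing the second — and
chained by nearest-neighbour steps from one extremal endpoint, summing
mm-scaled step lengths. The one-side convention shifts the line by half a
pixel laterally and does not change its length for parallel interfaces; it
also makes the measurement exactly invariant under 90° rotations. If
chaining detects a gap larger than `2 × adjacencyRadius + 1` px the
interface is considered disconnected and the endpoint chord is returned,
flagged `chord_fallback`.

### Phase selection

`selectPhases()` takes end-diastole as the frame of maximal LV size and
end-systole as the frame of minimal LV size. Only single-slice 4-chamber
masks exist here, so the per-frame size estimate is the **2D chamber area**
(pixel count × s_r × s_c); this assumption is recorded in the output
(`size_estimate = "2d_area"`). If the LV is absent or degenerate (< 10 px)
in more than half the frames, the LA is used with the mapping inverted —
the atrium fills while the ventricle empties, so the largest LA marks
ventricular end-systole. Area ties resolve to the earliest frame and are
flagged.

### Units

All millimetre values come from the pixel spacing, supplied explicitly or
read from DICOM metadata (`spacingFromDicom()`, PixelSpacing tag
0028,0030, returned in the standard's (row, column) order, exactly as
stored). No other rescaling is applied anywhere.

## Quality control and validation

- **Outlier exclusion** (`zscoreFlags()`): z = (v − mean)/SD with the
  sample (n−1) SD; excluded iff |z| > k. The default multiplier is
  **k = 3**; a stricter **k = 2.5** is available as an explicit argument.
  Both appear in the literature for this kind of cleaning and the two
  conventions are deliberately exposed rather than silently merged. With
  SD = 0 nothing is excluded. Under normality, k = 3 removes ≈ 0.27 % of
  a large cohort; the test suite checks this against binomial tolerance.
- **Body surface area** (`bsa()`): Mosteller, √(height·weight/3600) m²,
  chosen for its ubiquity in cardiology; Du Bois is selectable. "BSA" is
  passed as a raw covariate — no further adjustment is defined here.
- **Automated-vs-manual comparison** (`compareToManual()`): mean
  difference (mm), mean percentage difference (auto − manual)/manual, and
  OLS of the percentage difference on the supplied covariates (age, BSA,
  sex, imaging-plane deviation, cardiac phase), intercept included.
  Rank-deficient designs are flagged and coefficients withheld rather than
  silently dropped.

## The phantom: a stated world

`generatePhantomSeries()` builds synthetic 4-chamber cine series with
analytically known truth. Chambers are axis-aligned rectangles in
4-chamber topology: atria above, ventricles below, LA–LV and RA–RV
abutting along straight horizontal annular segments, LV–RV and LA–RA along
vertical septal segments. Straight interfaces make chord and arc truth
coincide for the annuli, and every interface length is exactly
controllable. Anatomical realism is explicitly **not** the goal; exact
geometric ground truth is.

Defaults (chosen once, as a realistic adult 4-chamber acquisition):

| parameter | default | why |
|---|---|---|
| mitral diameter | 32 ± 3 mm sinusoid | adult population norms; systolic > diastolic |
| tricuspid diameter | 33 ± 3 mm sinusoid | slightly larger than mitral |
| LV area | 3200 ± 800 mm² | max at frame 0 (cine starts at end-diastole) |
| RV area | 3000 ± 700 mm² | in phase with LV |
| LA, RA areas | 2000 ± 500, 1800 ± 450 mm² | counter-phased (atria fill in systole) |
| annular phase offset | π | annulus largest at ventricular end-systole |
| frames / cycle | 20 | typical retained cine sampling |
| grid, spacing | 224 × 224 px, 1 mm/px | chambers fit with margin |

The annular phase relation (largest annulus at end-systole) is the
population ordering reported for measured diameters, built in as the
default generating convention. Truth bookkeeping is two-fold, by design:
annular-diameter truth is the *continuous* generating sinusoid (the
rasterized measurement must come within a pixel diagonal of it), while
chamber-area truth is the *rasterized* pixel count × spacing (exact
equality is asserted on noise-free frames). Septal truth is the analytic
length of the straight rasterized band.

`perturbMask()` emulates segmentation jitter: pixels within ±⌈2·sd⌉ px
(Chebyshev) of a label boundary toggle, with probability
2·(1 − Φ(d/sd)) at band distance d, to the most frequent differing label
among their 8 neighbours. Everything is determined by (mask, sd, seed);
sd = 0 is the identity.

What a green phantom suite does **not** establish: robustness to real
segmentation failure modes (merged chambers, missing walls, through-plane
motion, papillary muscles), to oblique or curved annular planes, or to
non-rectangular chamber shapes. The phantom validates the geometry engine
and the cycle logic, not the upstream segmentation.

The accuracy benchmark (`phantomAccuracySuite()`, also driven by
`scripts/acceptance.R`) draws 100 phantoms with mean mitral diameters
uniform in 25–40 mm at 0.5 mm/px with boundary noise SD 0.5 px, scales the
other chamber parameters proportionally (so small-annulus phantoms remain
anatomically coherent), and scores the phase-selected diastolic mitral
diameter against truth. The grid is enlarged to 416 × 224 px there: at
0.5 mm/px a small-diameter, large-area ventricle is tall, and the default
square grid cannot hold the worst-case geometry. The orientation-QC pass
is switched off in the bulk benchmark — it only adds flags, never changes
values — to keep the 100-phantom run around a minute on one CPU.

## Numerical choices and degenerate inputs

- Coordinates are (row, col), pixel-centre convention; 0-based frame
  indices; label codes default to LV = 1, LA = 2, RV = 3, RA = 4 and are
  fully configurable (the encoding is a convention, not a standard).
- Adjacency radius defaults to 1 px (8-connectivity); configurable.
- All tie-breaks (farthest pairs, BFS sweeps, base/apex distance ties,
  area ties) are lexicographic/earliest and therefore deterministic.
- Single-pixel chamber overlaps give a zero-length, `degenerate`-flagged
  measurement rather than an error, so batch runs don't abort; a skeleton
  that collapses to one pixel returns that pixel duplicated, flagged, with
  a warning.
- Missing chambers yield *absent* measurements, never zeros.
- Mask I/O supports integer PNG, uncompressed single-frame NIfTI-1 and
  whitespace text grids. TIFF is not supported (no reader available in the
  dependency set). DICOM files are read for metadata only.

## Known limitations

- 2D only: no multi-slice volumetry, no 3D (saddle-shaped) annulus
  reconstruction, no leaflet or valve-function assessment.
- The annular diameter is an in-plane chord; oblique imaging planes bias
  it in ways the phantom does not model (the plane-deviation covariate in
  the validation model exists precisely to detect such bias empirically).
- Phase selection assumes the cine covers one cycle and that 2D area is a
  monotone proxy for chamber volume at the extremes.
- The LA-fallback inversion (largest LA ≈ ventricular end-systole) is a
  physiological reading; against ECG-triggered ground truth it should be
  treated as approximate.
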