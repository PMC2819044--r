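---
title: "Morphometric grading of cervical epithelium: models and methods"
author: "cervimorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometric grading of cervical epithelium: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cervimorph)
```

## The measurement problem

Grading of cervical intraepithelial neoplasia (CIN 1–3 versus normal
epithelium) rests on a small number of visual criteria: how much of the
epithelium is occupied by compact, basaloid, undifferentiated cells; how
large nuclei are relative to their cytoplasm; and how densely the nuclei
stain. Inter-observer agreement on the middle grades is notoriously poor.
cervimorph implements a fully automatic morphometric pipeline that turns an
8-bit grayscale micrograph of the epithelium (with a region-of-interest
mask delineating basal lamina to surface) into six parameters, three
discriminant ratios and a single calibrated 0–100 *cervical score*.

The pipeline, in order:

1. **Segmentation.** Grey levels inside the ROI are linearly rescaled so the
   1st/99th percentiles map to 0/255, nuclei are thresholded (Otsu's
   criterion on ROI pixels, or a manual level), holes are filled, components
   below 30 px² are discarded, and components touching the image frame are
   suppressed so the mean nuclear area N is unbiased. Touching nuclei are
   *not* split: cluster splitting has no robust automatic solution, and the
   synthetic generator keeps nuclei separable instead.
2. **Zones of influence.** The ROI is partitioned by geodesic distance
   propagation from the nucleus pixels (multi-source BFS under the
   8-neighbour chessboard metric, restricted to the ROI). Each zone is the
   territory "influenced" by one nucleus and serves as its cytoplasm proxy;
   the mean zone area is V = A / count. Propagation rather than Euclidean
   Voronoi cells is essential when the epithelium is concave. Equidistant
   boundary (SKIZ) pixels go to the lower nucleus label, which keeps the
   partition exact and deterministic.
3. **Triangulation.** The geodesic center of each zone — the zone pixel
   minimising the maximum within-zone geodesic distance — feeds a Delaunay
   triangulation. Edges whose straight segment leaves the ROI are discarded
   as false neighbour relations across concavities. The mean edge length e
   is taken over unique edges by default (`edgeMode = "triangle"` counts
   shared edges once per triangle instead; on our synthetic material the two
   differ by under 2%).
4. **Differentiation.** The mean nuclear radius is r = round(sqrt(N/π)) and
   the dilation/erosion coefficient k = round(4·e / r), i.e. the mean
   inter-nuclear distance divided by a quarter of the nuclear radius. The
   nuclei mask is closed (dilation then erosion) with the chessboard ball of
   radius k, constrained to the ROI; holes are filled; components anchored
   to the basal side (touching the bottom 5 px of the ROI) form the
   differentiated compartment of area D. Compact basal nuclei merge into
   one slab because their gaps are below 2k; sparse upper nuclei stay
   isolated and are excluded by the basal-anchoring filter.
5. **Chromaticism.** The segmented nuclei are superimposed on the
   contrast-normalised image, the masked image is inverted, and its mean is
   taken over the ROI (Hst) and over the upper, non-differentiated region
   (HstU). Non-nucleus pixels contribute zero, so these are *integrated*
   staining measures: sparse or pale upper nuclei give a small HstU even
   when each individual nucleus is dark.
6. **Score.** Three ratios — N/V, DR = D/A and HstR = HstU/Hst — enter an
   affine score `w1·(N/V) + w2·DR + w3·(1 − HstR) + b`, clipped to
   [0, 120]; grades are assigned to the nearest calibrated reference score,
   ties upward (the clinically conservative direction).

## Key numerical and design choices

**Square structuring element.** The closing uses the (2k+1)×(2k+1) square
(chessboard ball), not a Euclidean disc. The choice is forced by the
worked-example arithmetic of the method: two 199 px (radius 8) discs with a
32 px border gap must merge under k = 16 and stay separate under k = 15.
With a Euclidean disc of radius 16 the dilated discs are exactly tangent —
a one-pixel neck that the erosion destroys — whereas the square element
produces a 33-row contact band that survives closing. Classical
mathematical-morphology systems implement "a dilation of size n" as n
iterations of the elementary structuring element, of which the square is
the natural 8-connected square-grid analogue. `fig2Scene()` reproduces this
geometry and the tests pin k = 15/16/30/31 behaviour exactly.

**ROI-constrained closing.** Outside-ROI area is treated as foreground
during erosion and the result is clipped back to the ROI. This keeps the
closing extensive (output ⊇ input within the ROI) and idempotent — both
asserted as properties on random masks — and lets the differentiated slab
attach cleanly to the basal boundary.

**Geodesic center ties.** Under the chessboard metric the set of
eccentricity minimisers of a zone is typically a cross-shaped plateau (in a
wide rectangle, the whole middle column). Ties are therefore broken by
maximal geodesic depth — the most interior minimiser — and only then by
smallest (row, col). A pure lexicographic rule would park centers on zone
edges and distort the triangulation. The implementation is an exact
branch-and-bound (BFS from directional extremes gives lower bounds,
candidates are verified until none can win) and is tested against an
exhaustive oracle on small zones, including concave L-shapes where the
Euclidean centroid falls outside the region.

**Delaunay triangulation.** No installed package provides one, so the
package carries a Bowyer–Watson implementation. Pixel-grid points are
heavily cocircular; a deterministic jitter of 10⁻⁶ px (a fixed function of
the point index) breaks the degeneracy inside the incircle tests only —
reported geometry and edge lengths use the unjittered coordinates. The
triangulation is validated against the empty-circumcircle property on
random point sets and against hand geometry.

**Calibration.** The shipped calibration fits the affine score on the
reference group-mean ratio triples against the reference scores 27 (normal),
51 (CIN 1), 78 (CIN 2), 100 (CIN 3). With four groups and four free
parameters the least-squares fit is exact, so the reference triples map
exactly onto their targets. Note the fitted weights are
`r round(defaultCalibration()@weights, 2)` with offset
`r round(defaultCalibration()@offset, 2)`: the chromaticism weight is
*negative*. This is a property of the reference data — HstR is nearly flat
between CIN 1 and CIN 2 and collapses only at CIN 3 — so the score is not
monotone in each ratio separately, only over the joint trajectory the four
groups trace. Users can substitute their own calibration via
`fitCalibration()`.

**Calibration constant.** The reference optics image 0.066 mm² onto a
472×608 frame, giving 0.066·10⁶/286 976 ≈ 0.230 µm²/px
(`defaultPixelArea()`). The value 0.22 is also quoted for this setup; the
computed quotient is the default and every entry point accepts an override.

## The synthetic epithelium generator

No clinical images are distributable with the package, so testing rests on
a seeded generator (`generateEpithelium()`) that emulates the *statistical
structure* of the four diagnostic groups, not their visual appearance. For
a group preset (`makePreset()`):

- The ROI is a rectangle inset 10 px from the frame, basal lamina at the
  bottom. The lower `differentiationFraction` (D/A of the group) of the ROI
  height is the dense basal band; the rest is the sparse upper band.
- The total nucleus count is A/V for the group's mean zone area V, so the
  tessellation stage recovers V by construction. The upper-band density is
  set by the closed-form budget `upperZoneArea = darkness·N/HstU`, which
  makes the measured integrated chromaticism land near the group's Hst and
  HstU; the remaining nuclei fill the basal band.
- Nucleus areas are drawn from Normal(N, sd) truncated at ±2 SD; nuclei are
  ellipses with axis ratio uniform in [0.7, 1] and random orientation, so
  the radius-from-area formula is exercised off its exact circular case.
- Placement uses Mitchell best-candidate (farthest-point) sampling with
  exact target counts. The basal band runs at packing fractions of
  0.5–0.6, beyond what plain dart-throwing with rejection can reach; the
  farthest-point rule approximates a blue-noise layout at any density. At
  render time a nucleus overlapping the 1-px dilation of already-rendered
  nuclei is shrunk in 7% steps (at most 10) or dropped, which guarantees
  that no two nuclei touch even diagonally — segmentation recovers the
  placed count exactly. The price is a small negative bias (≈ 2–8%,
  densest presets worst) in realized mean nucleus area, well inside the 10%
  recovery tolerance the tests assert.
- Upper nuclei stand off from the band boundary by one upper-zone pitch so
  the closing does not bridge them onto the basal slab.
- Basal-nucleus darkness is derived in closed form from the group's Hst and
  HstU budgets; upper darkness is fixed at 200 (inverted grey), background
  at grey 210, with additive Gaussian noise of σ = 4 grey levels clipped to
  [0, 255] — enough to make thresholding non-trivial without defeating it.
- Identical (preset, seed, width, height) reproduce the raster bit for bit;
  the generator uses a private RNG stream and restores the caller's seed.

What the generator does *not* emulate: staining chemistry, koilocytotic
halos, stromal tissue, nuclear clustering/overlap, folds, or acquisition
artifacts. Passing recovery tests on this material shows the measurement
chain is correct and well-calibrated; it does not certify performance on
clinical images, where segmentation quality (especially overlapping nuclei
in high-grade lesions) dominates.

## Problem sizes and degenerate inputs

The test-suite and the reproduction script analyse 10 images per group at
the native 608×472 geometry — the study size of the reference material —
which keeps a full four-group batch around a minute on one CPU. Degenerate
inputs are defined, not fatal: a constant ROI passes preprocessing
unchanged with a warning; an image with no surviving nuclei yields
NA-valued features and no grade; collinear zone centers yield a flagged
chain of edges; zero variance in both Welch groups gives p = 1 (equal
means) or 0; the Welch correction is applied unconditionally, which removes
a data-dependent branch and is conservative.

## A worked example

```{r example}
g <- generateEpithelium(makePreset("CIN2"), seed = 1)
res <- runPipeline(g$image)
featureTable(res)[, c("N", "V", "D", "ncRatio", "diffRatio", "histRatio",
                      "score", "grade")]
```

The three-disc coefficient scene:

```{r fig2}
sc <- fig2Scene()
mask <- greyValues(sc) < 128
max(labelComponents(morphologicalClosing(mask, 16, roiMask(sc))))  # 2
max(labelComponents(morphologicalClosing(mask, 30, roiMask(sc))))  # 1
```

## Known limitations

- Touching or overlapping nuclei are segmented as one object; on clinical
  high-grade material this inflates N and deflates the count (and hence
  inflates V). The generator sidesteps this by construction.
- The square-grid chessboard metric shifts zone boundaries by up to ~1 px
  relative to a hexagonal-grid implementation of the same operations.
- The score calibration is exactly determined by four reference points;
  it extrapolates linearly outside the ratio ranges those points span and
  is clipped to [0, 120].
- Grade cut-offs (nearest reference, ties up) are a pragmatic default; the
  clinically meaningful treat/no-treat cut-off is left to the user.
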