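---
title: "Automated meibography analysis with meibographr"
author: "meibographr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated meibography analysis with meibographr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meibographr)
```

## The problem

Infrared meibography images the meibomian glands of the everted eyelid.
Clinically, the key quantity is the dropout area (DOA): the fraction of
the tarsal conjunctiva that has lost glandular tissue. Subjective
grading of meibography (the 4-grade Meiboscore) is fast but poorly
repeatable; `meibographr` implements a fully automated pipeline that
estimates the DOA and per-gland morphometrics from a single raster
image, with no user input, and grades the eyelid on both the legacy and
an objectively derived scale.

The pipeline has three stages:

1. **ROI selection** — locate the tarsal conjunctiva between the upper
   and lower boundaries of the everted eyelid.
2. **Gland segmentation** — isolate, label and (where necessary)
   fragment individual glands inside the ROI.
3. **Analysis** — dropout area, gland length/width/relative length, and
   a polar-profile irregularity score.

## ROI selection

The grayscale image is split in two by the row-mean intensity profile:
the bright tarsal band lies between the two eyelid boundaries, so the
argmax of the profile (after a 31-row moving average) is a row safely
inside the band. The split rule is the package's own choice; it is
deterministic and has a single parameter (the smoothing window). A flat
profile (no peak exceeding the profile median by `split_peak_margin`,
default 10 intensity units) signals an unusable acquisition and fails
the image rather than guessing.

**Upper boundary.** The upper subimage is eroded with a 10 px disk,
sharpened by unsharp masking built from a sigma = 30 px Gaussian
low-pass (`x + amount * (x - lowpass(x))`, amount = 1 — the standard
sharpening constructed from a low-pass kernel), median-filtered in a
40 x 40 px window, binarized with a global Otsu threshold
(parameter-free), and edge-detected with a horizontal Sobel filter
(replicate border padding; circular padding would fabricate edges at
the subimage borders). Edge components below 500 px (pixel count) are
dropped; each survivor is fitted with a quadratic in x and the curve
with the smallest strictly positive quadratic coefficient is kept,
matching the convex shape of the everted upper boundary. The fitted
constant term is then shifted up by the erosion radius: a disk erosion
of a bright region displaces its top edge downward by exactly the
radius, a known offset that would otherwise bias the ROI.

**Lower boundary.** The lower subimage is passed through a 9 x 9 local
entropy filter (16 intensity bins). Per column, local maxima of the
entropy response that reach at least `peak_frac` (default 0.5) of the
column's dynamic range are marked as peaks. The resulting peak map is
dilated with a horizontal 3 x 12 px rectangle, closed with a 6 px disk,
and components under 500 px are dropped; the component with the largest
horizontal extent is the boundary structure. Its per-column bottom edge
is fitted with a degree-4 Chebyshev series (x rescaled to [-1, 1]) with
the degree-4 coefficient constrained to be non-positive (the boundary
is concave). The single bound constraint is handled exactly: if the
unconstrained least-squares coefficient is positive, the optimum lies
on the constraint boundary, so the degree-4 term is dropped.

Two numerical choices here deserve comment, as the obvious defaults
fail. A peak criterion at 10% of the column range admits entropy peaks
produced by background noise below the eyelid; after dilation and
closing these merge with the boundary structure and drag the traced
edge toward the image bottom — 50% separates texture from noise
robustly. Second, the traced bottom edge can only be contaminated
*downward* (stray blobs hang below the true edge), so the fit is made
robust by asymmetric lower-envelope trimming: points sitting more than
1.5 interquartile ranges above the 75th residual percentile are
discarded and the curve refitted, for up to five rounds. Symmetric
(MAD-based) trimming fails here because contiguous contaminated
stretches inflate the scale estimate.

**Chan-Vese refinement.** The region between the fitted curves seeds a
two-phase Chan-Vese evolution on the 9 x 9 local-standard-deviation
transform of the image: the tarsal band is textured by the glands, the
surround is smooth. The implementation is a discrete narrow-band
scheme: each iteration recomputes the mean feature inside and outside
the current mask, lets only contour-adjacent pixels switch to the
nearer phase, and applies a 3 x 3 majority filter as the curvature
(smoothing) step. Three safeguards matter:

* **Displacement cap** (default 25 px): the contour may not move
  farther than this from the seed contour. Dropout regions are as
  texture-free as the image surround, so an unbounded region
  competition would carve dropout off the ROI rim — but dropout must
  stay inside the ROI. The cap turns the evolution into a local
  boundary correction. With the cap, iterations beyond about twice the
  cap cannot move the front, so the default iteration count is 60 with
  convergence declared when fewer than 0.1% of mask pixels change
  between 5-iteration checkpoints.
* **Halo compensation**: the local-SD transform responds within its
  window radius of the true texture edge, so the converged contour
  systematically overshoots outward by about `sd_radius`; the final
  mask is eroded by that radius.
* **Reflection pinning**: saturated specular reflections (> 200
  intensity) are texture-free and would be notched out of the rim;
  their feature value is pinned to the seed-region mean.

The final ROI is the largest 8-connected component. If any stage fails,
`select_roi()` records the causal condition and returns
`status = "failed"` instead of raising, so batches continue; a manual
ROI polygon can be supplied as a fallback.

## Gland segmentation

A difference-of-Gaussians band-pass (sigma 2 px minus sigma 30 px) —
the standard band-pass constructed from two low-passes — enhances
structures at the gland-width scale. Binarization is locally adaptive:
the threshold at a pixel is the ROI-masked local mean over a 75 px
window plus `(1 - sensitivity) * q95`, where `q95` is the 95th
percentile of the absolute band-pass deviation inside the ROI. Three
details were forced by experiment:

* The local mean must be *masked* (computed over ROI pixels only):
  the band-pass response has a broad halo across the ROI boundary that
  otherwise biases the rim.
* The window must exceed the gland-plus-intergland period (~50 px);
  with a window comparable to the gland width a gland raises its own
  local mean and suppresses itself, breaking into fragments.
* The offset must sit above the noise floor. An offset below it marks
  most pixels of texture-free dropout as foreground, which the
  size/orientation filters do not fully remove, and the dropout area is
  then drastically underestimated. Scaling by the strong-signal level
  `q95` keeps the sensitivity semantics (higher sensitivity, more
  foreground; default 0.7) while rejecting pure noise.

Foreground is additionally suppressed within `rim_px` (default 5 px) of
the ROI boundary: the boundary step produces its own band-pass ridge
which otherwise bridges neighbouring glands into a single component;
that merged component is nearly horizontal in the moment sense and the
orientation filter would delete all its glands at once.

The binary image is smoothed with a 5 x 3 median filter (on a binary
image, a majority vote), components under 800 px are removed, and
components whose moment-ellipse orientation is outside [40°, 140°]
(vertical = 90°) are removed as eyelid-edge artifacts. Components are
8-connected throughout; labels are numbered left-to-right by centroid
column.

## Fragmentation of compound glands

Glands occasionally merge in fork-like structures. For each labelled
object the column-wise pixel-count profile is computed; a column is a
*significant minimum* when it is a local minimum (plateau columns
count individually) whose depth below the lower flanking maximum is at
least 20% of the profile maximum. When the number of significant
minima exceeds `NlTH` (default 1) or the object orientation deviates
from vertical by more than `OTH` (50°), the object is split by
vertical cuts at the centers of the minima runs; fragments are the
column-range partitions of the object's pixels, so foreground is
conserved exactly. The split is accepted only when it yields more than
`NoTH` (1) fragments, every fragment is within `O2TH` (50°) of
vertical, and every fragment has a moment length/width ratio of at
least `RTH` (3); accepted fragments are re-examined recursively. The
five gate thresholds are the published device values; the split
mechanics (what exactly is counted and where cuts run) are a
reconstruction, as only the thresholds are documented for the original
instrument. Vertical cuts were chosen over distance-transform watershed
lines because they conserve pixels trivially, are deterministic, and
satisfy the same gates on fork-like fixtures.

## Dropout area

`DOA = 100 * (N_ROI - N_GL - N_R) / N_ROI`, with `N_GL` the pixel count
of the *gland region* — glands plus intergland tissue. Anatomically
intergland spaces are narrower than glands (~20 px at the reference
resolution), so the gland region is the morphological closing of the
binary gland image with a 20 px disk: background gaps narrower than
about twice the radius are filled, wide dropout stays open. A
mean-filter alternative (disk mean filter, threshold 0.5) is available
behind the `gland_region_method` switch. Saturated reflections (> 200)
inside the ROI are excluded from the dropout (they are tissue whose
state is unknown); reflections inside the closed gland region are not
double-counted. All three counts are taken over the same measurement
domain: the ROI minus the `rim_px` band excluded during segmentation —
pixels where detection was disabled cannot be scored as dropout.

## Morphometrics and irregularity

Gland length and width are the major and minor axis lengths of the
ellipse with the same normalized second central moments as the gland
(`4 * sqrt(eigenvalue)` of the pixel covariance with the 1/12
unit-pixel term). Relative length divides by the local eyelid height —
the distance between the fitted boundary curves at the gland centroid
column — and is flagged when it exceeds 100%.

For irregularity, the gland's 8-connected outer boundary is expressed
in polar coordinates about the mass center, sampled at 1° bins and
normalized by the maximum radius (profiles live in (0, 1], a circle
maps to 1; normalization by the maximum rather than the mean is the
package's choice and is configurable in spirit by rebuilding
envelopes). Non-star-shaped boundaries keep the outermost crossing per
ray and emit a warning. A reference envelope — per-angle mean ± 1 SD
over a population of regular glands — defines the regular corridor; the
irregularity score is the trapezoidal integral over angle (degree
units) of the profile's excess above the upper limit plus its deficit
below the lower limit. Because profiles are normalized, the score is
invariant to gland size and position and monotone in protrusion
amplitude.

The package ships an envelope built from 200 *synthetic* regular glands
(zero boundary waviness, natural size variation, fixed seed) in
`inst/extdata/reference_envelope_synthetic.csv`. It is a stand-in for a
clinically derived envelope and is labelled as such; users should
rebuild an envelope from their own segmented regular glands with
`build_envelope()` for clinical use. The eyelid-level irregularity is
the score of the per-angle *mean* profile across all glands of the
eyelid; per-gland scores are also reported.

## Grading

Two preset scales map DOA to grades 0-3. The legacy Meiboscore: grade 0
iff DOA = 0, then (0, 32], (32, 65], (65, 100]. The objective scale
derived from automated DOA values: [0, 16), [16, 32], (32, 59],
(59, 100] — note the half-open first interval. `otsu_class_limits()`
re-derives such boundaries from any DOA sample by multi-level Otsu
clustering: DOA percentages are binned at 1 percentage point (101
bins), and all threshold triples are searched exhaustively using
cumulative moments, so the result is the exact minimizer of the total
within-class variance on the binned values (about 1.6e5 combinations —
exactness at negligible cost). Agreement between graders is quantified
by unweighted Cohen's kappa with Landis-Koch verbal bands; kappa can
also be reconstructed from marginal category counts plus an agreement
count, since chance agreement depends only on the marginals.

## The synthetic generator

`generate_meibography()` renders: a bright tarsal band between a convex
quadratic upper curve and a concave quadratic lower curve (about 16%
and 85% of the frame height at their extrema, with randomized
curvature); near-vertical glands with Gaussian intensity cross-profiles
(amplitude 75 on a tissue background of 90 against a dark surround of
20), sinuous centerlines (3 px amplitude); a contiguous dropout span
grown from the temporal side to a prescribed fraction of the ROI area;
saturated reflection blobs (intensity 255, radius 5-9 px); a linear
illumination ramp (span 20); and additive Gaussian noise (SD 4). All
truth layers are emitted, and the truth DOA satisfies the dropout-area
identity exactly on the truth counts: the truth gland region is the ROI
minus dropout minus reflections, so truth DOA equals the dropout
fraction.

Default geometry: 1360 x 1024 px frame, 30 glands (intergland gaps
~24 px, consistent with the anatomical premise that intergland spaces
are narrower than glands and with the 20 px disk used for the gland
region; the count lies within the clinical range of 26 ± 6), gland
width 20 ± 2 px, glands spanning the full local band height. That last
choice is a deliberate idealization: it makes the truth DOA equal the
dropout fraction exactly and recoverable by the pipeline, whereas
clinical glands typically span ~70% of the eyelid height. Consequently
the generator validates the *measurement machinery*, not the clinical
distribution of relative lengths; synthetic relative lengths exceed
100% by construction (the moment length of a full-height strip is
2/sqrt(3) times its extent). Every random draw derives from a single
seed, so samples are byte-reproducible.

## Problem sizes used in the test suite

The validation experiments in the package's tests run the full pipeline
at the native 1360 x 1024 resolution: five seeds at each dropout
fraction in {0, 0.2, 0.5, 0.8} for dropout-area recovery (tolerance
5 percentage points), ROI overlap (Jaccard at least 0.85) and exact
gland-count recovery in the no-dropout runs, plus three seeds per gland
density in {5, 15, 25} for count recovery with the segmentation stage
isolated. Property-style checks (pixel conservation, idempotence,
invariances) use small constructed fixtures.

## Known limitations

* All structural parameters are calibrated to the reference device
  geometry (1360 x 1024 px); other instruments require re-scaling the
  radii and size thresholds via the configuration.
* The generator does not model defocus, eyelashes, partial eversion or
  tissue texture; pipeline failure modes on such images are exercised
  only by the flat-image and degenerate-input paths.
* On severely atrophic eyelids (very few, widely spaced glands) the
  lower-boundary entropy structure becomes sparse and the Chebyshev fit
  less reliable; such images are also where the clinical study needed
  manual ROI fallback. Gaps wider than twice the disk radius between
  surviving glands are scored as dropout by construction.
* `mm_per_px` is a configurable approximation (default 0.02 mm/px,
  chosen so a 20 px gland width is about 0.4 mm); absolute millimetre
  values inherit its uncertainty.
* The fragmentation control flow is a reconstruction around the five
  published thresholds.
* Lower-eyelid images and longitudinal image matching are out of scope.
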