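---
title: "microseg: models, parameters and numerical conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{microseg: models, parameters and numerical conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microseg)
```

# Scope and assumptions

`microseg` analyses 2-D fluorescence fields of view acquired as T repeated
raster scans (the default geometry is 256×256 px over 20×20 μm, i.e.
0.078125 μm/px, with T = 7). The working assumptions are:

- cells are brighter than the background (intrinsic or labeled
  fluorescence with roughly homogeneous intracellular distribution), so a
  mask's mean intensity is informative about whether it covers a cell;
- frames are registered (no drift correction is attempted): the per-pixel
  mean over scans is an unbiased, variance-reduced estimate of the true
  intensity;
- rod-shaped cells lie flat in the focal plane, so a 2-D spherocylinder
  footprint plus a 3-D spherocylinder volume model is adequate; round
  nuclei are modeled as spheres.

Segmentation proposals themselves come from a pluggable backend. The
package treats any proposal source identically: a set of binary masks with
confidence scores in [0, 1]. For prompt-based foundation-model segmenters
the score slot carries the model's predicted IoU; the built-in baseline
backend scores components by mean intensity so that confidence ordering is
still graded and non-maximum suppression is exercised realistically.

# Image preparation

**Stacking.** The T scans are averaged pixelwise in double precision. For
independent per-scan noise this divides the noise variance by T; the test
suite verifies the 1/T law empirically at T ∈ {1, 7, 28}.

**Normalization.** Intensity filtering and denoising operate on min–max
normalized images. Min–max was chosen (over e.g. percentile scaling)
because the multi-Otsu class means that anchor the intensity filter are
scale-dependent, and because a denoiser noise level of σ = 0.2 is only
meaningful on a unit range. Normalization happens *before* denoising; this
ordering is an explicit convention of the package (the σ value presumes a
[0, 1] range), and the denoiser rejects un-normalized input rather than
guessing.

**Clamping.** `clamp_image(image, fraction)` replaces v by
min(v, fraction·max). It deliberately does *not* rescale afterwards:
clamping and re-normalization are separate calls, so both the clamped and
the clamped-then-denoised displays of a bright-nucleus/dim-membrane image
are reproducible as pipeline states.

**Denoising.** Denoising is a contract — matrix in [0, 1] plus σ in, same
shape out — behind a registry. The built-in implementation is a fast
non-local-means filter: for every offset in a (2·5+1)² search window the
patch distance image is computed by one squared difference and one
box-filter pass (integral images), patch distances are noise-compensated by
subtracting 2σ², and weights are exp(−max(d²−2σ², 0)/h²) with bandwidth
h = 0.6σ. Patch radius 2, search radius 5 are conventional NLM settings and
are exposed as arguments. An external BM3D implementation can be registered
under the name `"bm3d"` and becomes selectable everywhere; the contract
test (denoised-to-clean MSE strictly below noisy-to-clean MSE on a σ = 0.2
scene) applies to whatever sits behind the contract. σ defaults to 0.2, the
appropriate scale for the photon-starved fast-scanning regime the package
targets.

# The refinement chain

The chain runs area → intensity → NMS → edge → closing; every removal is
logged with the proposal's original index, the removing stage and a
diagnostic value, and the report provably partitions the input set
(checked by a count-conservation test).

**Area bounds** (defaults: min 10 px, max (shorter side/4)²). Comparisons
are *strict* at both bounds — a 10-px mask and a mask of exactly
(s/4)² px are retained — following the rule's literal "smaller than" /
"exceeding" phrasing. The maximum defaults to the shorter-side rule and can
be overridden numerically.

**Intensity band.** The whole normalized image is partitioned into K
multi-Otsu classes; a mask is kept iff r₁μ₁ ≤ mean ≤ r₂μ_K *inclusive*.
Two interpretive choices are documented here because they change absolute
results: (i) μ_k are the mean intensities of the pixels assigned to class
k over the whole image — not Otsu threshold values, and not mask-restricted
means; (ii) K defaults to 3 (background / dim structure / bright cells)
but is a plain configuration field, since the right K depends on the
contrast structure of the image. Multi-Otsu itself is solved exactly by
dynamic programming over a 256-bin histogram (maximizing between-class
variance, O(K·256²)); a brute-force exhaustive search over threshold pairs
serves as the independent oracle in the tests. An image with fewer than K
distinct values is a configuration error, reported as such.

**Non-maximum suppression.** Only the pairwise rule is inherent to the
method ("if IoU > threshold, discard the lower-confidence mask"); a
complete algorithm needs an order. The package uses the standard greedy
descending-score sweep comparing each candidate against *kept* masks only,
so a suppressed mask cannot veto a later one. This makes the outcome
reproducible and guarantees: retained pairwise IoU ≤ threshold, and every
removed mask has a kept, strictly higher-score suppressor with
IoU > threshold. The acceptance suite verifies exactly this predicate
against 120 random proposal sets. Score ties are broken by input order,
and the baseline backend orders its output deterministically
(descending score, then first foreground pixel in row-major order), so the
whole path is reproducible.

**Edge removal.** With margin m = 2 (the default), any mask with a
foreground pixel in the first or last two rows or columns is removed —
0-based indices ≤ 1 or ≥ side−2. The margin is a parameter; m = 0 disables
the stage.

**Closing.** Morphological closing (dilation then erosion, disk of radius
1 — realized as EBImage's discrete radius-1 disc, the full 3×3 box) is
applied per mask, never to a fused label image, so closing cannot merge
adjacent cells. Masks are padded before the operation so the result equals
the closing on an unbounded canvas restricted to the image, independent of
any library border convention; a loop-based dilate/erode oracle pins this
down in the tests. Area and IoU bounds are enforced on *pre-closing*
masks; closing is cosmetic smoothing applied last and may grow areas
slightly. Whether the area bounds should be re-applied after closing is
genuinely open; the package does not re-apply them and documents that
choice here.

# Morphometrics

**Length.** "The bounding box with maximum overlap" is realized as the
minimum-area rotated enclosing rectangle, computed by rotating calipers
over the convex hull of the mask's pixel-*corner* points. Corner points
matter: the hull of pixel centres of a 40×10 px rectangle spans only
39×9 px, while corners give the exact 40×10 extents — so an axis-aligned
rectangle is recovered with zero error, and rotated rectangles to within
rasterization error.

**Width.** The box is divided into four equal sections along its length;
within the middle two sections the mask's perpendicular extent is measured
in 1-px axial bins (max − min of the perpendicular coordinate of pixel
centres, + 1 px for the pixel footprint) and averaged. Restricting to the
middle two quarters excludes the hemispherical caps, whose chords would
bias the width low. The exact refinement used by practitioners varies;
this estimator is isolated in `fit_rod()` so it can be replaced wholesale.
W is clamped to ≤ L so the volume model's precondition always holds.

**Volumes.** `rod_volume(L, W) = π(W/2)²(L−W) + (4/3)π(W/2)³` and
`sphere_volume(r) = (4/3)πr³`, both in fL. The two models agree exactly at
L = W = 2r, which the tests assert to machine precision across a radius
grid — a useful internal consistency check on both formulas.

**Sphere radius.** The radius of a round mask is taken as that of the
equal-area circle, r = √(area/π)·scale. This is this package's documented
estimator choice; nothing about the workflow constrains how a radius
"should" be derived from a 2-D mask, and alternatives (half the box side,
maximal inscribed circle) would differ at the percent level on irregular
masks.

**Units.** μm and fL throughout. Passing `pixel_scale = NA` to
`extract_features()` switches geometric output to pixels and suppresses
volumes, for data with unknown scale.

# Detection evaluation

The error rate is (missed + incorrect)/n over n annotated points: an
annotation is *detected* when its point lies inside a retained mask,
assignment is one-to-one, a mask covering several points keeps the one
nearest its centroid (surplus points count as missed), and masks
containing no point are incorrect. "Wrong position" is thus realized as
"mask containing no annotation point" — a deliberately simple operational
definition, stated prominently because it shifts absolute rates relative
to stricter definitions (e.g. centroid-distance gating). The rate has no
upper cap: spurious masks can outnumber cells. Per-image tables close with
the *unweighted* mean of per-image rates, matching the convention of
averaging image-level accuracies rather than pooling cells.

# The synthetic generator

`generate_scene()` emulates the reference acquisition: spherocylindrical
footprints rasterized exactly (pixel centre within W/2 of the medial
segment), placed without overlap by rejection sampling, then T frames each
drawn as Poisson(expected photons) + N(0, dark σ), clipped at zero.
Defaults, chosen once as a realistic mid-density condition: 50 cells of
length 2–4 μm and width 0.6–1.0 μm (an *E. coli*-like population),
cell signal 20 and background 2 photons/px/frame with dark σ = 1 (a
shot-noise-dominated low-SNR regime), placement margin 4 px and minimum
separation 2 px. The margin keeps ground-truth cells out of the
edge-exclusion band so the detection metric is well defined; the
separation prevents 8-connected merging of adjacent truth cells, which
would make point-level evaluation ambiguous. Scenes are bit-reproducible
from their seed, and generation restores the caller's RNG state.

What the generator deliberately does **not** model: optical PSF blur,
photobleaching kinetics, cell overlap and crowding, intra-cell intensity
structure, and non-rod morphologies. Consequently, passing the end-to-end
tests demonstrates that the *chain* is correct (stages compose, thresholds
act as specified, geometry is recovered within quantization error) — it
does not certify segmentation accuracy on real micrographs, where contrast
heterogeneity and touching cells dominate the error budget and where a
learned proposal backend is expected to replace the thresholding baseline.

# Problem sizes and test budgets

The test suite runs entirely on synthetic data built at test time:
256×256 px scenes of up to 20 cells for end-to-end properties, 128×128
fields for denoising MSE checks, 60 rendered rods for parameter recovery
(median relative errors for L and W must stay within 10%), 120 random
proposal sets for the NMS oracle, and small hand-built fixtures (a 64×64
six-mask scene) for the refinement contract. These sizes were chosen as
the smallest at which the Monte-Carlo tolerances involved (20% on variance
ratios, 10% medians) are comfortably stable across seeds.

# Known limitations

- The baseline backend cannot split touching cells (8-connected components
  merge them); dense fields need a stronger proposal source.
- Width estimation assumes an approximately straight rod; strongly bent
  cells would need a medial-axis length instead of a box side.
- The intensity filter's class means are computed over the whole image, so
  a field with no cells at all makes class structure — and hence the band —
  meaningless; K must reflect the actual contrast levels present.
- Only 2-D analysis is supported; no z-stacks, no tracking across fields.
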