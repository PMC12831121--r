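# microseg

Automated instance segmentation and morphometric analysis of microbial
cells in low-photon-count fluorescence microscopy.

## The problem

Quantifying microbial growth and morphology at the single-cell level
requires delineating every cell in a field of view — typically a 256×256 px
raster-scanned image covering 20×20 μm, acquired as several fast scans with
photon shot noise dominating each one. Manual annotation does not scale, and
segmentation models produce raw masks contaminated by noise specks,
background artifacts, duplicates and cells truncated at the image border.

`microseg` provides the full workflow around any mask-proposal source:

1. **Image preparation** — average the T raster scans pixelwise (noise
   variance falls as 1/T), min-max normalize, optionally clamp to a fraction
   of the maximum to reveal dim structures, and denoise on the [0, 1] scale
   (built-in fast non-local means; an external BM3D implementation plugs in
   behind the same contract via `register_denoiser("bm3d", fn)`).
2. **Proposal generation** — a pluggable backend produces binary instance
   masks with confidence scores. A deterministic thresholding baseline
   (8-connected components, scored by mean intensity) is built in;
   prompt-based foundation-model segmenters attach as adapters fed by the
   standard 32×32 point-prompt grid (`point_grid()`).
3. **Mask refinement** — the four-stage post-processing chain with an
   auditable removal report:
   - *area*: drop masks smaller than 10 px or larger than
     (shorter side / 4)² px;
   - *intensity*: partition the image histogram into K multi-Otsu classes
     with means μ₁ < … < μ_K and keep only masks whose mean intensity lies
     in [r₁μ₁, r₂μ_K] (defaults r₁ = r₂ = 1.3);
   - *NMS*: confidence-guided non-maximum suppression — among masks whose
     pairwise IoU exceeds 0.3, only the highest-score one survives;
   - *edge*: remove masks touching the first/last two rows or columns;
   - finally each mask is smoothed by morphological closing.
4. **Morphometrics** — rod-shaped cells are modeled as spherocylinders:
   length L from the minimum-area rotated bounding box, width W averaged
   over the middle two quarters of the box, and volume

   V = π (W/2)² (L − W) + (4/3) π (W/2)³   (in fL; 1 μm³ = 1 fL).

   Round nuclei use the equivalent-area sphere model V = (4/3) π r³.
5. **Evaluation** — detection error rate against point annotations:
   (missed + spurious detections) / annotated cells, with per-image summary
   tables.
6. **Synthetic scenes** — a fully seeded generator places non-overlapping
   spherocylinders in the reference field geometry and simulates each scan
   with Poisson shot noise plus Gaussian dark noise, with ground-truth
   masks, parameters and annotations, so the entire pipeline is testable
   without any real data.

## Worked example

```r
library(microseg)

sc      <- generate_scene(scene_spec(n_cells = 20, cell_intensity = 50, seed = 7))
stacked <- stack_frames(sc$frames)
den     <- denoise_image(normalize_image(stacked), sigma = 0.2)
ps      <- propose(den, "baseline", threshold = 0.4)
pp      <- run_postprocess(ps, den, filter_config())
match_detections(pp$proposals, sc$annotations)
#> <match_result> 20/20 matched, 0 missed, 0 incorrect; error rate 0.0%

ft <- extract_features(pp$proposals, stacked, model = "rod")
head(ft[, c("cell_id", "L_um", "W_um", "volume_fL", "mean_intensity")], 3)
#>   cell_id  L_um   W_um volume_fL mean_intensity
#> 1       1 3.922 0.7123     1.468          52.24
#> 2       2 2.812 0.7812     1.223          52.02
#> 3       3 3.601 0.7345     1.422          51.83
```

All 20 simulated cells are detected (error rate 0%), and each retained mask
yields its length and width in μm, spherocylinder volume in fL, and mean
intensity on the stacked image (here ≈ 52, the simulated
cell-plus-background photon rate). The two reference volume computations:

```r
rod_volume(3.215, 0.865)   # E. coli cell, L x W in um  -> 1.720 fL
sphere_volume(1.014)       # yeast nucleus radius in um -> 4.367 fL
```

A command-line wrapper over the same functions is provided in
`exec/microseg.R` with subcommands `simulate`, `denoise`, `segment`,
`postprocess`, `features`, `evaluate` and `run` (full pipeline with a YAML
config and a provenance manifest).

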