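# thrombotrack

Quantitative analysis of thrombus deformation during stent-retriever
thrombectomy, from fluoroscopic x-ray frame series.

During mechanical thrombectomy the clot itself is radiolucent: it is
invisible under fluoroscopy, so the mechanical interaction between the
stent retriever and the thrombus — compression, stretch, slip, distal
migration, fragmentation — happens entirely out of view. In a bench
(in-vitro) model the clot *is* visible as a contrast filling defect, and a
calibrated frame series of a retrieval contains everything needed to
measure that interaction objectively. `thrombotrack` implements the full
measurement chain for such recordings:

1. **Preprocessing** — crop to the operator-chosen ROI around the vessel
   model, then subtract the per-pixel temporal **median baseline**, which
   removes all stationary structure and leaves only moving content
   (thrombus positive, radiopaque marker negative).
2. **Segmentation** — a drag path over the structure defines both the seed
   pixels and an intensity interval `[min, max]`; a threshold-bounded 2D
   flood fill segments the seed frame, and the mask is propagated forward
   and backward in time (previous-frame mask, filtered by the interval on
   the new frame, seeds the next fill) until the series ends or the
   structure leaves the frame. Masks are stored as NIfTI-1 label volumes
   (1 = thrombus, 2 = stent-tip marker).
3. **Metrics** — per retrieval, with pixel spacing and frame rate from the
   calibration:
   - deformation index `D = (1/N) Σ_{i=1..N} |p_i − p_0| / p_0`, the mean
     relative absolute change of the thrombus pixel count `p_i` versus the
     first frame (dimensionless, reported ×10³);
   - contour change `CC = mean_{p ∈ C_t} min_{q ∈ O_{t+1}} ‖p − q‖`,
     averaged over frame transitions (pixels; 0 iff successive contours
     coincide);
   - peak distal tip migration, categorized minimal (< 1 mm), moderate
     (≥ 1 to < 2.5 mm), marked (≥ 2.5 to < 4 mm), extensive (≥ 4 mm);
   - maximal shortening/elongation (mm and % of initial length), stent
     grip (mm/slice change of the tip-to-tip gap), GCOG speed and
     acceleration.
4. **Visualization** — colored temporal overlays: per-frame masks aligned
   by GCOG stacking plus a bounded overlap-maximizing shift, hue running
   red (start) to green (end), brightness 50–100% with overlap count.
5. **Reliability** — Dice, Jaccard, HD95 and average surface distance
   between raters' masks.
6. **Statistics** — Wilcoxon rank-sum with U statistic and Cliff's δ,
   Fisher's exact test for r×c contingency tables, Clopper–Pearson
   binomial intervals, z-based CI half-widths, Benjamini–Hochberg FDR,
   and per-device covariate (ANCOVA-style) regression.
7. **Synthetic phantoms** — a calibrated generator of retrieval scenes
   (static vessel band, capsule-shaped clot with motion/migration/
   deformation schedules, stent-tip marker, Gaussian noise) with exact
   ground truth, used to validate the entire chain.

## Worked example

Segment a synthetic moderate-migration retrieval (40 frames, 256×256 px,
0.308 mm/px, 6 frames/s, noise at 10% of the thrombus contrast) and
quantify it:

```r
library(thrombotrack)

suite <- default_fixture_suite(noise_sd = 3)
ph <- generate_phantom(suite$moderate$cfg)

roi <- roi_box(1, 256, 108, 148)                 # band around the vessel
ns  <- normalize_series(crop_series(ph$series, roi))
thrombus <- seed_path(1, cbind(170:190, 21))     # drag along the clot
stent    <- seed_path(1, cbind(149:153, 21))     # drag over the marker
mask <- segment_retrieval(ns, thrombus, stent)

retrieval_metrics(mask, axis_col = 21)
#> retrieval_metrics
#>   deformation D: 0.03145 (x10^3: 31.4)
#>   contour change CC: 0.613 px
#>   distal migration: 1.54 mm (moderate)
#>   max shortening: 0 mm (0.0%), max elongation: 0 mm (0.0%)
#>   stent grip: 0.813 mm/slice
#>   mean GCOG speed: 5.3 mm/s over 40 frames
```

The phantom's scheduled truth was 1.54 mm moderate migration at a mean
speed of 5.354 mm/s: the pipeline recovers the migration category exactly
and the kinematics to within the one-voxel uncertainty. `D` and `CC` are
nonzero here purely because of the injected noise — on the noise-free
phantom both are recovered exactly. Agreement with the ground-truth mask:

```r
truth <- segmentation_mask(ph$truth_mask$voxels[, 108:148, ],
                           ph$truth_mask$calibration)
reliability_report(mask, truth)
#> reliability_report: DICE 0.914, JACC 0.842, HD95 0.924 mm, ASD 0.286 mm
```

`render_overlay(mask)` then produces the red-to-green temporal overlay and
`write_overlay_png()` saves it. The whole chain is also available through
a YAML-configured [`run_pipeline()`] and the `inst/cli/thrombotrack`
command-line script (`simulate`, `segment`, `metrics`, `overlay`,
`reliability`, `compare` subcommands).

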