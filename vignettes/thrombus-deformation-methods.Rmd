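---
title: "Measuring thrombus deformation from fluoroscopic retrieval series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring thrombus deformation from fluoroscopic retrieval series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thrombotrack)
```

## The measurement problem

A stent retriever engages a clot that x-rays cannot see: in vivo the
thrombus is radiolucent and the retrieval happens blind. In a bench model
the clot appears as a contrast filling defect inside a stationary vessel
phantom, recorded as a calibrated grayscale frame series (here: 6 frames/s;
pixel spacing from the acquisition metadata, e.g. 0.154 mm per side).
`thrombotrack` turns such a series into per-retrieval measurements of
device–thrombus interaction. This vignette documents the model behind each
stage, the conventions and tunable parameters, and the package's own design
decisions where the procedure left genuine choices open.

## Geometry and conventions

Frames are matrices indexed `[row, col]`, 1-based and inclusive; the row
axis is the vessel (Y) axis with increasing row pointing in the *distal*
direction, columns are X. Time is the third array dimension, which is also
the third dimension of exported NIfTI-1 masks (in-plane pixel spacing in
the first two voxel-dimension fields, the frame period in seconds in the
third). Anisotropic spacing is honored everywhere: lengths along rows use
the row spacing, widths the column spacing, Euclidean surface distances
both. One caveat of the NIfTI-1 container: voxel dimensions are stored as
32-bit floats, so spacings round-trip at that precision while label voxels
round-trip bit-exactly.

Calibration also fixes the measurement uncertainty quoted alongside
distances and velocities: one voxel corresponds to
`sqrt(row spacing × col spacing)` in any distance (0.154 mm at the
acquisition calibration, i.e. 0.024 mm² of area) and to that side length
times the frame rate in a per-frame velocity (0.924 mm/s at 6 frames/s).

## Preprocessing: the stationarity assumption

Because the vessel phantom does not move, cropping to one operator-chosen
rectangle is valid for the whole series, and the per-pixel **temporal
median** of the cropped stack is an image of the empty model: anything
present at a pixel in fewer than half of the frames is voted out. The
median frame is subtracted from every frame. Signs are kept: a radiolucent
clot displaces contrast and becomes positive, the radiopaque marker
negative. For even series lengths the median is the mean of the two central
order statistics (a deterministic, widely used convention; the choice only
matters for pixels whose occupancy is close to half the series).

The assumption has a sharp failure mode, which is kept deliberately
visible rather than patched: a structure covering a pixel in at least half
of the frames leaks into the baseline and is no longer zeroed. For a clot
of length `L` translating `s` mm per frame this happens once
`L/s + (frames at rest)` reaches `T/2`. The synthetic defaults (12-mm clot,
0.924 mm/frame, 4 rest frames, T = 40) keep per-pixel occupancy at ~17
frames, below the T/2 = 20 threshold with margin; slower or shorter series
will leak, and the preprocessing tests pin down exactly that behavior.

## Segmentation: drag, threshold, flood, propagate

The operator's click-and-drag is represented as a `seed_path`: ordered
pixel coordinates on one frame. The path serves double duty — its pixels
seed a flood fill, and the minimum and maximum normalized intensity under
the path define the inclusive threshold interval `[lo, hi]`. The 2D flood
fill returns the union of connected components of in-interval pixels that
contain an in-interval seed; connectivity is 8-connected by default and
configurable to 4 (the procedure itself does not fix it).

Temporal propagation applies the *same* interval to neighboring frames:
the frame-`t` mask, filtered by the interval evaluated on frame `t+1`,
seeds the flood fill on frame `t+1`; symmetrically backward from the seed
frame. The interval is held fixed throughout — re-estimating it per frame
could drift onto other structures, and the fixed interval makes
propagation deterministic and idempotent. Propagation in a direction stops
when the new mask is empty or when every retained pixel lies on the image
border (the structure has left the field of view); in the border case the
clipped frame keeps its mask and later frames stay empty.

One consequence of the drag-interval coupling is worth stating: a path's
own pixels always satisfy the interval they define, so the seed frame can
never produce an empty mask. A drag placed on background therefore floods
the background component — an operator error that is immediately visible
in the result rather than silently suppressed (the defensive empty-mask
warnings remain for programmatic callers).

The interactive correction step of the original workflow is replaced by
programmatic mask editing (`edit_mask`): ordered add/remove voxel-set
edits with label invariants enforced.

## Per-retrieval metrics

**Deformation.** With `p_i` the thrombus pixel count at frame `i` and
`p_0` the first-frame count,

$$D = \frac{1}{N}\sum_{i=1}^{N}\frac{|p_i - p_0|}{p_0},$$

dimensionless and reported ×10³. The reference frame is a genuine choice:
the defining formula compares each frame with frame 0, while a
frame-to-frame variant (`deformation.reference = "previous"`) measures
incremental change. The formula as printed is the default; both are
exposed and tested.

**Contour change.** Contours are 4-neighbor boundary pixels. For each
transition `t → t+1`, every contour pixel of frame `t` contributes its
minimum Euclidean distance to the next frame's outline; `CC` is the mean
over transitions of the mean over pixels, in pixel units, zero exactly
when successive contours coincide. The measure is *directed* (`t → t+1`),
and the tests check this asymmetry against a brute-force oracle. "Contour"
and "outline" refer to the same 4-neighbor boundary. Transitions whose
next-frame outline is empty are skipped and counted.

**Migration.** The distal tip is the maximal-row thrombus pixel. Migration
is the *peak* distal displacement of that tip relative to frame 0, floored
at zero (proximal motion is retrieval, not migration), and categorized by
the fixed half-open thresholds 1 / 2.5 / 4 mm. Peak rather than mean is
used because the categories describe the extent of an excursion —
retrievals typically migrate early and then stabilize, and a mean would
dilute the excursion by the stable tail.

**Grip, kinematics, shortening.** Grip is the signed mean per-frame change
of `|stent tip − distal thrombus tip|` (mm/slice). Speed is the GCOG
displacement in mm times the frame rate; acceleration its per-frame
change; the lateral shift is measured from an operator-supplied vessel
middle-axis column. Shortening and elongation are the positive parts of
`L_0 − L_t` and `L_t − L_0`, maximized over the retrieval, absolute and as
a percentage of `L_0`; percentages are kept at full precision internally
and rounded only for display.

## Temporal overlay

The overlay stacks per-frame masks after alignment: frames are first
centered on the previous aligned frame's GCOG, then refined by a greedy
search within ±5 px (configurable) maximizing pixel overlap with the
previous aligned frame; ties prefer the smallest `|dr| + |dc|`, then
lexicographic order, making alignment deterministic. Hue interpolates
linearly from red (first frame) to green (last) using the *mean* time
index of a pixel's contributions (the mean is the package's choice for
multi-time pixels). Brightness maps overlap linearly: one contribution →
50%, the maximum observed overlap → 100% (linearity is a choice; the
endpoints are part of the definition and are tested exactly, which is also
why colors are computed in floating point rather than through 8-bit color
strings). Filled masks are painted by default; `outline_only` renders
contours instead.

## Reliability metrics

Dice `2|A∩B|/(|A|+|B|)` and Jaccard `|A∩B|/|A∪B|` are computed on label
volumes; two empty masks agree perfectly by convention (1.0). Surface
distances are computed per frame between 4-neighbor boundary sets in mm,
directed distances pooled symmetrically across both directions and all
frames; HD95 is the 95th percentile of the pool (linear-interpolation
quantile) and ASD its mean. A frame segmented by only one rater makes the
distance comparison undefined and is flagged rather than guessed. Surface
distances are strictly in-plane: time is not a spatial axis, and the
boundary errors of interest are mm-scale in-plane deviations.

## Study statistics

The statistical layer wraps the standard machinery (`wilcox.test`,
`fisher.test`, beta quantiles, `p.adjust`, `lm`) behind the interfaces the
analysis needs, adding the U statistic from midranks (half-integers under
cross-group ties) and Cliff's δ as effect size. Conventions, all
two-sided: rank-sum p-values use the tie-corrected normal approximation
without continuity correction by default, exact enumeration for small
tie-free samples; Fisher's exact test for r×c tables uses the
probability-ordering definition under fixed margins (zero-margin tables
carry no information, p = 1); binomial proportions get exact
Clopper–Pearson intervals; mean CIs use z-based half-widths
`z₀.₉₇₅·sd/√n` (the convention of the study's summary table — its
per-stratum table uses a different, internally inconsistent convention
that is deliberately not reproduced); multiplicity over migration strata
is handled by Benjamini–Hochberg; the clot-length dependence check is an
ordinary per-device least-squares fit with a t-test on the length slope.

## The synthetic phantom: what it does and does not emulate

The generator renders the bench scene at desk scale: a 256 × 256 frame at
0.308 mm/px (the 0.154-mm detector binned 2×, preserving the physical
field of view) instead of the full 1024 × 1024, 40 frames at 6 frames/s, a
static contrast band of 5 mm lumen width, a capsule-shaped clot (12 mm ×
3 mm by default — short enough that the median baseline stays clean at
T = 40, see above), and a square radiopaque marker 2 mm proximal to the
clot. Motion follows per-frame schedules: a 4-frame engagement pause, then
steady proximal drag of 0.924 mm/frame (≈ 5.5 mm/s, a typical retrieval
speed); migration episodes ramp the distal tip offset to a peak during the
pause and hold it (initial migration, then stabilization). Schedules are
quantized to whole pixels and the capsule is rasterized from integer row
offsets, so an undeformed clot translates *exactly* rigidly — this is what
makes exact-recovery tests meaningful. Deformation schedules scale the
clot length; ground-truth `D` is the deformation formula applied to the
generator's own rasterized pixel counts (the truth of the rendered scene),
with the analytic schedule value reported alongside, since binary
rasterization makes counts only approximately proportional to scheduled
area factors. Noise is additive Gaussian only.

The fixture suite covers all four migration categories, a
fragmentation-like split (the distal fragment detaches with a gap, the
count drops), and a clot exiting the field of view (propagation must stop
early). Frames where the clot straddles the image border are flagged
`in_frame = FALSE` in the truth record and excluded from mask-agreement
scoring, because the stop rule deliberately truncates there.

What passing these tests shows: the implementation chain — normalization,
flood fill, propagation, geometry, metrics — is exact on its own model.
What it does not show: robustness to the physics the phantom omits —
quantum/Poisson noise, scatter, motion blur, contrast washout, curved or
moving vessels, overlapping devices. Results on real fluoroscopy depend on
those factors and on operator ROI/drag placement.

## Numerical choices and degenerate inputs

* Even-length medians: mean of the two central order statistics.
* Flood fill: inclusive interval bounds; out-of-interval seeds contribute
  nothing; empty seed sets are an error, empty *results* are valid.
* Empty frames yield `p = 0` geometry records with `NA` shape fields;
  trailing empty frames (after a propagation stop) are excluded from the
  pixel-count and length series.
* `p_0 = 0` or `L_0 = 0` are errors (the metrics are undefined), as are
  single-frame series for any per-transition quantity.
* Distal tip ties: the extreme row is a scalar, so ties are unambiguous.
* Fisher probability ordering uses a 1e-7 relative guard against float
  ties; quantiles use the linear-interpolation convention.
* Problem sizes in the test-suite simulations (phantom 256 × 256 × 40,
  coverage 10⁴ replicates, type-I 10³ fits of n = 200) are chosen as the
  smallest sizes at which the checked property is stable.

## Limitations

The package analyzes 2D projections: out-of-plane deformation is
invisible, and pixel counts conflate thickness with area. The median
baseline requires a stationary scene and sufficient clot motion. The
drag-derived interval assumes the structure is homogeneous enough that its
intensity range separates it from background; low-contrast recordings
will flood beyond the target. DICOM input is not read directly — series
are expected as TIFF/PNG stacks with a JSON calibration sidecar (or a
programmatic `calibration`), with spacing and frame rate taken from the
acquisition metadata upstream.
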