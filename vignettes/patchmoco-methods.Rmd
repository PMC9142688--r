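---
title: "Patchwise motion and distortion correction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patchwise motion and distortion correction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(patchmoco)
```

## The problem

In vivo two-photon calcium imaging of awake animals suffers from two
geometrically distinct artifacts. Fast motion (body movements, ~100 ms)
displaces whole frames by spatially uniform translations. On top of that,
the imaged field slowly distorts over minutes to hours — non-uniformly
across the field of view — so that a region of interest drawn early in a
session drifts off its structure later on. A single global transform
cannot fix a non-uniform distortion, and translation-only patch methods
cannot express local rotation, scaling or shearing. patchmoco addresses
both artifacts with a two-step pipeline: rigid translation correction per
frame, then patchwise affine warp correction per block of frames.

## Step 1: rigid correction with template re-estimation

Each frame is aligned to a template by the integer translation maximizing
Pearson correlation on the valid overlap, found by greedy hill climbing
over a 4-level image pyramid (downscale factors 1/8, 1/4, 1/2, 1 by 2x2
block averaging), with the coarse optimum doubled as initialization for
the next level. A 1-D parabola through the correlation at the optimum and
its two neighbors, fitted independently per axis and clamped to (-1, 1),
gives subpixel precision. Both operands are rank transformed first, so
the estimate is invariant to any monotone intensity remapping — frames
with strong calcium transients match their template as well as dim ones.

When the net distortion over a long session is severe, a single template
taken anywhere in the session differs too much from the far ends.
The session is therefore split into 5 equal blocks and corrected
bidirectionally from the middle: the mean of the middle 2500 frames (T1)
registers those same frames, whose corrected mean (T1') registers block 3;
templates built from the corrected edge frames of block 3 register blocks
2 and 4, and templates from the near edges of blocks 2 and 4 register
blocks 1 and 5. Each template thus reflects the distortion state of the
frames it registers.

Numerical choices: hill-climbing ties prefer the smaller shift norm, then
smaller dy, then dx (determinism); candidate shifts leaving less than 25%
frame overlap are rejected; the search bound defaults to `min(H, W)/4`
(larger shifts are not physiological for head-fixed preparations);
resampling uses edge replication by default so no dark borders bias the
later ECC stage. Correlation is evaluated only on the valid overlap — the
non-overlap region is excluded rather than filled.

## Local intensity normalization

Relative brightness across cells fluctuates with activity, which corrupts
correlation-based geometry matching. Before any ECC step, images are
normalized by their local neighborhood mean: the image is convolved with
a binary disk (radius 32 px by default; membership `dy^2 + dx^2 <= r^2`),
divided by the disk convolved with an all-ones image to undo the
zero-padding attenuation at the borders, and the original image is divided
by this compensated local mean and rescaled by the global mean. The
result is homogeneous of degree one (a global gain passes through) and a
cell brightening inside its own neighborhood barely changes its
normalized appearance, so the ECC sees structure, not activity. Pixels
whose neighborhood mean falls below `1e-12 x` the global mean (all-dark
borders of vignetted GRIN-lens fields) are set to zero and counted in a
warning rather than producing division blow-ups.

## Step 2: patchwise affine warp correction

The field of view is tiled into `M x M` nominal tiles of `ceiling(H/M)`
pixels; each interior tile edge is extended by `round(0.3 H / M)` pixels
(rounded half away from zero), so adjacent patches overlap and can be
averaged back together seamlessly. `M = 8` suits cellular-resolution
imaging; 12–15 suits axons, whose movements are more local. All frames
are averaged in non-overlapping 500-frame blocks (~17 s at 29 Hz — slow
distortions are negligible within a block), each block mean is locally
normalized, and for every patch an affine transform is fitted against a
single fixed template: the locally normalized mean of the middle 5500
frames of the rigid-corrected session (clipped for shorter sessions).
Using one fixed template maps all blocks onto one reference geometry;
blocks are fitted independently from identity initialization, so errors
never accumulate across blocks. The fitted transforms are applied to
every raw frame of their block by inverse-mapping bilinear resampling per
patch, and overlapping pixels are averaged with equal weights. Frames of
a trailing sub-block merged by the downsampling remainder rule (kept
separate only if at least half a window long) reuse the transforms
estimated from the block that absorbed them.

### The ECC objective and its maximization

Alignment quality is the enhanced correlation coefficient: the normalized
inner product of the zero-centered template and warped-target pixel
vectors, `rho = (t - mean t) . (w - mean w) / (||.|| ||.||)`, equivalent
to the loss `L = 2 - 2 rho`. It is invariant to gain and bias changes of
either image, complementing the local normalization. Maximization is
iterative and forward-additive: the (Gaussian pre-smoothed, sigma 1 px)
target and its central-difference gradients are warped to the current
estimate, the Jacobian of pixel values with respect to the 6 affine (or
3 Euclidean) parameters is assembled on the valid support, and the
closed-form ECC update step is solved. Steps that would decrease rho are
halved up to five times (backtracking), so the accepted rho sequence is
non-decreasing and the best iterate is returned. Iteration stops when the
rho gain falls below 1e-6, the parameter update norm below 1e-8, or after
50 iterations. A result counts as converged only if the final rho reaches
0.3 and the determinant of the linear part stays within [0.2, 5]; patches
failing either guard keep the identity transform (the rigid-only result)
with diagnostics recorded — a deliberate fallback for patches without
landmarks. The support shrinks to in-bounds pixels every iteration, and a
caller-supplied validity mask is warped along with the target so borders
introduced by earlier resampling never enter the objective.

The rho floor, tolerances and iteration cap are configuration defaults
(`ecc_config()`), not constants of the method; they are deliberately
conservative and all overridable.

## Across-session registration

To track the same neurons across days, the summary images (mean and max
projections) of a "moving" session are registered onto a reference
session in two steps. First, a Euclidean transform (rotation + shift —
the dominant across-day mismatch, including objective-rotation angle) is
fitted by ECC maximization with pyramid initialization from level 3, run
separately on the normalized mean pair and max pair; the transform with
the larger full-field rho wins and is applied to both moving summaries.
Second, an `M x M` grid (default 8, independent of the within-session M,
since across-day distortion is smooth) of affine transforms is fitted
without a pyramid — large displacements are already gone — again per
patch on both summary pairs with per-patch winner selection. A patch can
be matched through the mean image where the max image lacks landmarks and
vice versa; if both fail, the patch keeps the identity. The result is
`M^2 + 1` matrices that transport any image of the moving session (frames,
projections, correlation images, ROI masks) into the reference frame.
Intensity images are transported with bilinear stitching by overlap
averaging; label masks use nearest-neighbor sampling with majority vote
in overlaps, which never invents new label values.

## Quality metrics

Two scalar metrics quantify registration without ground truth. mMD (mean
max-intensity difference) compares pixel means of max projections taken
after 50-frame averaging (which suppresses noise contributions to the
max): motion smears structures across more pixels of the projection, so
successful registration makes the post-minus-pre difference negative.
mCM (mean correlation with mean image) is the average Pearson correlation
of individual frames with a mean image — the stack's own mean ("self") or
the compared condition's mean ("cross"); registration increases both. All
frames enter the mCM by default (a stride option exists for speed), and
metrics run over the full field including borders, which edge-replicated
fills keep valid.

## The synthetic generator

Tests and the acceptance script run on seeded synthetic movies with known
ground truth. The generator emulates exactly the structure the method
assumes: Gaussian-blob somata (radius 3–6 px) or curvilinear axons on a
dim textured background; calcium transients with Poisson event times,
instantaneous rise and exponential decay (tau = 15 frames, GCaMP6s-like);
per-frame translational jitter as a bounded random walk (sigma 1 px,
reflected at ±8 px); a slow non-uniform distortion, ramped linearly over
the session and rendered through the same patchwise warp-and-stitch
operator the correction uses (so inversion tests are self-consistent);
and Gaussian read noise plus variance-matched Gaussian shot noise (a
standard approximation to Poisson photon noise — registration is
insensitive to the exact count distribution). Per-patch distortion
parameters are drawn as a spatially smooth field by default (bilinear
interpolation between four random corner values): real slow distortions
are smooth across the field, and spatially independent patch transforms
would make the stitched rendering ambiguous in overlap zones. An
independent-field mode exists as a stress condition. For across-session
tests, two sessions share one scene but have independent transients and
noise, 10% of cells silenced in one session, and the moving summaries are
additionally resampled through a rotation + shift followed by barrel
distortion `r' = r (1 + k r^2)` about the field center; the default
`k = 1e-7 px^-2` displaces a 512x512 corner by about 4.7 px.

What the generator does not emulate: optical point-spread blur, line-scan
(rolling-shutter) artifacts within frames, and the fast image distortions
caused by midline-sinus dilation. The last is a genuine limitation of the
method itself, which estimates transforms from multi-frame means and
therefore corrects slow distortions only; passing tests on this generator
says nothing about fast distortion robustness. For such data, a stable
structural channel (e.g. a red co-expressed indicator) is the appropriate
registration target.

## Problem sizes and reproducibility

Validation runs at desk scale, chosen to exercise the standard parameters
while remaining comfortable on one CPU: within-session checks use
2000-frame 256x256 sessions with `M = 4` and `M = 8` (four 500-frame
blocks), rigid oracle-equivalence checks use 64x64 scenes with shifts up
to ±8 px against exhaustive and 0.05-px dense-search oracles, and
across-session checks use 512x512 summary pairs with 5° rotation,
(10, −7) px shift and the default barrel coefficient. Every random draw
derives from an explicit seed with documented draw order; the pipeline is
serial and deterministic, so identical seeds give bit-identical outputs —
we chose determinism over parallel throughput, which also makes results
independent of any worker configuration. Transform containers (warp
fields, session transforms, ground truth) serialize to JSON; movie stacks
to multi-page TIFF. The TIFF writer stores unsigned 16-bit samples;
signed 16-bit data (as produced by some acquisition systems) use a
documented +32768 bias reversed at read time, and a 32-bit mode covers
float data at a caller-chosen range.

## Known limitations

* Only slow distortions are corrected; within-block (< ~17 s) distortion
  changes average into the block mean. Smaller blocks trade robustness
  (fewer landmarks per mean) for speed of tracking.
* Patches lacking landmarks in all summaries fall back to identity; the
  diagnostics matrix should be inspected when many patches fail.
* The rigid stage treats frames as rigid units; line-by-line correction
  within frames is out of scope.
* Cross-session cell identification (matching ROIs) is not provided —
  only the geometric transport of images and masks.
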