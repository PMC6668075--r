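---
title: "Methods: segmenting, aligning and measuring wheat grains in micro-CT"
author: "graintomo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmenting, aligning and measuring wheat grains in micro-CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(graintomo)
```

This vignette explains the models and procedures behind `graintomo`, the
assumptions they rest on, the parameters that matter, and the choices made
where the design was genuinely open. Nothing here states a result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The imaging situation

A fresh wheat grain is scanned inside a gelatin capsule with a droplet of
paraffin to hold it. The reconstruction is a stack of 16-bit grayscale
transverse slices at an isotropic resolution of roughly 4--15 µm/voxel.
Three intensity populations dominate: dark background (air and the enclosed
lysis cavities), intermediate paraffin, and bright plant tissue (with the
capsule wall similarly bright). The grain's tissues — pericarp shell outside,
endosperm-dominated core inside — have nearly identical attenuation, so the
outer/inner distinction cannot come from intensity; it comes from geometry:
the shell is a thin bright layer separated from the compact core by
discontinuous dark voids left by mesocarp lysis.

Conventions used throughout: arrays are indexed `[x, y, z]` with `x` the
image column, `y` the image row, `z` the slice; XY is the transverse view,
ZY frontal, XZ sagittal. Voxels are isotropic; anisotropic input is rejected
rather than resampled, and the voxel size is always supplied explicitly
(TIFF tag dialects are too unreliable to parse silently).

## Grain segmentation

The pooled histogram of all slices is trimodal. After moving-average
smoothing (default window 5 of 256 bins — on 16-bit data the modes are broad
and finer binning only adds ripple), interior local minima are accepted as
valleys when their prominence exceeds 0.5% of the total voxel mass; the
threshold is the highest-intensity valley, i.e. the one separating the
paraffin mode from the bright grain mode. This is equivalent to taking the
second interior peak of the complemented histogram. Fewer than two valleys
raise a classed `degenerate-histogram` error carrying the count, so a caller
can fall back to a bimodal method deliberately rather than silently.

Thresholding is strict (`intensity > t`). The grain is the largest
26-connected component — the capsule wall is bright too, but smaller — and a
ball median filter (radius 2 by default, 2--3 in routine use) removes
speckle. Because a median filter can split a component, a second
largest-component pass follows; downstream stages require exactly one
component. Component ties break deterministically on the lowest minimum
linear index. A slice-wise 2D median (`median_2d`) is kept as an option for
fidelity experiments; 3D is the default.

## Morphology kernels

Spherical structuring elements are the discrete balls
$\{o : \|o\|_2 \le r\}$. Erosion and dilation with a ball are computed
through exact squared Euclidean distance transforms (two-pass parabolic
lower envelopes per axis): a voxel survives erosion iff its squared distance
to the nearest background voxel — with everything outside the image counted
as background — exceeds $r^2$. This is voxel-identical to the defining
min/max sweep (the test suite checks equality against an independent
shift-and-intersect oracle on random masks) while costing $O(n)$ instead of
$O(n\,|B|)$. Arbitrary elements fall back to an explicit sweep kernel.

Voids are enclosed background: 6-connected background components (the dual
connectivity of the 26-connected foreground, avoiding the usual connectivity
paradoxes) that do not touch the image border. The open crease channel is
border-connected and therefore never counted.

## Tissue partition

The inner compartment is the largest 26-connected component of the opening
of the grain mask with a ball whose radius exceeds the shell thickness;
the outer compartment is the set difference, so outer and inner partition
the grain foreground exactly. The radius is a per-scan choice (it depends on
resolution and pericarp thickness); when not supplied, a heuristic estimates
the shell thickness as the median distance from the void-adjacent inner
shell surface to the outside and multiplies by 1.25 — enough to remove the
shell while sparing the core — and it always remains overridable.

With `downsample = 2` the opening runs on a block-decimated half-resolution
mask with the radius halved (rounded half-up) and the result is upsampled by
nearest-neighbour replication and intersected with the full-resolution grain
mask. Decimation/replication preserves binarity; the intersection preserves
the partition invariant. On phantoms with features of at least 4 voxels the
inner volume changes by well under 5%.

The method has two documented failure regimes, both inherited from the
physics rather than the implementation. When the shell is thick and voids
scarce (early development), the grain is quasi-solid and the opening keeps a
large region that is not the core; when voids are missing in patches (late
development), the opening leaks through the unlysed bridges. No geometric
property of the opened set alone can detect this — the opening of a solid
blob is the blob — so the pipeline scores the partition by *void support*:
the fraction of the inner compartment's surface lying within 3 voxels of a
void or of the background. On the preset phantoms the
well-segmentable regimes score clearly above, and the thick-shell regime
clearly below, the warning threshold of 0.7, which was placed inside the
empirical gap between them (the acceptance suite asserts the resulting
stage statuses). An opening that removes the whole
grain raises `se-too-large` carrying the largest feasible radius (found by
bisection on the erosion).

## Alignment

Each transverse section is summarised by the orientation of its equivalent
ellipse, $\theta = \tfrac12\,\mathrm{atan2}(2\mu_{11},\,\mu_{20}-\mu_{02})$
mapped to $(-90^\circ, 90^\circ]$. Orientations have period 180°, so windows
of slice angles are combined by the axial circular mean (double, average on
the circle, halve), weighted by section area so that sliver sections near
the grain tips — whose orientations are dominated by rasterization — cannot
bias the estimate. Internal voids would bias the second moments, so
sections are hole-filled before the moments are taken. Isotropic sections
return 0 with an `isotropic` flag; collinear or near-empty sections raise
`degenerate-slice` and are skipped with a count.

The pose is estimated sequentially: the rotation about Z from up to 200 XY
slices centred on the middle slice, then — after an intermediate
nearest-neighbour resample — the rotation about Y from XZ slices around the
middle Y slice. This order is exactly consistent with a forward pose
$R_z(\theta_z)R_y(\theta_y)$: $R_z$ acts slice-wise in XY and $R_y$
slice-wise in XZ, so each estimate sees its own angle undistorted. The final
output is resampled once from the original mask with the combined inverse
map (nearest-neighbour by default to preserve binarity;
interpolate-then-threshold at 0.5 is available). The window is clipped
symmetrically when the grain spans fewer slices.

Orientation leaves a two-fold ambiguity about Y. The crease side is read
from the concavity evidence itself: over sampled central sections, the
convex-hull concavity mass is split between the two Y half-sections, and if
it predominantly lies below the section centroid the grain is flipped about
the XZ plane, so the crease always opens toward +Y. (A simpler
centroid-versus-midline statistic was considered and rejected: for shallow
notches the extent shift almost cancels the centroid shift, making its sign
unreliable on segmented masks.)
No rotation about X is applied (the embryo-end disambiguation has no
counterpart in the phantoms and the crease measurements do not require it);
`theta_x` is carried as 0 in the pose record. Residual angles are
re-estimated on the output; on phantoms the recovery error stays within 2°
over a ±40° grid in both angles and realignment is an identity within 1°.

A grain whose rotated extent exceeds the target grid raises
`target-too-small` with a suggested size. The canonical full-scan target is
1000×1000×1200 voxels; phantom work uses smaller grids, which is a pure
scale choice.

## Morphometry

Length is the Z extent of the aligned bounding box; width and thickness are
the mean Y and X extents of 2D bounding boxes over the same 200-slice
central window used by the alignment (internal consistency; the window is a
parameter). By the crease-up convention, Y is the crease-to-dorsal dimension
(width) and X the across-lobe dimension (thickness). Volumes are voxel
counts scaled by voxel_size³, so the partition identity
`vol_inner + vol_outer = vol_grain` is exact by construction, and all
quantities obey the exact scaling law (lengths ∝ s, volumes ∝ s³).
Replicate summaries use the sample (n−1) standard deviation, reported as 0
for singletons.

## Crease depth

Per slice: the convex hull of the hole-filled section minus the section
itself is the concavity region; internal holes are removed first so an
annular section has no concavity, and a convex section legitimately yields
`no-concavity`. When several concavities exist (a dorsal indentation occurs
early in development), only the ventral one — centroid on the +Y side — is
measured. The region's outer boundary is traced into an ordered closed
curve by Moore-neighbour walking; on a binary mask this *is* the gradient
edge, ordered. Termination is by repeated walk state (pixel, backtrack
direction), which survives one-pixel isthmuses that a plain
visited-start criterion would truncate.

Corners come from Chord-to-Point Distance Accumulation: for each scale
$L \in \{10, 20, 30\}$ samples, the perpendicular distances from each curve
point to every chord of $L$ samples spanning it are accumulated, each scale
is normalised to $[0,1]$, and the product across scales is the corner
response. Local maxima above 0.2 are corners unless their opening angle
(to neighbours ±5 samples away) is blunter than 157°. The small angle span
matters: normalisation makes even a circle's response approach 1
everywhere, and with ±5 samples a circle of radius 20 px still presents an
angle above 157°, so constant-curvature curves yield zero corners across
radii 20--100. The curve is pre-smoothed with a circular Gaussian
(σ = 1.5 px); reported corner positions are the unsmoothed points. Chord
lengths are clipped for short boundaries, and curves too short for any
scale yield `detector-failed`.

Among the three strongest corners, the apex is the one farthest from the
convex-hull chord that closes the concavity (the crease mouth), and the
depth is that perpendicular distance. Selecting the *deepest* corner rather
than an extreme-Y corner is deliberate: with the crease opening toward +Y,
the maximal-Y corners are the mouth corners sitting on the chord at zero
distance, whereas the deepest corner is the crease apex under any slice
orientation; on constructed wedge and rectangular notches it reproduces the
nominal depth within 2 px. The reading of "distance to the opposite side"
as depth-below-the-mouth-chord measures indentation depth and is verifiable
on constructions; the alternative reading — distance across to the dorsal
boundary — is available as `depth_mode = "dorsal"`.

Failures are never raised per slice; they are encoded per measurement
(`no-concavity`, `detector-failed`) so a profile shows *where* detection
broke, as it genuinely does when a deep narrow crease's lobes touch and
seal the channel. A profile with under 10% valid slices raises
`profile-failed`. Profiles are resampled by linear interpolation onto 100
points over relative grain length for replicate averaging; the mean profile
excludes missing points pointwise and reports contributing counts.

## The phantom generator

The generator produces scans the pipeline can be validated against with
voxel-exact truth. A cross-section is an ellipse with semi-axes
`lobe_radius + lobe_separation/2` (X) and `lobe_radius` (Y), tapered
elliptically along Z, notched from +Y by a triangular wedge whose depth
follows d(z), a sum of parabolic bumps over normalized length (one bump
gives the parabolic mid-grain profile; two bumps give the mid + top shape
seen in developing grains). An ellipse-with-notch was chosen over a union
of two discs so that a zero-depth phantom is convex on every slice — a
property the crease tests rely on. The wedge construction makes the true
depth equal to the apex-to-mouth-chord distance analytically.

Nested offsets of the same shape produce the shell (thickness `t`), a gap
(`gap_width`), and the core; the gap is filled by voids over a seeded,
smoothed random angular field covering `void_fraction` of it, the remainder
bridging shell to core as unlysed tissue. The default coverage is 0.85:
in the well-segmentable mid-development regime the voids surround the core
except at sparse bridges (the vascular bundle region), and those bridges
are precisely where opening-based tissue separation legitimately leaks.
The core and gap stop `end_cap` voxels short of the grain tips (default
`max(4, 2t)`), leaving solid tissue caps — real endosperm does not reach
the extremities, and without the caps a one-voxel rim would let the median
filter connect the entire void network to the outside. A thin bright
capsule-wall cylinder (smaller in volume than the grain, so component
selection is genuinely exercised) and mid-intensity paraffin fill the
scanner frame; the grain itself can be posed with $R_z, R_y$ and a
translation, evaluated analytically in the posed frame so no resampling
error enters the truth. Gaussian noise is added last; a single seeded
stream drives void placement and noise, and generation is bit-reproducible.

Presets encode three developmental regimes. `mid` is the well-behaved
case. `early` has a shell thicker than the core radius, few voids, and a
field sized so the small grain still occupies a realistic fraction of the
volume (early stages were scanned at finer resolution, so the grain fills
a comparable share of the field at every stage). `late` has a thin shell,
a deep narrow crease and *touching lobes*, modeled by a tissue roof
(`crease_bridge`) sealing the crease mouth over the lower 45% of the grain;
the sealed channel becomes an enclosed cavity and per-slice crease
detection fails there, which is exactly the fluctuation the pipeline must
flag rather than report silently wrong depths.

What the phantoms do not emulate: beam hardening, ring artifacts, partial
volume blur, the embryo, intensity gradients within tissues, and
non-ellipsoidal lobe asymmetry. Passing the phantom suite therefore
demonstrates correctness of the geometry and the measurement chain under
realistic topology, contrast and noise — not robustness to every
reconstruction artifact of a real scanner.

## Problem sizes and numerical choices

The validation suite runs phantoms at 192³ voxels (lobe radius 50, shell 6,
gap 4) for segmentation, tissue, void, morphometry and profile checks, and
96×96×112 phantoms for the 17×17 pose grid; these sizes were chosen so the
whole suite completes comfortably on a single core while keeping every
feature ≥ 4 voxels, the scale at which the downsampling acceleration is
specified to be faithful. Other fixed choices: strict `>` thresholding;
component ties by lowest minimum linear index; erosion treats out-of-image
as background; axial means via doubled-angle vectors; nearest-neighbour
mask resampling; hull rasterisation includes boundary pixels via a 1e-7
half-plane slack; the CPDA response threshold 0.2 and 157° rejection follow
the detector's published settings.

## Known limitations

Tissue separation inherits the opening's blindness to unlysed bridges and
solid end caps; the void-support score flags, but cannot repair, those
regions. Crease depth under `"chord"` mode measures indentation relative to
the crease mouth, which differs from dorsal-distance readings when the
mouth itself is deeply recessed. The embryo is not separated and is counted
with the inner compartment. Multi-grain scans are out of scope (one grain
per acquisition), as are acquisition and reconstruction.
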