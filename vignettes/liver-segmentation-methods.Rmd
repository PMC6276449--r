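---
title: "Automatic liver segmentation from CT slices: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic liver segmentation from CT slices: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sddliver)
```

## The problem

The liver in an axial abdominal CT slice borders organs whose intensities can
be indistinguishable from its own (stomach, kidney, heart, body-wall muscle).
A single global threshold therefore cannot delineate it.  `sddliver`
implements a heuristic, fully automatic pipeline: it derives *several*
thresholds from the slice histogram, segments the bright bones, the whole
body and the adjacent organ with them, converts those segmentations into
spatial *constraints*, and only then thresholds the liver inside the
unconstrained region.  Per-slice boundaries are finally smoothed, resampled
and stacked into a 3D surface.

## Multilevel thresholding from the slope difference distribution

The slice is rescaled to intensities $\{1,\dots,255\}$ and its histogram
$P(x)$ is normalized by its largest bin (so $\max_x P = 1$; this is a
max-normalization, not a density).  $P$ is band-limited with a low-pass DFT
filter that keeps the DC bin, the $W$ lowest positive frequencies and their
conjugate mirrors; the default bandwidth is $W = 12$ bins.  At every interior
intensity $i$ two lines are fit by ordinary least squares through the $N$
smoothed-histogram points ending at $i$ (left window) and the $N$ points
starting at $i$ (right window); the default window is $N = 20$.  The slope
difference

$$s(i) \;=\; a_l(i) - a_r(i), \qquad i = 1+N,\dots,255-N,$$

dips to a negative valley wherever a falling histogram arm meets a rising one
— i.e. at class-separating intensities — and peaks at class modes.  The sign
convention is chosen so that boundaries are the *valleys* the detection rule
looks for: index $i$ is a valley when $s(i)<0$ and $s(i)\le s(i\pm1)$
(plateaus contribute their central index, floor of the midpoint).  Two
numerical guards keep the discrete rule robust: valleys closer than 8
intensity levels are merged keeping the deeper one (band-limited histograms
ring slightly), and dips shallower than $10^{-12}$ are ignored (floating-point
noise on flat stretches).

Where classes overlap (the common case in soft-tissue CT, where neighbouring
classes sit 2–3 noise standard deviations apart), the valley of $s$ lies near
the density crossing of the two classes.  Where classes are widely separated,
the curvature of the histogram concentrates on the *shoulders* of each mode
and $s$ instead shows one valley per shoulder, with a flat stretch over the
empty gap; any of these valleys is a serviceable segmentation threshold
(every point of the gap separates the classes), but the valley is then not at
the density crossing itself, and a single boundary may contribute two
valleys.  The role-assignment rule below is designed to be robust to this.

### Threshold roles

With the detected valleys sorted ascending, `assign_threshold_roles()` maps
them to the four anatomical thresholds:

* `T2` (body) — the lowest valley (background/body split);
* `T1` (bones) — the highest valley (soft tissue/bone split);
* `T4` (liver) — among the classes bounded *below* by an interior valley,
  the most populated one (smoothed-histogram mass between its bounding
  valleys) is taken to be the liver; `T4` is its lower bounding valley;
* `T3` (adjacent organ) — the next valley above `T4`; with three valleys it
  falls back to `T1`, with two to `T2`.

The class-mass rule is what makes the assignment immune to shoulder-splitting
of wide gaps: a gap "class" between two shoulder valleys carries almost no
histogram mass and never wins.  The number of valleys adapts by itself to the
number of tissue classes in the slice, which is how the three adjacency cases
(stomach, kidney or heart next to the liver) are handled without case
detection: when the adjacent organ is separable by intensity it gets its own
valley and `T3`; when it is not (organ at liver intensity), `T3` falls back
and the organ constraint simply deactivates.

### Calibration

$W$ and $N$ interact: the window should roughly match the smoothing scale
(the defaults $W=12$, $N\approx255/W$ do).  `calibrate_sdd()` grid-searches
$(W, N)$ maximizing mean Dice on any labeled slices, deterministically
(ties resolve to the first cell, $W$ outer, $N$ inner).

## Binary denoising by clique-energy minimization

Thresholded masks are cleaned under a pairwise Ising prior on the
4-neighbourhood: a neighbour pair contributes $-\beta$ when the labels agree
and $+\beta$ otherwise ($\beta = 1$ by default; the fixed point does not
depend on it).  The printed objective has no data-fidelity term — its global
optimum is a uniform image — so the minimization is run as iterated
conditional modes (ICM) *from the observed mask*: raster-order sweeps in
which each pixel takes the majority label of its neighbours (ties keep the
current label), stopping at the first sweep with no flips, capped at 20
sweeps.  This is deterministic, monotonically energy-decreasing, and stops at
a single-flip local minimum — exactly the "remove label inhomogeneity while
retaining structure" behaviour the pipeline needs.  A simulated-annealing
solver would approach the degenerate global optimum and was deliberately not
used.

## Morphological filtering and merging

The structuring element is the 4-connected radius-1 disk — the 5-pixel
diamond.  $n$ repeats compose to the radius-$n$ L1 ball (a diamond, not a
Euclidean disk); users should expect diamond-shaped rounding.  The
*morphological filter* is $N_F$ erosions followed by $N_F$ dilations
(default $N_F = 8$): an opening that removes every blob whose inscribed
diamond radius is below $N_F$, even when attached to a larger structure.
The *morphological merge* is the opposite — $N_M$ dilations then $N_M$
erosions (default $N_M = 16$), a closing that unites parts of a split organ
separated by small gaps.  Pixels outside the image are background for both
operations (masks are zero-padded before each kernel pass), so structures
touching the frame are not artificially propped up; the merge additionally
pads by $N_M$ so the closing is exact near the frame.  Blob labelling uses
8-connectivity (diagonal bridges in rib chains should not split); structuring
elements themselves are 4-connected.

## Anatomical constraints

Three constraint masks restrict the liver threshold:

1. **Rib curve.**  Bone blobs (threshold `T1`) are split at the body-centroid
   column: blobs clearly left of it (beyond a 2 % tolerance band, since the
   spine sits *around* the centre) are ribs, and the largest remaining blob
   is the spine.  A least-squares quadratic `col = f(row)` through the rib
   and spine centroids separates the liver from body-wall tissue of the same
   intensity.  The excluded half-region is the side *not* containing the body
   centroid; the body centroid is used as the interior reference because the
   spine centroid is itself a fit point of the curve (its residual is near
   zero, so its side is numerically unstable).  Pixels exactly on the curve
   count as interior.
2. **Body ring.**  The body mask (threshold `T2`, then the morphological
   filter) is eroded $N_c$ times, where $N_c$ is the average rib width —
   twice the mean maximal inscribed diamond radius of the rib blobs — and
   subtracted from itself, leaving a margin ring of thickness $N_c$ that
   covers the body-wall band adjacent to the liver.
3. **Adjacent organ.**  Threshold `T3`, ICM denoising, bone subtraction,
   morphological filtering, retention of components whose centroid column
   lies strictly beyond the spine centroid column ("right of the spine"),
   then the morphological merge.  An empty result is valid and simply
   deactivates this constraint.

The liver is then `T4`-thresholded where all three constraint masks are zero,
denoised by ICM, opened, and reduced to its largest 8-connected component
(ties broken toward the top-left-most component).  A flag `orientation.flip`
mirrors the slice for acquisitions with the flank on the other side.

## Boundary extraction and smoothing

The outer boundary is traced with Moore-neighbour tracing (8-connected,
started at the top-left-most pixel, terminated when the first move repeats),
then normalized to counter-clockwise orientation.  Smoothing minimizes

$$(1-\alpha)\sum_j \|B_s(j)-B(j)\|^2 \;+\;
  \alpha \int \left\|\tfrac{d^2B_s}{dt^2}\right\|^2 dt,$$

discretized per coordinate with second differences on the vertex index
(a Whittaker-type penalized fit; periodic for closed contours, solved exactly
in the Fourier domain).  The default is $\alpha = 0.5$; $\alpha = 0$ returns
the input exactly, and $\alpha$ is clamped below 1 because the
curvature-only objective degenerates (it shrinks closed curves).  The
penalty is discretized on the vertex parameterization rather than exact arc
length; for pixel-spaced contours the two differ by at most the
$1$-vs-$\sqrt2$ step ratio, and the subsequent equal-arc-length resampling
removes any residual parameterization bias.  A circle is an effective fixed
point: its coordinates are single-frequency harmonics which the periodic
penalty attenuates by less than $10^{-5}$.

## 3D reconstruction

Each slice boundary is resampled to 200 points at equal arc-length intervals,
start indices are aligned down the stack (cyclic rotation minimizing the
summed squared distance to the previous aligned contour, after making all
orientations consistent), and the points are placed at physical coordinates
`x = col * pixel_spacing`, `y = row * pixel_spacing`,
`z = slice_index * slice_spacing` (1 mm defaults when headers are absent).
Each of the 200 z-trajectories is then smoothed with the same penalized
criterion (open-curve variant).  The printed form of the stacking objective
indexes the in-slice points; it is implemented per z-trajectory as the
surrounding description of "curved lines in the stacking direction" requires.
Slices whose segmentation failed are filled by linear interpolation of the
aligned trajectories between the nearest valid neighbours.  The surface is
exported as a triangle mesh (PLY or OBJ), periodic around each ring, with
optional centroid-fan caps making it watertight; `mesh_volume()` integrates
the enclosed volume by the divergence theorem.

## The synthetic phantom

`generate_slice()` draws a deterministic abdominal phantom (default
220 x 220 px): an elliptical body (intensity 60) on dark background (15),
five bright rib blobs (230) along the left flank at 84 % of the body radius,
a spine blob at the posterior centre, a large liver ellipse (120) in the left
half, a flank muscle wedge at *liver* intensity reaching inward past the rib
line (the same-intensity tissue the rib curve and body ring exist to
exclude), and a case-dependent adjacent organ touching the liver: a
two-lobed bright stomach (165, anterior, exercising the merge), a bright
kidney (160, posterior), or a heart at exactly the liver intensity
(superior), which exercises the fallback path where intensity cannot
separate the organ.  Gaussian noise (default sd 6, a realistic soft-tissue
noise level on the 255-level scale) is added and clipped.  Identical spec and
seed give identical bytes, and the generator restores the caller's RNG
state.  `generate_stack()` sweeps the liver cross-section along z with a
constant (cylinder) or spherical profile, giving an analytic ground-truth
volume.

What the phantom does *not* emulate: beam hardening, streak artifacts,
partial-volume gradients at organ interfaces, textured parenchyma, irregular
liver shapes, and contrast-dependent intensity shifts.  Passing the phantom
study therefore shows that the pipeline's logic (threshold recovery, role
assignment, constraint geometry, reconstruction) is correct under its own
modelling assumptions — not that the fixed default parameters transfer to any
clinical scanner protocol; on real data $(W, N)$ are expected to need
recalibration, as the calibration utility provides.

With an organ at exactly the liver intensity and in contact with it, no
intensity- or constraint-based rule can separate the two; the segmentation
then includes the organ sliver and the per-slice Dice degrades gracefully
(about 0.91 for the phantom's heart geometry versus about 0.96 for the
separable cases), which is the intended, documented behaviour of the
heuristic rather than a failure mode.

## Evaluation metrics

`evaluate_segmentation()` implements the community-standard definitions:
VOE $=100(1-|A\cap B|/|A\cup B|)$, RVD $=100(|A|-|B|)/|B|$, and the
symmetric surface distances ASD / RMSD / MSSD as the mean / RMS / max of all
nearest-neighbour distances between the two border-voxel sets (face-adjacent
background defines a border voxel; voxels on the array frame count as
border), scaled by the physical spacings.  Border voxels rather than meshed
surfaces are used — the usual convention in liver-challenge tooling — so the
distances are upper bounds within half a voxel of the sub-voxel surface
values.

## Numerical and scale choices

Problem sizes used by the tests and the acceptance script were chosen to
exercise every code path at desk scale: 220 px phantom slices, a 30-slice
phantom study (10 seeds per adjacency case), 30-ring analytic solids for the
reconstruction checks, and exhaustive enumeration up to 4 x 4 masks for the
ICM local-minimum proof.  At these sizes the full suite runs in well under a
minute on one CPU.  All randomness is seeded; the pipeline itself contains
no randomness and is bit-reproducible.

## Known limitations

* The thresholds presume the canonical intensity ordering
  (background < body < liver ≤ organ < bone) and at least two detectable
  valleys; slices violating it come back as flagged empty results.
* In the resolved-histogram regime a wide inter-class gap yields one valley
  per shoulder rather than one at the density crossing (see above); role
  assignment tolerates this, but the reported threshold is then not the
  crossing point.
* "Left flank" geometry is assumed (configurable only by mirroring); oblique
  or heavily rotated acquisitions are out of scope.
* DICOM input is not supported; PNG/TIFF slice directories and NIfTI volumes
  are.
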