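---
title: "Methods: a simulation phantom for mitral valve MR imaging strategies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a simulation phantom for mitral valve MR imaging strategies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvphantom)
```

## Why a phantom

Whether an MR slice-planning strategy captures the mitral valve well cannot
be settled on acquired images: the true valve geometry of a patient is
unknown, so segmentation error and acquisition error cannot be separated.
`mvphantom` builds the experiment the other way around.  Every piece of the
anatomy is parametric and therefore known exactly; the imaging process and
the human annotator are then simulated on top of it, so any discrepancy
between "what was annotated" and "what is there" is attributable to the
sampling strategy and the annotation noise, both of which are under the
experimenter's control.

## Anatomy

The **annulus** is the classic bileaflet saddle,
`p(θ) = c + a cosθ e1 + b sinθ e2 + h cos2θ e3`, with defaults
`a = 20 mm`, `b = 15 mm`, `h = 3 mm`.  The `cos 2θ` term puts the high
points at the anterior (aortic) and posterior horns and the low points at
the commissures, which is the accepted first-order description of the human
mitral annulus, and it makes the ground-truth "annulus height" nonzero
(full extent `2h = 6 mm`).  Dropping the `e3` coordinate of the saddle
curve recovers the flat ellipse exactly, which is what the projected
annulus area (`πab ≈ 942 mm²`) relies on.

Two **leaflets** are lofted from the annulus halves to free-edge curves that
droop `leaflet_depth = 22 mm` towards the ventricle and are separated by
`orifice_gap = 16 mm` across the coaptation plane in the open state.  Those
two defaults were chosen together from anatomy and mechanics: 22 mm is in
the range of human anterior-leaflet lengths and — this is the binding
constraint — long enough that the free edge can reach the coaptation plane
without stretching the sheet (the taut limit for this annulus is ≈17 mm);
a 16 mm gap gives an open orifice area of `π·a·(gap/2) ≈ 5 cm²`, a normal
human value.  Mesh density is chosen iteratively so the mean triangle area
matches a 0.55 mm² target, the density of the reference segmented valve
model this phantom stands in for.

The **thorax** (lungs, bronchi, rib arcs and spine, liver, kidney, aorta,
four chambers as wall/cavity ellipsoid pairs) is deliberately schematic:
ellipsoid and sphere-swept-tube primitives painted back-to-front so that
cavities hollow their walls.  Its purpose is a complete label inventory
with roughly correct sizes and positions around the valve, not realistic
organ shapes.  Components are fused by rigid landmark alignment (ten named
landmarks: four valve centres, apex, septum centre, four aortic
centreline markers).  Because correspondences are known by name, the
iterative closest point problem collapses to a single closed-form
orthogonal Procrustes step (SVD with a determinant guard against
reflections); with exact landmarks the residual is numerically zero, and
the unit tests verify recovery of arbitrary rigid poses to 1e-6 mm.

The valve surface is **rasterized** into the label volume by exact
point-to-triangle distance: a voxel is labelled when its centre lies within
half the surface thickness (default 1 mm) of any triangle.  This is slower
than scan conversion but exact at the 1 mm scale of the leaflets, and it is
evaluated only inside per-triangle dilated bounding boxes.  The valve label
may overwrite the atrial and ventricular blood-pool labels (otherwise the
thin leaflet would vanish inside the cavities) but never walls or other
organs; the overwrite set is configurable.

## Valve closure

Closure is simulated with position-based dynamics over 180 frames with the
annulus pinned.  Each frame (1) the free-edge vertices are driven towards
the coaptation mid-plane — every free-edge vertex scales its mid-plane
coordinate by a common closing factor, so the leading edge advances at
`closing_drive = 0.05 mm/frame` and closure completes around frame 160 —
(2) edge-length and cross-edge bending constraints are projected for 20
sweeps, and (3) a mid-plane barrier keeps each leaflet on its own side and
forbids the free edge from retreating, which makes the approach of the two
free edges monotone by construction.  Constraint projection uses a greedy
graph colouring of the constraints: the constraints in one colour share no
vertex, so each colour is projected in a single vectorised step with
immediate (Gauss–Seidel) effect between colours.  The result is
deterministic and independent of constraint storage order; an optional
position jitter is the only stochastic element and is off by default.

One property deserves honesty rather than tuning: edge-to-edge closure of
this sheet is not an isometry.  The closed free edge, draped taut from the
fixed annulus, is several percent shorter than the open free edge for any
anatomically plausible depth/gap combination, so some membrane strain at
the coaptation phase is geometrically unavoidable.  With the default
configuration the RMS edge strain stays below 2.5% at every frame and
local peaks stay below 15%, concentrated in the final coaptation phase —
magnitudes comparable to the 10–30% strains reported for real leaflets in
vivo.  The test suite asserts exactly this contract.

Temporal sampling to the imaging frame rate (10 timesteps per closure)
supports two modes: `decimate` (frames at evenly spaced indices, endpoints
included) and `window_average` (vertex positions averaged over contiguous
equal windows).  Window averaging is the default because it emulates the
temporal partial-volume blur of cine imaging; for linear motion it returns
exactly the window-midpoint positions, which the tests verify.

## Image synthesis

Per timeframe the pipeline runs: rasterize the valve → assign per-tissue
Gaussian intensities → add zero-mean Gaussian noise (σ = 38, the largest
standard deviation among the heart-tissue intensity distributions) →
Gaussian reconstruction smoothing → slice extraction → two-step in-plane
resampling.  Tissue intensities are Gaussian; a Rician model is the
textbook alternative for magnitude MR data but at these signal-to-noise
levels the two are nearly indistinguishable, and the Gaussian is what this
package samples.

* **Smoothing kernel**: σ = 0.7 mm by default (about half the acquired
  pixel), specified in millimetres and converted per axis so anisotropic
  voxels are handled; kernel rows are renormalised at the borders so
  constant volumes are exact fixed points.
* **Slice geometry**: the valve axis is the smallest principal component of
  the mesh vertex covariance, oriented towards the atrial side (towards the
  annulus centroid by default, since the leaflets droop ventricularly).
  SAX planes share this normal with 6 mm thickness and 6 mm centre-to-centre
  spacing — i.e. contiguous slabs, the standard cine short-axis layout;
  "slice spacing" is interpreted as centre spacing and is configurable.
  rLAX planes all contain the axis and rotate by `180°/n`; a 360° span
  would duplicate every plane, so the half-circle is the only sensible
  reading, and 18 planes give 10° increments.
* **Slab sampling**: pixel value = mean of trilinear samples on 5 (odd,
  configurable) sub-planes across the 6 mm thickness.  Trilinear
  interpolation breaks ties at exact voxel boundaries towards the lower
  index (floor).  Out-of-volume samples take a configurable background fill
  and raise a warning.
* **In-plane chain**: box-average down to the acquired 1.4 mm, then linear
  interpolation up to the reconstructed 0.87 mm, both as separable 1D
  operators with rows normalised to one, so constants survive exactly and
  the acquisition step strictly reduces variance.
* **Randomness**: every stochastic stage derives its own 32-bit substream
  from the single study seed and a stage tag, so reruns are bit-identical
  and no stage depends on the RNG state another stage left behind.

## Annotation simulation

Annotators see slices, not meshes, so the ground truth offered to the
simulated annotator is the plane–valve cross-section.  On radial planes the
protocol is two annulus points (annulus curve ∩ plane), up to two leaflet
ends (free edges ∩ plane) and leaflet contour points every 2 mm.  On SAX
slices the section is computed on 5 sub-planes across the 6 mm slab and
projected to the slice centre plane — this is where the through-plane
ambiguity of thick-slice annotation enters the simulation, and it is the
mechanistic reason SAX performs worse: a structure sitting anywhere in the
slab is annotated as if it were at the slab centre, an error of up to 3 mm
that radial planes (which contain the valve axis) largely avoid.  Each
annotator then adds in-plane Gaussian click noise, σ = 1.5 mm per axis by
default — a free parameter of the simulation, not a measured human value;
it was chosen so that simulated inter-annotator contour distances land
around 2 mm on radial planes, the scale reported for expert annotation of
this valve, and the recovery study sweeps it (0–1.5 mm) rather than
treating it as truth.  Annulus/orifice points can additionally be missed
with a configurable probability.

## Quantification

Annulus diameters and height come from a PCA of the pooled annular points:
`Dmax` and `Dmin` are the extents (max − min of projections) on the first
two components and height the extent on the third.  Extent was chosen for
"height" because it matches the visual meaning of annular height glyphs;
`2·max|deviation|` is available as an alternative.  Components are ordered
by descending eigenvalue; for circular annuli the first two are degenerate
but the extents are tie-invariant, and component signs are canonicalised.
Areas are shoelace areas after projecting onto the annular plane; unordered
point sets (annotations pooled across planes) are ordered by angle about
their centroid first, and self-intersecting projections warn but still
report the shoelace value.  Bias is the mean signed difference over
annotators (`N = 3` by default).  Contour distances are exact
point-to-segment minima (annotation → ground truth, asymmetric), and
point-to-surface distances exact point-to-triangle minima; both are tested
against exhaustive brute-force oracles to 1e-9 mm.  Distance reports list
min, quartiles, mean, sd, max, and outliers by the standard 1.5·IQR
boxplot rule.

## What the generator does and does not emulate

The phantom reproduces the *geometry* of the problem — thin moving valve,
saddle annulus, slab partial volume, anisotropic sampling, annotation
noise — with known ground truth.  It does not simulate MR physics: no
k-space, coil sensitivities, flow or field-inhomogeneity artifacts, no
breathing or heart-bulk motion (the annulus is fixed), no chordae or
papillary muscles, and organ shapes are schematic.  A passing test
therefore says the *evaluation machinery and sampling geometry* behave as
specified; it does not certify performance on clinical images.

## Problem sizes

The default study runs a 110³ volume at 2 mm, a ~3000-face valve, 180
closure frames and 10 imaging timeframes.  The test suite exercises the
same code paths at reduced sizes (volumes of 32–64 voxels per side, 8–60
closure frames, 2–10 timeframes), which it states alongside each check;
the statistical contracts (noise sd on 10⁶ voxels, intensity recovery on
6.4·10⁴-voxel regions) run at full size because they are cheap.

## Known limitations

* The closure is kinematically driven, not pressure-driven; coaptation
  shape is plausible but not mechanical truth, and the coaptation-phase
  membrane strain discussed above is a model artifact of edge-to-edge
  closure.
* SAX annulus points are taken from section endpoints (spline extremes);
  deriving them from full contours is supported but not default.
* The annotator model is isotropic in-plane Gaussian noise with independent
  misses; real experts are biased (e.g. systematic under-segmentation),
  which this model cannot reproduce.
* Radial planes are rotated about a single axis estimated once from the
  open-valve mesh; scanner-side plane prescription errors are not modelled.
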