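---
title: "Filament detection, tracking and cell-event monitoring: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Filament detection, tracking and cell-event monitoring: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(filamentr)
```

This vignette is the package's own account of its methods: the models and
procedures, the parameters that matter, the numerical choices that were
genuinely open, and the limits of what a green test establishes. It states
no empirical result that the test suite does not itself compute.

## Coordinate and angle conventions

Images are matrices indexed `[row, col]`; a point is `(x, y)` with
`x` = column and `y` = row, origin top-left. Orientations are undirected,
in degrees in [0°, 180°), measured from the +x axis counter-clockwise in
display space (so the direction vector of θ is `(cos θ, −sin θ)`). All
modules share this convention; under image transposition orientations map
to `90° − θ (mod 180°)`, which a property test pins.

## Preprocessing

Filters are registered by name with a declared parameter schema
(`register_filter()`); a pipeline is an ordered list of named steps,
serializable as a JSON array and re-importable in batch mode. Adding a
filter touches no pipeline code. The shipped registry (gaussian, box mean,
Laplacian, invert, normalize) is nominal: real analyses tune their own
chain per fiber type and image quality, and the pipeline exists precisely
so that the chain travels with the data.

Binarization is deliberately decoupled: the tracer accepts any logical
mask, so externally produced masks can bypass preprocessing entirely.
Three methods are provided — global Otsu (default), local mean, fixed
threshold. Numerical choices: Otsu uses 256 bins over the intensity range
and takes the *first* maximum of the between-class variance (deterministic
tie-break); a constant image has no histogram structure and yields an
*empty* foreground rather than an arbitrary half-split; `fixed_threshold`
is strict (`> t`), making the foreground monotone non-increasing in `t`.

## The width map

For each foreground pixel, `compute_width_map()` stores the largest disk
diameter `d` centered there whose *miss fraction* — disk pixels on
background or off the image, over disk size — stays within `tolerance`
(default 0), growing `d` until the condition first fails. One
rasterization rule fixes all odd/even ambiguity: the disk of diameter `d`
contains the pixels whose center distance is ≤ `d/2`. The implementation
sweeps diameters with an FFT correlation over the shrinking set of "still
alive" pixels; a brute-force per-pixel disk-growing oracle (written
independently in the test helpers) must agree exactly on random masks,
which is the package's strongest internal check.

Two consequences worth knowing: thresholding the map at diameter 1
reproduces the mask exactly, and because growth stops at the *first*
failing diameter the map is not simply a rounded distance transform when
`tolerance > 0`.

## Curve tracing

Seeds are visited in decreasing width-map diameter order (row-major within
a diameter). At a seed the tracer probes all directions in increments of
`3° · ϕ_diff` with rays of length `2·ℓ_str` (seed pixel included — the
spec left inclusion open; including it biases all directions equally) and
selects the opposite pair maximizing the summed mean width, ties to the
smallest angle. Each side then grows stepwise: among the previous
direction and its two neighbors (± one increment) the direction with the
largest mean width over an `ℓ_str` ray is chosen; if the best mean width
is below 1 the side stops; otherwise the step is appended and trailing
points with pointwise width below 1 are trimmed back — a trimmed step just
sets a new endpoint, it does not stop growth. The two sides are joined at
the seed; candidates shorter than `ℓ_min` are dropped.

Ranking and acceptance are a second phase. Candidates are sorted by
(length, score, first point) — score being the width-sum the gatherers
accumulated — and validated longest-first against the orientation field:
a pixel conflicts if the field is set and differs by more than `α_tol`
(default 20°); acceptance requires the conflict fraction to be *strictly*
below 0.30 (exactly 0.30 is rejected); with conflicting endpoints the
filament is shortened inward to the first clean points and re-queued at
its new length; with clean endpoints it is discarded. Accepted filaments
mark their per-piece orientations into the field and claim their covered
pixels.

Two claim radii reconcile "a pixel claimed by a longer filament is not
re-used" with robust seeding: during candidate collection a traced
candidate claims its centerline dilated by its width + 1 px, which only
suppresses redundant *seeds*; accepted filaments claim width + 2 px, and a
later candidate whose centerline is mostly (> 50%) on claimed pixels is
dropped as a duplicate. The narrow first-phase claim matters: an
aggressive claim can starve the full-length trace of a curve whose best
seed lies under a neighboring candidate's band.

### Parameters and the capability envelope

| parameter | unit | default | role |
|---|---|---|---|
| `l_min` | px | 30 | minimal accepted filament length |
| `l_str` | px | 10 | straight-piece step length; seed probes use `2·l_str` |
| `phi_diff` | — | 1 | multiplier of the hard-coded 3° probing increment |
| `alpha_tol` | deg | 20 | conflict threshold against the orientation field |
| `conflict_fraction_limit` | — | 0.30 | strict acceptance limit |
| `tolerance` | — | 0 | width-map miss fraction |

The tracer has a *geometric capability envelope* that users must respect,
exactly as the original tool expects settings tuned per fiber type:

1. **Curvature capacity.** Per step the direction changes by at most one
   increment, so a curvature κ is trackable only if
   `(3° · ϕ_diff) / ℓ_str ≥ κ` (in degrees per pixel, κ·180/π).
2. **Pixel resolvability.** A turned probe must rasterize to different
   pixels than the straight one: `ℓ_str · sin(3° · ϕ_diff) ≥ 1` px.
   Below this, the mean-width comparison cannot see the turn and the
   tracer runs straight until it starves.

The arc fixtures in the acceptance suite use `(ℓ_str, ϕ_diff)` = (5, 4),
(7, 3), (10, 2) for R = 30, 60, 120 px — chosen from these two
inequalities, not fitted. A residual limitation remains: near a wide, flat
apex (curvature much lower than the capacity), coarse increments (~12°)
sometimes cannot disambiguate directions from 10-px mean-width probes, and
a stroke may split into two half-length candidates meeting at the apex.
The fix would widen the neighbor search beyond ± one increment, which the
design deliberately does not do; choose finer increments (smaller
`ϕ_diff`, longer `ℓ_str`) for gently curved fibers instead.

## Descriptors

Filament length is the Euclidean polyline length over *vertices* (the
step endpoints), not over raster pixels — turning angles measured at
Bresenham staircase pixels would swamp curvature with rasterization noise.
Curvature is the total absolute turning angle (radians) at interior
vertices divided by length; on discretized circular arcs this converges to
1/R, which the acceptance suite pins at 20%. The angle is the endpoint
chord orientation (robust for gently curved fibers); a length-weighted
circular mean of piece orientations is available via
`angle_mode = "weighted"`. The nematic order parameter is the standard
length-weighted second-moment statistic `S = |Σ ℓ e^{2iθ}| / Σ ℓ`,
invariant under global rotation, 1 for parallel fibers, 0 for an isotropic
population.

Cell half axes come from the eigenvalues of the second central moment
matrix (`2·√λ`, exact for solid ellipses); the boundary "contour" is the
angular sort of boundary pixels about the centroid — adequate for the
star-shaped blobs this package measures, not a general contour tracer.

Object-wise comparison uses the simple containment criterion (a matches b
when ≥ 75% of a's pixels are covered) with *greedy* one-to-one assignment
in decreasing-overlap order rather than optimal matching: deterministic,
and equal to exhaustive search on all test scenarios.

## Tracking by unbalanced optimal transport

Fragments of ~`fragment_length` px (default 10; the final remainder merges
into the previous piece when at most half a fragment, so fragment weights
sum exactly to filament length) are matched between consecutive frames.
The base cost is `factor_length·d_l² + factor_angle·d_ϕ²` with defaults
(4, 1); `d_l` is the minimum point-pair distance between the two pieces at
1-px sampling, `d_ϕ` the undirected orientation difference in [0°, 90°].

A dummy producer and consumer carry "infinite" weights (the opposite
side's total mass) and cost `d_max²` against everything — including each
other. The dummy–dummy cost is the one place the package takes a stance:
with a zero dummy–dummy cost, rerouting mass through both dummies would
cost `2·d_max²` and fragments up to twice the advertised distance could
still join; with `d_max²` on the dummy pair, a true pair receives flow
only if its cost is at most `d_max²`, which is exactly the advertised
locality (at most `d_max/2` px apart *and* at most `d_max` degrees
twisted, with the default factors). The locality property is asserted over
randomized instances.

The balanced problem is solved exactly by a transportation simplex
(northwest-corner start, MODI duals on the basis tree, most-negative
entering cell, first-minimum leaving cell). No entropic approximation is
used: plans are deterministic and the objective matches an independently
written dense two-phase simplex to 1e-6 on every random instance the suite
draws (plans themselves may differ at degeneracy; objectives, not plans,
are compared).

Consolidation sums plan blocks per filament pair; linking accumulates
successors in decreasing-mass order until `MIN_MATCHED` (0.6) of the
filament's length is matched, pre-filtering candidates by `MIN_ABS_SIZE`
(10 px) and `MIN_REL_SIZE` (0.25), and declares the filament solitary
below `MIN_VALID` (0.3). These four constants have no published values;
the defaults here are conservative choices and the acceptance fixtures
are built to be insensitive to them (drifts of 3 px/frame at `d_max = 20`
match essentially all mass). Lifelines chain primary successors; a
contested successor goes to the larger transported mass.

## Cell-event monitoring

Regions are 8-connected components above `min_area`. The matching score
is the exact pixel intersection over the smaller area — bounding boxes
are a pre-filter only, never the scorer, so the box test cannot drop a
truly overlapping pair. The score is capped at 1 defensively; with exact
pixel sets it cannot exceed 1 (the package asserts this rather than
trusting the cap).

Classification groups each region by its predecessors above
`intersect_tolerance` (default 0.2, user-settable): none → Start; one
(and an unshared predecessor) → Alive; one shared predecessor → Split
(closing the predecessor's lifeline); several → Fusion (closing all).
Post-processing rewrites a Fusion whose fused lifeline later splits into
Touch/DeTouch: the pre-fusion lifelines continue unbroken, reconnected to
post-split regions by best matching score (ties: larger area, then
smaller lifeline id), and the merged-episode regions are owned by the
best-matching lifeline so that every region belongs to exactly one
lifeline. A merge with no later split — including a merge at the end of
the stack — remains a Fusion; this is a stated limitation of the method,
not an implementation accident. Terminal lifelines get an End event, and
`lifespan = death − birth + 1` always.

## Synthetic fixtures: what they do and do not establish

The generator renders hard-edged strokes (a pixel is foreground iff its
center lies within `width/2` of the centerline — no antialiasing, so the
noiseless foreground is exactly the dilated raster) on a 256×256 8-bit
canvas, background 10, foreground 200, with optional additive Gaussian
noise (σ tiers 0/5/15) clipped to range; every random step takes an
explicit seed and reproduces bit-identically. Truth tables — arc length
(closed form for lines and arcs, 32-node Gauss–Legendre quadrature for
Béziers), curvature, tracks, scripted events — are computed from the
specification *before* rasterization, never measured back from pixels, so
detection tests are not circular. Blob movies script splits (children of
half radius drifting apart a few pixels per frame), fusions (a blob
drifting onto a target and freezing there), and touch episodes (freeze,
then retreat), with the event list derived from the script.

What a green suite does establish: oracle-exact width maps; exact
single-filament recovery on in-envelope strokes with length within 10%,
width within ±1 px (one arc fixture sits exactly at 1.0 px — the bound is
inclusive), and arc curvature within 20% of 1/R; the strict 30% veto
boundary; LP-exact transport with the advertised locality; correct
lifelines and event taxonomy on scripted movies; and byte-identical batch
reruns. What it does not establish: performance on real cytoskeletons —
no point-spread function, no intensity texture, no crossing clutter at
realistic density, no photobleaching; the σ = 15 noise tier is far
cleaner than bad live-cell data. The settings that pass here are starting
points, not universal defaults.

## Known limitations

* The flat-apex ambiguity described under the capability envelope.
* The straight-line sensor reports endpoint-to-endpoint filaments; it does
  not split a run at small-angle kinks the width map cannot see.
* The boundary polygon is angular-sorted, valid for star-shaped regions.
* Touch correction reconnects by matching score; if both cells change
  size drastically during the episode the assignment can err — inherent
  to the score, and called out rather than patched.
* Tracking assumes frame-to-frame motion well inside `d_max/2` px;
  faster motion needs a larger `d_max`, at the price of more permissive
  joins.
* 3D stacks are out of scope; the tracker could in principle stitch
  fibers across z the same way it links frames in time.
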