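---
title: "Spherical frame projections: model, fitting choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spherical frame projections: model, fitting choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfproj)
```

## The representation

A joint pose is the orientation of the distal bone's anatomical
coordinate system (ACS) relative to the proximal bone's, a proper
rotation $R \in SO(3)$.  `sfproj` stores $R$ in the row convention: row
$i$ is the unit endpoint of the distal frame's $i$-th axis expressed in
proximal coordinates.  Plotting those rows for every pose in a
range-of-motion (RoM) dataset paints three point clouds on the unit
sphere — the *frame trace* — and fitting one closed boundary per cloud
gives the spherical frame projection (SFP): a triplet of spherical
polygons, one per frame axis, drawn around the null-pose frame.

Because each polygon constrains one axis endpoint, the triplet captures
the *interactions* between rotational degrees of freedom that scalar
per-axis angle ranges cannot: the reachable excursion of one axis
depends on where the other two currently point.  Three polygons are
needed — two alone leave the third axis only implicitly constrained
through orthogonality.

Worked 1- and 2-DoF cases anchor the geometry and serve as exact test
oracles:

* a pure rotation of $\pm\theta$ about one axis leaves that axis's
  cloud a single point and sweeps the other two along arcs of exactly
  $2\theta$;
* independent ranges of $\pm 30°$ and $\pm 15°$ about two axes form a
  $60° \times 30°$ rectangle in Euler space, and the third axis's
  spherical polygon shows those side lengths as geodesic spans through
  the null pose.

```{r one-dof}
rom <- generate_rom(rom_spec("one_dof", 30, axes = "X", step = 1))
fit <- sfp(rom)
summary(fit)
```

## Boundary fitting

The boundary fitter replaces interactive patch selection with a
reproducible occupancy rule on a subdivided icosahedral grid:

1. every grid patch containing a trace point is marked occupied (a
   point landing exactly on a shared edge or vertex occupies all
   incident patches, which keeps the occupied strip of a continuous
   trace connected even when the trace runs along the grid's symmetry
   planes);
2. optionally the region is dilated by whole patch rings
   (`dilation`, default 0 — a tight fit; raise it for sparse
   hand-sampled data);
3. the outer perimeter of the occupied region is extracted as an
   ordered loop of grid vertices, stored counter-clockwise seen from
   outside with an explicit interior reference point.

Every input point lies inside the resulting polygon by construction,
at any resolution.

**Resolution.** The default grid uses 3 subdivisions (1,280 triangular
patches, ≈9.4° patch width).  Patch solid angles sum to $4\pi$ exactly,
so the occupied-patch total equals the polygon's enclosed solid angle.
The occupancy fit is one-sided: boundary patches are included whole, so
fitted areas overestimate the true region by roughly half a patch width
times the perimeter.  For a solid octant cloud this bias falls below
5% at 4 subdivisions (5,120 patches), the resolution the dense-cloud
tests use.

**Pinches and holes.** Sparsely sampled clouds can occupy patches that
meet only at a vertex.  The fitter resolves such pinch vertices by
filling the narrowest unoccupied gaps of the patch fan around them
(selected by proximity to the data), which edge-connects the region
with minimal growth.  If the occupied region still splits into
disconnected clusters the fit aborts with advice to dilate or refit per
cluster, rather than guessing a perimeter.  Regions with interior holes
keep only the longest boundary loop, with a warning: the hole is
covered.  A consequence worth knowing: for *very* sparse subsets these
repairs can add patches that a denser sampling of the same joint would
not need, so fitted areas are only guaranteed monotone in the data at
adequate sampling density (the raw patch occupancy is always pointwise
monotone).

**Geometry primitives.** Arc lengths use `atan2` of cross- and
dot-product magnitudes (stable near 0° and 180°).  Polygon solid angle
comes from the Gauss–Bonnet turning-angle sum, valid for non-convex
loops.  Point-in-polygon is crossing parity along the geodesic from the
interior reference point, with points within `1e-9` rad of an edge
classified inside (the region is closed, so boundary-defining points
test inside); paths through a vertex or antipodal degeneracies are
retried from a deterministically jittered reference.

## Pose checks are necessary, not sufficient

`check_pose()` (or `predict()` on a fitted SFP) reports per-axis
membership.  All-inside is *necessary* for reachability but not
sufficient: the three endpoints may each have been visited by different
poses.  The package constructs this failure mode explicitly in its
tests — an annular 2-DoF dataset leaves a hole under one cloud, the
outer boundary covers it, and the null pose then passes membership
while lying 15° from every sampled pose.

`check_pose_path()` is the stronger check: connectivity from a known
viable start pose through the sampled dataset, stepping only between
poses whose relative rotation (the geodesic metric on $SO(3)$, free of
Euler-space distortion) is at most `step_max` (default 10°; samples
isolated at that radius fall back to their `k = 6` nearest
neighbours).  It certifies reachability only up to the sampling
density, and is offered as a heuristic on that basis.

## From motion-capture markers to joint orientations

The capture rig chain is composed of homogeneous transforms
$T = \begin{bmatrix} R & t \\ 0 & 1 \end{bmatrix}$ (mm):

$$
{}^{dACS}T_{pACS} \;=\;
  {}^{dACS}T_{dPlate}\, {}^{dPlate}T_{markers}\;
  {}^{markers}T_{base}\;
  \left({}^{pACS}T_{pPlate}\, {}^{pPlate}T_{base}\right)^{-1}
$$

and only the rotation block is kept, so every translational offset in
the rig cancels.  Inverses use the exact rigid form
$(R^\top, -R^\top t)$; the often-quoted shortcut "the transpose of a
homogeneous matrix is its inverse" holds only when $t = 0$, though the
extracted rotational component is the same either way.

Marker rigid-body poses come from an orthogonal Procrustes (Kabsch) fit
of the marker-tree model to each frame's observed markers; frames with
partial occlusion are solved from the visible markers and flagged,
frames with fewer than 3 visible markers are dropped.

Plate frames are fitted from ≥3 landmarks on each of three faces:
least-squares plane normals, oriented outward, then formally
orthogonalised; the origin is the intersection of the three planes (the
corner where the faces meet).  Bone frames use principal-direction
lines through proximal and distal edge points; the long axis joins the
edge midpoints, the second axis comes from the proximal edge direction,
and the third completes a right-handed triad.

**Orthogonalisation.** Near-orthogonal fitted triads are finished by a
cyclic recursion: each axis in turn is replaced by the normalised
average of itself and the sign-matched cross product of the other two,
until every pairwise dot product is ≤ 1e-12 (cap 10,000 iterations; 2°
skews converge in ~50).  The residual never increases between steps.
The axes move by the same order as the input perturbation — for
2°-skewed frames up to ≈2.6°, and no orthogonalisation can do
fundamentally better: the drift-optimal polar decomposition already
moves some axes past 2° on the same frames.

## The synthetic generator

`generate_rom()` and `simulate_session()` provide ground truth for
every stage without external data.  Design choices:

* **Regimes.** 1/2/3-DoF Euler boxes sampled on grids or uniformly at
  random (seeded), and a coupled regime where one axis's half-range is
  a piecewise-linear function of another axis's angle — emulating
  joints whose flexion opens up only away from the null pose.  The
  worked examples use the ±30°/±15° ranges of the 1- and 2-DoF
  demonstrations.
* **Rig geometry.** Fixed non-trivial plate/marker transforms
  (rotations of 10–20°, translations of tens of mm) and a 4-marker
  non-coplanar tree at the ~50 mm scale of a small-animal rig, so chain
  errors cannot hide in near-identity transforms.
* **Marker noise.** Isotropic Gaussian, default sd 0.1 mm — a typical
  optical motion-capture residual.  Zero noise makes the forward model
  the exact inverse of the transform chain (round trip ≤ 1e-9 over
  1,000 frames); at 0.1 mm the median angular error is ≈0.2°.
* **Passive torque.** Soft-tissue resistance is a piecewise power-law
  spring per axis: zero inside the soft-limit onset (default 25°), then
  `stiffness * excess^exponent` N·mm (defaults 0.5 and 3) — the
  simplest nonlinear stand-in for soft-tissue stress–strain behaviour.
  Feedback classification uses a cut-off threshold (5 N·mm) and upper
  limit (50 N·mm); the pitch fraction rises linearly between them.
  All torque parameters are user-settable; no canonical values exist.

What the generator does **not** emulate: translational joint motion
(rotational DoF only), marker-label swaps and ghost markers,
soft-tissue artefact (markers ride rigidly on the handle), lens
distortion, and torque cross-talk between axes.  Passing tests
therefore validate the geometry and the processing chain, not the
idiosyncrasies of any particular capture system.

## Coverage accounting

Live-feedback coverage is modelled as a pass counter per grid patch:
consecutive trace samples in a patch are one *pass*; leaving and
re-entering (after ≥1 sample elsewhere) starts a new one.  Intensity is
`min(passes, 3) / 3`, saturating after exactly three independent
passes.  The dwell state carries across streamed updates.

## Problem sizes and numerical settings

The test-suite and example fits use the 1,280-patch default grid
(5,120 for the dense-cloud area check), 61–700-pose grids for the
worked examples, 1,000 frames for the chain round trip, and $10^6$
uniform sphere samples for the Monte-Carlo area cross-check —
desk-scale runs chosen to exercise every code path at full precision.
Rotation validation uses 1e-9 (double-precision composition of a
ten-transform chain stays well below this); orthogonalisation converges
to 1e-12; quaternions are canonicalised to $w \ge 0$ (ties broken by
the first nonzero vector component), which fixes the axis-angle sign
convention: `rotation_axis()` always reports an angle in (0°, 180°].

## Known limitations

* Boundary polygons are resolution-limited: spans and areas are exact
  only to one patch width; degenerate 1-DoF "line" regions are
  reported as thin patch strips, not zero-width arcs.
* Holes in reachable regions are dropped from the fitted boundary
  (outer perimeter only), which is precisely what makes membership
  checks optimistic — use the path check.
* The path check can refuse valid poses if sampling is sparse relative
  to `step_max`, and cannot prove anatomical feasibility; it certifies
  connectivity of the *sampled* set only.
* Translational degrees of freedom are out of scope throughout.
* Mocap input is the tab-separated marker-trajectory dialect; binary
  capture formats are not parsed.
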