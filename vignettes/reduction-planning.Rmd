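---
title: "Virtual fracture reduction: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual fracture reduction: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

fragreduce is an offline, scriptable model of the computational core of a
haptics-assisted planning workstation for cranio-maxillofacial trauma: a
surgeon loads a patient's CT, the bone fragments are segmented and labeled,
and each fragment becomes a rigid body that can be picked up, felt against
the others, and snapped into its anatomical position until the whole
reconstruction is planned. This vignette explains the models the package
implements, the parameters that matter, and the design decisions taken
where more than one reasonable choice existed.

## Geometry conventions

All world coordinates are millimetres. A voxel grid carries a per-axis
spacing (the package default, 0.35 x 0.35 x 0.60 mm, is a typical facial
CT protocol: fine in-plane resolution, coarser slice spacing) and an
origin; voxel `(i, j, k)` (1-based) is centred at
`origin + (index - 0.5) * spacing`. Working in index space would make the
physics anisotropic, so every computation downstream of the voxel grids is
metric.

Poses are rigid transforms: a unit quaternion (scalar-first, active) plus
a translation. `q` and `-q` are the same rotation and are treated as equal
everywhere; rotation differences are measured by the shortest-arc angle,
computed from the quaternion chord (`4 asin(|a - b|/2)`) rather than
`acos` of the dot product, which cannot resolve angles below about 1e-8.
Forces travel as wrenches (force + torque about a stated world point); the
torque reference for everything acting on a manipulated fragment is that
fragment's world centroid.

## Segmentation pre-processing

Bone is separated from soft tissue by a plain intensity threshold, after
which isolated components with fewer than 100 connected voxels are
removed — the classic `bwareaopen`-style clean-up, with the boundary
semantics taken literally: a 99-voxel component is debris, a 100-voxel
component survives intact. Connected-component analysis defaults to
26-connectivity (configurable to 6 or 18); component labels are assigned
in descending size order with ties broken by the smallest linear voxel
index so labeling is deterministic. No default threshold value is baked
in: Hounsfield calibration varies by scanner and protocol, so the
threshold is an explicit argument everywhere.

## Per-fragment precomputation

Real-time six-DOF contact between voxelized bodies is classically done in
a voxmap–pointshell style, and that is the concrete structure used here:

* a **signed Euclidean distance field** per fragment, computed by the
  separable lower-envelope squared-distance transform with anisotropic
  spacing, negative inside, stored in the fragment's local frame so that
  moving a fragment never triggers recomputation. Distances are measured
  between voxel centres, which means the trilinear interpolant crosses
  zero on the voxel interface but has slope ~2 within the boundary band
  (the value at a point half a voxel inside is already minus one voxel).
  This is the same construction ITK's signed Maurer distance map uses; the
  practical contracts (sign, zero-set location, outward gradient) hold,
  and the contact model simply defines penetration as the interpolated
  field deficit.
* a **surface point shell**: one point per surface voxel (6-neighbour
  test), projected onto the field's zero level set by a damped Newton
  iteration with a short line search (the raw Newton step oscillates
  where the interpolant's slope departs from 1). Two normal estimators
  are available. The default, the normalised field gradient at the
  projected point, carries voxel-scale angular noise but preserves the
  sharp micro-relief of fracture surfaces — which is exactly what the
  snap-to-fit weighting discriminates on; replacing it with smoothed
  normals measurably degrades alignment accuracy. The alternative,
  `"plane_fit"`, is a feature-preserving local PCA (neighbours within
  2.5 x max spacing that face the same way, oriented by the gradient):
  on a smooth sphere it is radially accurate to ~2 degrees where the raw
  gradient scatters by 10-25 degrees, so it is the right choice for
  metrology on smooth surfaces, at the price of low-pass filtering
  millimetre-scale detail.
* a **uniform-grid spatial hash** over shell points supporting
  nearest-neighbour and radius queries that return exactly what an
  exhaustive scan would.

## Contact and the static virtual coupling

Contact is a penalty model: every shell point of the moving fragment is
tested against each static fragment's field; a point at field value
`-d < 0` contributes a force `k_c d` along the static field's normalised
gradient. Pruning (bounding-box rejection in the static frame) never
changes the result — points outside a field's grid cannot be in contact by
construction — and the package keeps an exhaustive code path purely so
tests can assert that equivalence.

The handle is connected to the manipulated fragment by a *static virtual
coupling*: a translational spring `k_t` (N/mm) between handle and fragment
translation and a rotational spring `k_r` (N.mm/rad) on the shortest-arc
relative rotation. There is no inertia anywhere: the fragment pose is the
quasi-static equilibrium of coupling plus contact wrenches, tracked per
trajectory sample by damped first-order descent. The step is
preconditioned by effective stiffnesses — `k_t + k_c n_contacts` along the
net contact normal, `k_t` tangentially (the penalty only stiffens the
normal direction; without the split, a fragment pressed against a wall
slides tangentially at a crawl), and `k_r + k_c * sum(r_i^2)` for rotation.
Convergence is declared when the equivalent pose residual (`|F|/k_t` in
mm, `|T|/k_r` in rad) drops below `tol` (default 1e-4); non-convergence
within `max_iters` is reported, never raised.

The ratio `k_c / k_t` (default 50 per contact point) is the parameter that
matters: at equilibrium against an obstacle,
`penetration <= k_t * D / k_c + (one interpolation voxel)` for a handle
driven a distance `D` past the surface, which is the stop-at-the-surface
behaviour that makes rigid manipulation feel solid. Absolute stiffness
values only scale reported wrenches.

## Snap-to-fit

Snap-to-fit is the alignment aid: the user paints the fracture surface of
each fragment with a spherical brush (only painted points ever enter the
model, which is what stops a fragment from snapping to plausible-looking
but wrong regions), and attraction forces pull the painted surfaces into
the closest stable fit. Each marked moving point pairs with its nearest
marked target point within `capture_radius` (default 5 mm, ties to the
lowest point id, re-paired every iteration); the pair attracts with force
`k_a w (target - moving)` where

```
w = max(0, -n_moving . n_target) ^ p        (default p = 2)
```

is the colinearity weight of the two outward world normals: 1 for exactly
opposing normals (mating faces), 0 for same-facing or perpendicular ones.
Clamping removes anti-matches; the exponent sharpens selectivity. The mean
weight over pairs is reported as the `similarity` of the two surfaces —
damaged (compression-fracture) faces converge with visibly lower
similarity than intact ones. Descent uses the same damped stepper as the
coupling, with `k_a * sum(w)` and `k_a * sum(w r^2)` as the effective
stiffnesses; a `step_scale` of 0.8 is appropriate for attraction-dominated
descent (the equilibria are identical to smaller steps, verified
empirically, with ~40% fewer iterations). "Stable fit" means a local
equilibrium: re-running from a small perturbation of the converged pose
returns to it.

Two deliberate choices deserve a note. Pairing is one-directional
(moving to target): a symmetric variant was implemented and benchmarked
and did not improve recovery accuracy, so the simpler rule stands. And the
contact term is *disabled* during snapping by default: the interpolated
zero level sets of two voxelized mating fragments overlap by a fraction of
a voxel, so a penalty contact active during snapping biases the
equilibrium outward by that overlap (~0.7 mm measured); residual contact
can always be resolved afterwards through the coupling stepper.
`snap_to_fit()` also accepts several targets at once (the attraction model
is additive), though the phantom pipeline below performs best snapping
each fragment to its single largest interface.

## Grouping and plans

Fragments positioned relative to one another can be grouped and moved as
one unit. A group stores its own pose plus, per member, the offset
(member local to group frame) captured at attach time, so creating,
attaching and detaching are exactly motion-free and group motion preserves
all pairwise relative poses to machine precision. A detached fragment
keeps its current world pose. For contact simulation a group acts as a
single rigid body whose shell is the union of the member shells
(`group_body()`); intra-group contacts are skipped — the group is rigid,
so its internal contact state is frozen by construction. Scenes export to
a versioned JSON plan (poses at full precision, groups, markings) that
round-trips bit-exactly at 1e-9.

## The phantom generator

Synthetic fractured phantoms stand in for patient CT and carry exact
ground truth. An intact base shape (cube, ellipsoid shell, or
mandible-like bent tube) is cut by `n_cuts` randomized rough surfaces:
planes perturbed by a mixed sinusoid spectrum — one long undulation
(9–13 mm wavelength) plus three shorter components (3.5–6 mm) with a total
RMS amplitude of `cut_roughness` (default 2.0 mm). The mix is deliberate:
the long component keeps neighbouring interlock minima far from any
coarse-alignment start, the short components sharpen the in-plane
rotational minimum, and millimetre-scale amplitude is both the realistic
scale of cortical fracture interlock and the smallest scale resolvable at
this voxel size (flat cuts would leave in-plane translation unobservable
for any surface-matching method). Each non-anchor fragment is displaced by
a random rigid transform (rotation up to `displacement_deg` about its
centroid, translation up to `displacement_mm` biased outward); the inverse
transforms are stored as truth.

The displaced volume is re-voxelized *analytically* — each output voxel is
tested against the base-shape predicate and exact cut-side functions at
its inverse-displaced position — rather than by resampling the intact
label grid. Nearest-neighbour resampling imprints a moiré pattern of
half-voxel surface bias between the two sides of a cut, which shifted snap
equilibria by ~0.5 mm / 1-2 degrees before this was changed. Displaced
fragments are guaranteed pairwise non-adjacent (translations are escalated
outward until separated): the pipeline recovers fragments by connected
components, and separating touching fragments manually is a workstation
task outside this package's scope. Cut slivers below 100 voxels (the same
threshold the segmentation filter applies) are dropped as debris.
Optional extras: compression-fracture damage (spherical craters of depth
`erosion_voxels` carved into fracture faces, so portions of the surface go
missing) and junk specks (each strictly below 100 voxels, kept clear of
the fragments) so the segmentation filter has real work. All randomness
derives from the single spec seed through a fixed splitting scheme.

What the phantoms do *not* emulate: CT noise and beam hardening, partial
volume effects, soft tissue, teeth, or anatomically accurate bone shapes.
Passing tests on phantoms therefore demonstrate the geometric and
numerical correctness of the pipeline at realistic voxel anisotropy — not
robustness to the full messiness of clinical data.

## Study sizes and observed behaviour

The validation suite runs at desk scale, chosen so the full suite
completes in minutes while remaining honest about resolution: default
phantoms are 56 x 56 x 40 voxels (~20 mm of bone at CT spacing, one cut,
two fragments, ~2000 marked points per face), the closure pipeline uses
64 x 64 x 48 voxels with two cuts (four fragments), and collision
equivalence runs on 30 x 30 x 22 phantoms. With intact faces and coarse
starts of exactly 2 mm / 5 degrees, snap-to-fit recovers the true relative
pose within 0.5 mm / 1 degree in ~95% of seeded phantoms; the residual
failures (~1-2 degrees of in-plane rotation) converge robustly from any
nearby start and step size, i.e. they are genuine displaced minima of the
voxel-scale energy landscape, not numerical artifacts. Translation errors
sit well under a quarter voxel (median ~0.05 mm).

## Known limitations

* One moving entity at a time; no dynamics between two simultaneously
  moving bodies, no inertia, no haptic-rate guarantees.
* Penetration is defined through the interpolated signed field, which
  overestimates shallow geometric depth by up to a factor of two inside
  the boundary voxel band (conservative for the stop-at-surface bound).
* The distance-field gradient magnitude is not 1 within the boundary
  band (centre-to-centre signed EDT); tests assert outwardness and
  projection accuracy rather than unit slope at the surface itself.
* Snap-to-fit accuracy is resolution-limited: at 0.35/0.60 mm spacing the
  rotational minimum about the face normal can sit 1-2 degrees off truth
  for a small fraction of fracture geometries.
* DICOM series input is not supported; convert to NIfTI or NRRD first.
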