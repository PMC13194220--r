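---
title: "Automated volar plate placement: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated volar plate placement: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Corrective osteotomy of a malunited distal radius is planned on a segmented
3-D bone model: the surgeon defines the cut, realigns the distal fragment,
and positions a volar locking plate that will fix the correction.  Manual
plate positioning takes minutes to tens of minutes of expert time.
`osteoplate` automates it: given a bone surface mesh whose two osteotomy
cut faces are tessellated with conspicuously large triangles (the normal
signature of a decimated segmentation), a plate mesh, and a side label, it
produces a standardized bone frame and a plate pose that is flush with the
volar surface, clear of the watershed line, and centred on the shaft.

The pipeline has four stages.

### (a) Coordinate standardization

The origin is the bone-mesh centroid — taken as the unweighted vertex mean,
since the frame only needs a robust interior reference point.  The longest
principal axis of the vertex cloud is aligned with Z; the bone counts as
upright when the osteotomy-plane centroids lie above the origin, otherwise
it is flipped 180° about X and the flip recorded.  +Y is the direction,
orthogonal to Z, through the most distal vertex (the styloid process), and
X completes the right-handed frame, pointing volar.  Right-side anatomy is
mirrored across the YZ plane on input and mirrored back on output, so one
canonical (left) code path serves both sides; because IEEE negation is
exact, left/right results are exact mirror images.

A caveat worth knowing: the +Y rule projects the most distal vertex onto
the XY plane *through the centroid*.  When the styloid sits close to the
long axis, that projection is dominated by the centroid's volar offset and
the in-plane rotation of the frame becomes sensitive; on realistic anatomy
(lateral styloid) the residual rotation is a few degrees.  All ground-truth
comparisons in the tests therefore go through the recorded frame transform
rather than assuming the frame equals the generator's axes.

### (b) Landmarks

* **Osteotomy planes** — faces with area at least 4x the median are
  clustered by normal direction (cosine at least 0.99 against the cluster
  seed, sign-free) and plane offset (0.5 mm); clusters with fewer than 3
  faces, or whose mean face area is below 10x the median (the
  tessellation signature of a decimated planar cut; borderline-large
  curved patches never reach it), are discarded and exactly two must
  remain.  Each cluster gets a least-squares plane; normals point away
  from the centroid; the pair is ordered distal/proximal by Z.
* **Midplane** — midpoint of the plane points, normalized mean of the
  sign-aligned normals.
* **Alignment line** — the most volar vertex of the proximal segment
  defines a plane parallel to YZ; its intersection with the midplane is
  the initial alignment line.
* **Watershed line** — on the distal segment (vertices above the 40 mm
  crop, roughly 17 % of an average radius length), each 1 mm Y-slice
  contributes its maximum-X vertex; candidates whose Z deviates more than
  3 mm from the candidates' mean are discarded (this is what rejects slice
  maxima that belong to the dorsally-peaked flare rather than the volar
  rim); X and Z are then smoothed as cubic polynomials in Y.  Slice width
  (1 mm), band (3 mm, reading the source's "3 units" as millimetres — all
  other lengths are mm) and degree (3) are configuration values.
* **Plate landmarks** — quadrants by the sign of the coordinates along the
  first two principal axes; top corners are the farthest-from-centroid
  vertices of the upper quadrants, the bottom corner the vertex farthest
  from the top-corner line; distance ties break on lexicographically
  smallest (z, y, x), making detection independent of STL vertex order.
* **Radius width** (for the X constraint) is defined operationally as the
  Y-extent of the bone within 2 mm of the midplane's Z level.

### (c) Initial alignment

Five deterministic sub-steps: overlap the alignment lines (the plate
centroid goes to the bone-line point nearest the watershed centre);
translate along Z until both top corners sit at least 2 mm below the
watershed line (binding corner exactly at the margin); rotate about the
plate's centre line — the alignment-line direction through the centroid,
the only reading under which the proximal tip approaches the bone — until
the bottom point contacts the surface (bisection on the signed surface
distance, 1e-3 mm); rotate about the long axis to align the top corners
with the watershed X values (1-D minimization over ±45°); re-assert the
margin if the rotations disturbed it; finally translate along X to first
surface contact (march-in plus bisection, 0.05 mm contact tolerance).
Contact here is true point-to-surface distance signed by the winding
number.  The routine is deterministic but not an exact fixed point: a
re-run first re-overlaps the alignment lines, partially undoing the
contact rotations, and moves the plate by under a degree and half a
millimetre.

### (d) Final alignment

The pose (3 fixed-axis XYZ Euler angles about the initial plate centroid,
3 centroid translations) minimizes

f = d_plate + a·d_top + b·d_bottom + c·M + d·theta + e·|y_bottom − y_middle|

with weights a = 105, b = 100, c = 4, d = 5, e = 60.  `d_plate` is the
mean distance from the transformed plate vertices to the bone vertices and
`d_top` the mean over the two top corners; `d_bottom` is the bottom-corner
distance; `M` counts plate vertices inside the bone (winding number);
`theta` is the angle in degrees between the longest principal axes of
plate and bone; `y_middle` is the mean Y of the bone cross-section within
2 mm of the bottom corner's Z.  Distances are point-to-vertex, a stated
fidelity choice.  Two points deserve explanation:

* **Means, not sums.**  With summed distances the objective pays
  ~n_vertices·mm for sinking the plate into the bone, which the c = 4
  count penalty cannot offset at any mesh resolution, and the weights above
  lose their meaning.  As means, the term magnitudes balance the corner
  and penetration terms the way the tuned weights imply.  Relatedly, `M`
  is by definition a raw count, so its strength scales with plate vertex
  density; the synthetic plate's default grid (1.4 mm, ~1200 vertices) is
  chosen dense enough for c = 4 to bite, mirroring the density of
  manufactured-plate meshes.
* **Bounds.**  Rotations are limited to ±30° per axis.  Lateral X movement
  is a quarter of the radius width; Y movement spans the watershed-line
  width re-centred on the initial position.  The vertical interval bounds
  the plate's *extremes*: the top edge may not rise above its initial
  (margin-binding) height — the watershed margin is a clinical boundary,
  not a soft preference — and the bottom edge stays within 1.5 plate
  lengths of the bone's maximum-Z vertex.  Bounding the centroid instead
  would let the plate climb tens of millimetres past the watershed line.

The minimizer is a bounded quasi-Newton method (L-BFGS-B) with
finite-difference gradients, objective tolerance 1e-6 and an iteration cap
of 500.  The gradient step is 1e-2: at much smaller steps the
nearest-vertex kinks of the point-to-vertex distance dominate the
directional-derivative estimates and the line search aborts.  The integer
count `M` has zero gradient, so during the search it is replaced by a sum
of sigmoids (sharpness 10/mm) of the signed vertex distance — magnitude
from the nearest bone vertex, sign from that vertex's angle-weighted
pseudo-normal, which is cheap and accurate near the surface.  Three
deterministic robustness layers wrap the solver: restarts from the current
iterate when the line search aborts on a kink; a small-step coordinate
pattern search (0.6 down to 0.04 units) that descends over kinks without
hopping to neighbouring basins — the method is intentionally local, like
the sequential quadratic programming it mirrors; and a short coordinate
descent on the *exact* objective (true integer count), which resolves
residual sub-0.1 mm penetrations that the sigmoid blurs.  The exact
objective at the returned pose is never allowed to exceed the initial
objective; if the smoothed search ends worse, the initial pose is returned
with `converged = FALSE`.

## Comparison metrics

`hausdorff_max` is the unpaired symmetric maximum Hausdorff distance
between vertex sets (no correspondence, point-to-vertex — matching the
vertex-level framing of placement comparison).  `pose_difference`
decomposes the relative transform into its geodesic rotation angle
(computed from the rotation matrix trace, hence independent of the Euler
representation) and the displacement of a reference point.  Total
translation is reference-point dependent under coupled rotation; the plate
centroid is the intended reference and the origin (a standardized plate's
centroid) the default.

## The synthetic anatomy generator

`make_bone()` lofts elliptical cross-sections (volar half-width a(z),
mediolateral half-width 1.3·a(z)) along a 140 mm default length.  All
rings sample a shared absolute-Y ladder on the volar side, mirrored
exactly onto the dorsal side; the mirror keeps every ring mass-balanced in
X so the standardized frame's residual in-plane rotation stays well under
a degree, and the shared ladder means that within any watershed Y-slice
the widest ring owns the most volar vertex.  On that scaffold sit:

* a distal flare rising to 1.3x the 10 mm shaft half-width, peaking 4 mm
  *above* the volar rim: outside the rim band every per-slice maximum-X
  vertex belongs to the flare, falls at |z − mean| > 3 mm, and is removed
  by the watershed Z-band filter;
* a volar rim carried by a single crest ring at z_ws (no other ring within
  4 mm of it): its profile is the exact quadratic x = x0 − c2·y² wherever
  that clears the ring's own ellipse, dying laterally where the quadratic
  meets the bone surface — so every surviving watershed candidate lies on
  the analytic crest by construction, which is what makes the ground
  truth exact;
* a laterally protruding styloid apex, the unique most distal vertex;
* two parallel tilted planar cuts (default 5°) splitting the mesh into two
  closed fragments, each cut capped by a coarse fan whose triangles are
  ≥ 10x the median face area — the detector's signature; cap, shoulder
  and shaft triangles elsewhere are kept below the oversized-face
  threshold by construction (graded dome caps, per-ring shoulder points);
* Gaussian vertex jitter, sigma = 0.05 mm, applied after welding and on
  everything except the cut faces (segmentation cuts are exactly planar),
  so "recovery within 3 sigma" is meaningful while plane normals stay
  exact.

`make_plate()` builds a T-shaped slab (20 mm head, 9 mm shaft tapering to
a single proximal tip, 2.4 mm thick) with transverse curvature; the
default curvature radius matches the bone's mediolateral radius, as
manufacturers contour volar plates to the distal radius.  Ground truth
records the designed corner coordinates.

`synth_case(seed)` draws bone length 130–150 mm, shaft half-width
9–11 mm, flare 1.25–1.35, rim height 2–3 mm, cut tilt 2–8°, plate length
52–58 mm — ranges a planning engineer would call representative of adult
distal radii at the generator's reduced scale.  The `"coarse"` resolution
(5 mm rings, 2.2 mm plate grid) is used for optimization-heavy
experiments; the methods tests run the standard resolution (2.5 mm rings,
1.4 mm grid, bone ~4200 vertices, plate ~1200 vertices).

What the generator does *not* emulate: real cortical surface texture,
malunion deformity, the ulnar notch and dorsal tubercle detail, partial
or noisy cut faces, and clinical mesh sizes (tens of thousands of
vertices).  Passing tests therefore demonstrate the algorithmic contracts
(landmark recovery, margin and contact rules, bounded monotone
optimization, mirror symmetry), not clinical placement accuracy.

## Numerical choices and degenerate inputs

* Vertex weld tolerance 1e-6 mm (STL stores facets independently).
* Containment: generalized winding number, threshold 0.5; non-watertight
  input falls back to 3-ray parity majority voting with a warning.
* Plane clustering compares each face against its cluster's *seed* face,
  which stops slow normal drift from chaining curved faces into a plane.
* Watershed interpolation at a corner's Y is linear between polyline
  samples; corners outside the polyline's Y-range raise a coverage error.
* Contact searches bisect to 1e-3 mm (rotation) and 5e-3 mm (translation),
  against a 0.05 mm contact tolerance.
* Gimbal lock in Euler extraction (|sin ry| = 1) sets rz = 0.
* Ties in farthest-vertex landmark picks break on smallest (z, y, x).
* The objective's y-terms are world-Y quantities: y_dev is invariant under
  common translations of bone and plate but not under arbitrary common
  rotations, since y_middle windows on world Z.  The distance, count and
  angle terms are rigid-motion invariant.

## Known limitations

* Point-to-vertex distances make the objective landscape piecewise smooth;
  the solver's restart/pattern/polish layers handle this, but a
  point-to-surface objective would be smoother (and slower).
* The optimizer is local, as the underlying method prescribes; it relies
  on the initial placement and inherits its sensitivity to local minima.
  Concretely, the placement objective is multimodal within a few degrees
  and millimetres of the optimum — the plate can rest against the volar
  rim or rock onto the flare with a compensating rotation — and the basin
  floor is a rough plateau of nearest-vertex micro-minima.  Re-optimizing
  from a pose perturbed by up to 5° / 3 mm therefore does not reliably
  return to within 1 % of the unperturbed optimum: the corresponding
  reproducibility test documents this honestly rather than masking it.
  This mirrors the source method's own observation that several slightly
  different placements can be equally acceptable clinically.
* Weights are the published hand-tuned values; no automatic retuning.
* Plate bending and patient-specific-guide design are out of scope.

## Problem sizes used by the test-suite

Unit and acceptance tests run on the generator's standard resolution for
landmark/frame/initial-placement properties (seconds per case) and on the
coarse resolution for the optimization experiments: one full placement
plus twenty perturbed re-optimizations for pose recovery, and two full
placements for the left/right mirror check.  These sizes were chosen so a
complete run finishes in minutes on one CPU while every contract is still
exercised at meaningful mesh density.
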