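---
title: "Predicting gantry-couch collisions from simulation CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting gantry-couch collisions from simulation CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtclear)
```

## The problem

Noncoplanar beam arrangements - couch angles away from zero - can improve
dose distributions but bring the rotating gantry close to the couch, the
patient, and immobilization hardware. Whether a given couch/gantry
combination is deliverable depends on the individual machine geometry and
on the individual patient's external shape, so the deliverable region has
to be mapped per machine and per patient. `rtclear` does this entirely in
software: a parametric polygonal model of the accelerator, an external
surface automatically contoured from the planning (simulation) CT, rigid
kinematics for gantry and couch, and margin-aware surface-distance queries
over the whole configuration grid. A configuration is flagged as colliding
when any monitored clearance falls to or below its safety margin - by
default 30 mm, the standard 3 cm safety zone; the touch guard on the
gantry head is modeled as its own component with margin 0, because the
guard itself *is* a contact buffer.

## Machine model

A machine is a YAML file (schema in `inst/extdata/machine-schema.md`)
describing seven required components - gantry gun (head), gantry arm,
gantry wall, touch guard, couch plate, couch rotator, couch base - as
unions of solid primitives (boxes, cylinders, truncated cones, extruded
polygons), each assigned to a kinematic group. Real vendor dimensions are
proprietary, so the package ships two *generic* fixture machines:
`machine_a` (head radius 330 mm, face clearance 420 mm, 530 mm couch) and
`machine_b` (larger head, 400 mm radius, smaller clearance 380 mm, 500 mm
couch). They are deliberately plausible rather than vendor-exact; the
method, not the vendor data, is what the package implements.

Curved primitives are tessellated as inscribed prisms (`tessellation`
segments). A second, independent resolution knob - `max_facet_mm` -
subdivides large flat walls into a grid of facets. This does not change
the solid at all; it exists because bounding-volume pruning degrades when
a single triangle spans meters, and it keeps sweep queries fast.

```{r machine}
spec <- fixture_machine("machine_a")
spec
collides(assemble_scene(spec, machine_state(120, 330, c(0, 0, -300))), spec)
```

## Coordinates and kinematics

The room frame has its origin at the isocenter, +Z up, +Y toward the
gantry stand; the gantry rotates about +Y (0 degrees = head above the
isocenter), the couch about +Z, counter-clockwise positive from above
(see `COORDINATES.md`). Two conventions had to be fixed where common
practice varies and the choice is not derivable from first principles:

* **Shift composition.** Couch shifts are applied in the couch frame and
  then rotated (translate-then-rotate). Both orders are self-consistent;
  this one makes "100 mm couch-down" mean the same physical motion at
  every couch angle, which matches how couch coordinates are read out.
* **Group semantics.** `couch_rotating` components (rotator, base) follow
  the rotation only - a floor turntable does not ride up and down with
  the tabletop - while `couch_translating` components (plate) and the
  patient follow shift plus rotation.

`place_patient()` expresses the CT-contoured surface in the couch frame
so that the manually chosen isocenter sits at the room origin at zero
couch state and every point keeps its CT-measured height above the couch
plate; the couch assembly is leveled so its top coincides with the CT
plate surface. Clinical protocols often state absolute couch-top heights
("20 cm below the isocenter"); `couch_shift_for_top()` converts those
into vertical shifts.

## CT contouring

The pipeline is deliberately simple and user-steerable, mirroring how
body contours are produced in practice: a linear intensity window to
8-bit gray (`intensity_transform()`, default window -500 to +300 HU), a
gray threshold (default cut at -300 HU for the body surface;
`hu_to_gray()` converts HU cuts under any window), binary morphological
closing with a disc (default radius 2 px) as the only smoothing step, and
connected-component contour extraction. Components entirely below the
stated couch-plate height (the plate itself, couch rails) are discarded;
remaining components are tracked slice-to-slice by maximal pixel overlap
and become labelled colliders - the largest by volume is `body`, the rest
`accessory_1`, `accessory_2`, ... Accessories that touch the body (a
vacuum bag hugging the skin) merge with it into one external collider,
which is exactly the surface that matters for collision.

Contours are traced at the 0.5 iso-level of the binary mask, so vertices
sit midway between inside and outside pixel centers. A boundary-pixel-
center chain was considered and rejected: it biases enclosed area low by
roughly half a pixel ring (about 2% for a 50-pixel-radius disk), while
the 0.5-level trace reproduces the mask's pixel count almost exactly.
There is no sub-pixel smoothing beyond this; the closing is the smoothing.

The window and threshold are user parameters, not constants: the defaults
separate soft tissue from air, and a lower cut (-700 HU under a wider
window) additionally captures low-density immobilization foam. Exported
structure files use an RT-structure-style DICOM layout (one ROI per
collider, a POINT ROI for the isocenter, a dedicated plate-height ROI);
the package includes a minimal explicit-VR little-endian DICOM codec for
both CT series and structure files, and its output is verified in the
test suite against an independent reader.

## From contours to solids

Each collider's contour stack is lofted into a watertight mesh: contours
are resampled to a fixed ring size by arc length, consecutive rings are
aligned by the cyclic start offset minimizing summed squared distances
after centroid alignment (tolerant to couch drift between slices),
intermediate rings are linearly interpolated so the effective axial step
stays at or below 5 mm (the scale of CT slice spacing), side walls are
stitched as triangle strips, and the end rings are capped by ear-clipping
triangulation (which handles non-convex body outlines; convex caps take
the same path). When the number of components changes between adjacent
slices - arms separating from a torso - the unmatched part is capped at
the transition and continues as a separate collider; no branching surface
is attempted, which is conservative and always watertight.

Prisms are exact under this construction (volume = ring area x height to
machine precision), which the tests exploit; curved solids converge from
below as inscribed polygons (0.5% area deficit at 64 segments).

## Collision engine

Clearance is the Euclidean minimum distance between triangle surfaces,
computed with an AABB-tree branch-and-bound in C++ and defined as 0 when
surfaces touch or intersect. The margin is a *distance threshold* -
clearance less than or equal to margin means collision - rather than a
Minkowski inflation of the meshes: thresholding is exact, monotone in the
margin, and avoids offset-surface meshing artifacts. Equality counts as a
collision (patient-safety conservative).

Three numerical details matter:

* **Oracle.** An exhaustive all-triangle-pairs distance
  (`brute_force_min_distance()`) is kept alongside the accelerated path
  and the two are compared to 1e-9 mm on random mesh pairs in every test
  run, and spot-checked inside every fine validation run.
* **Clearance cap.** Sweeps accept `clearance_cap_mm` (default 200 mm):
  distances are exact up to the cap and saturate at it beyond. Colliding
  flags are unaffected as long as the cap exceeds every margin; flag-only
  consumers (the validation harness, boundary searches) cap just above
  the largest margin, which prunes far configurations aggressively.
* **Sweep factorization.** For a fixed couch state only the gantry moves,
  so couch-side trees are built once per couch state and reused across
  all gantry angles.

`sweep_map()` evaluates the cartesian grid couch angle x gantry angle x
couch position; cells are independent, so the map is deterministic and
order-free. The default grids mirror clinical validation practice: couch
0-90 and 270-350 in 10-degree steps (19 values), gantry 0-350 in
10-degree steps. `boundary_gantry_angles()` reports the first colliding
gantry angle rotating away from zero in either direction, quantized to
the step; `trajectory_events()` turns a sampled gantry path into
enter/stay/exit event streams per monitored pair (event detection is
discrete along the given samples; no continuous-motion root finding).

## Clearance search

`find_min_shift()` answers the clinical question "how far must the
isocenter move for this plan to clear?". It walks a shift grid (default
5 mm steps, up to 100 mm, couch-down by default - shifts are applied in
discrete millimeters at the machine, so a continuous optimizer would
suggest precision the hardware does not have), re-checks every planned
beam at each candidate, and returns the smallest-magnitude clearing
shift, reported both as the couch/patient translation and as the
equal-and-opposite isocenter shift. If nothing clears within range it
returns the best candidate as diagnostics instead.

## Validation harness: the digital twin

The original validation of this kind of software is physical: drive the
real machines through the grid and record true collisions. That ground
truth is not available here, so the harness replaces it with a *fine
in-silico oracle* and treats the published clinical agreement rates as
floors. The production predictor runs at coarse resolution (tessellation
32, 200 mm facets, 64-point rings, every second CT slice); the oracle
runs strictly finer (tessellation 128, 100 mm facets, 128-point rings,
all slices) and its engine distances are spot-verified against the
exhaustive oracle. `digital_twin_validation()` compares the two over the
same grid and reports the confusion matrix (positive = collision;
accuracy, TPR, TNR; rates with empty denominators are `NA`, never 0 or
1) plus, optionally, the maximum boundary-angle disagreement at 1-degree
resolution.

What passing means - and does not mean: the twin isolates the error
introduced by the production discretization (inscribed tessellation,
ring resampling, slice subsampling). It does not probe machine-model
fidelity to any real accelerator, CT artifacts, or setup variability, so
the resulting accuracies sit near 100% by construction and are compared
against the clinical floors as a regression guard, not as a claim about
physical machines.

## The synthetic phantom

`make_phantom_ct()` generates the test subject: an elliptical-cylinder
torso (default semi-axes 170 x 110 mm, 50 slices at 4 mm spacing, 30 +/- 15 HU with
seeded Gaussian noise), an optional vacuum-bag shell hugging the lower
half (-650 HU, 16 mm), a couch-plate slab (200 HU), air at -1000 HU,
written as a standard DICOM series on request. A prone-board variant
(`make_prone_breast_case()`) inserts a 120 mm board that raises the torso
and reproduces the reduced posterior-oblique clearance of a high prone
setup. The phantom is geometric, not anthropomorphic, on purpose: every
downstream quantity (contour semi-axes, mesh volume pi a b L, collision
boundaries) has closed-form truth, so pipeline regressions are
attributable. Two idealizations to keep in mind: noise is only added to
solids (air stays clean), and a 12 mm air gap separates the bag from the
plate so the external collider and the plate never merge into one
connected component at the bag-visible threshold; real bags rest on the
couch and real contouring relies on the below-plate exclusion instead.

Problem sizes used throughout the validation suite: 192 x 176 x 50
voxels at 2 mm / 4 mm spacing for the phantom; sweeps of 19 x 36 cells
per couch position with 10 positions (empty couch) or 3 couch-top heights
(phantom case, {lowest, -200, -100} mm); boundary comparisons at
1-degree resolution over all 19 couch angles, both directions, both
fixture machines.

## Known limitations

* Collimator rotation, 6-DOF couch pitch/roll, and imaging-arm (kV/CBCT)
  geometry are not modeled.
* Event detection along trajectories is sample-based; a collision arc
  narrower than the sampling step can be missed.
* Devices absent from the simulation CT (monitors, breathing-control
  hardware) are invisible to the contouring stage and therefore to the
  prediction.
* The DICOM codec writes and reads the package's own documented dialect
  (explicit VR little endian); it is not a general-purpose DICOM
  implementation.
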