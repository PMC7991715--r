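# rtclear

Vendor-independent prediction of mechanical collisions in external-beam
radiotherapy, directly from a simulation CT series and a parametric
machine description. For medical physicists and treatment planners who
want to know, **before** planning, which couch/gantry combinations are
deliverable for *this* patient on *this* accelerator — especially for
noncoplanar beams, where the rotating gantry comes close to the couch and
the patient.

## What it computes

A configuration `(couch angle θ_c, gantry angle θ_g, couch position s)`
is flagged as colliding when any monitored pair of scene surfaces comes
within its safety margin:

```
collide(θ_c, θ_g, s)  ⇔  min_{(A,B) monitored} d(A(θ_g), B(θ_c, s)) ≤ m_AB
```

where `d(·,·)` is the Euclidean minimum distance between triangle
surfaces (0 when touching or intersecting), `m_AB` is the per-pair margin
(default 30 mm — the 3 cm safety zone; 0 for the touch guard, which is
itself a contact buffer), the gantry assembly rotates about the
horizontal axis through the isocenter and the couch assembly (plus
patient) about the vertical one. Around that core the package provides:

- **`machine_model`** — YAML-described polygonal accelerators (two generic
  fixture machines included), watertight primitive meshing, scene
  assembly, STL/OBJ export.
- **`ct_contouring`** — DICOM CT ingestion, HU windowing, threshold +
  morphological closing, per-slice external contours with accessory
  tracking, RT-structure-style DICOM export/import (self-contained
  explicit-VR-LE codec).
- **`mesh_builder`** — arc-length resampling, cyclic correspondence,
  linear contour interpolation, lofting into watertight meshes.
- **`collision_engine`** — BVH-accelerated surface distance (C++) with an
  exhaustive oracle, configuration-space sweeps (`sweep_map`), collision
  boundary angles, trigger-style trajectory events.
- **`clearance_search`** — minimal isocenter/couch shift that clears all
  planned beams (`find_min_shift`).
- **`metrics_validation`** — confusion matrices and the digital-twin
  harness (coarse production predictor vs fine in-silico oracle).
- **`synthetic_data`** — seeded CT phantom generator (torso + vacuum bag,
  prone-board variant) so everything is testable with no clinical data.

Coordinate conventions are in `COORDINATES.md`; the methods vignette
(`vignettes/collision-prediction.Rmd`) explains the model, parameter
choices, and limitations.

## Worked example

```r
library(rtclear)

# a synthetic torso phantom with a vacuum bag, as a DICOM series
vol   <- make_phantom_ct(phantom_params(noise_seed = 7))
case  <- contour_phantom(vol)           # -700 HU cut: body + bag collider
body  <- loft_stack(contour_stack_label(case, "body"), n = 128)
pat   <- place_patient(body, case$isocenter_mm, case$plate_height_mm)

spec  <- fixture_machine("machine_a")
sweep <- sweep_map(spec, pat,
                   positions = list(c(0, 0, couch_shift_for_top(spec, -200, pat))))
sweep
#> <collision_map 'machine_a': 19 couch x 36 gantry x 1 positions = 684 cells, 310 colliding>

st <- machine_state(gantry_angle_deg = 120, couch_angle_deg = 330,
                    couch_shift_mm = c(0, 0, -300))
collides(assemble_scene(spec, st, patient = pat), spec)
#> <collision_result: COLLIDING, min clearance 0.00 mm>
#>          group_a           group_b clearance_mm margin_mm colliding
#>  gantry_rotating couch_translating      0.00000        30      TRUE
#>  gantry_rotating    couch_rotating    171.42127        30     FALSE
#>  gantry_rotating           patient     74.99299        30     FALSE
#>      touch_guard couch_translating      0.00000         0      TRUE
#>      touch_guard    couch_rotating    146.42127         0     FALSE
#>      touch_guard           patient     49.99299         0     FALSE
```

At that state the gantry head has driven into the lowered couch plate
(clearance 0 against the 30 mm margin), while the patient surface still
has 75 mm — the map marks the cell colliding and reports the binding
pair. For a prone-board case in a high setup position, `find_min_shift()`
answers how far the couch must move for the plan to clear:

```r
prone <- contour_phantom(make_prone_breast_case(seed = 7))
body2 <- loft_stack(contour_stack_label(prone, "body"), n = 128)
pat2  <- place_patient(body2, prone$isocenter_mm, prone$plate_height_mm)
high  <- couch_shift_for_top(spec, 40, pat2)   # torso top 40 mm above iso plane
find_min_shift(spec, pat2, beams = list(machine_state(0, 0, c(0, 0, high))))
#> <shift_solution: couch shift (0, 0, -20) mm, clearance after 7.0 mm, 5 states tested>
```

(The reported clearance is against the zero-margin touch guard; the
30 mm safety-zone pairs are all clear after the 20 mm downward shift.)

A thin CLI wraps the same pipeline
(`inst/cli/rtclear synth|contour|sweep|clearance|validate`).

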