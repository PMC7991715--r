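# Machine description schema (version 1)

One YAML file describes one accelerator. All lengths are mm, all angles
degrees. Poses are given in the machine's zero state: gantry head above the
isocenter, couch long axis toward the gantry stand, zero shifts.

Top-level keys:

| key | meaning | default |
|---|---|---|
| `name` | machine identifier | required |
| `version` | schema version | 1 |
| `isocenter_clearance_mm` | isocenter to gantry-head face distance | required |
| `default_margin_mm` | safety-zone margin for pairs without their own | 30 |
| `couch_top_mm` | vertical coordinate of the empty couch-plate top at zero shift | 0 |
| `gantry_angle_range_deg` | must cover `[0, 360]` | `[0, 360]` |
| `couch_angle_range_deg` | couch rotation range | `[0, 360]` |
| `couch_height_range_mm` | vertical travel | `[-450, 50]` |
| `couch_shift_ranges_mm` | `lateral` / `longitudinal` / `vertical` ranges | see source |
| `components` | list, see below | required |
| `collision_pairs` | list, see below | required, nonempty |

Each component: `label`, `group` (one of `gantry_rotating`,
`couch_rotating`, `couch_translating`, `static`) and a `primitives` list.
Required labels: `gantry_gun`, `gantry_arm`, `gantry_wall`, `touch_guard`,
`couch_plate`, `couch_rotator`, `couch_base`.

Primitive shapes and their dimension keys:

- `box`: `width_mm` (x), `depth_mm` (y), `height_mm` (z); centered on the
  origin of its pose.
- `cylinder`: `radius_mm`, `height_mm`; base in the pose's z = 0 plane,
  axis +z.
- `truncated_cone`: `r_bottom_mm`, `r_top_mm`, `height_mm`.
- `extruded_polygon`: `vertices_mm` (list of `[x, y]`, simple polygon,
  >= 3 vertices), `length_mm` extruded along +z.

Curved shapes take `tessellation` (segment count, >= 8, default 32).
`pose` holds `rotation_deg` (XYZ Euler) and `translation_mm`, applied in
the component frame. All dimensions must be positive.

`collision_pairs` entries: `a` and `b` each name a kinematic group, a
component label, or `patient`; optional `margin_mm` (else the default
margin) and `exclude` (component labels removed from a group side -
used to give the touch guard its own zero-margin pairs while the bare
gantry uses the safety zone).
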