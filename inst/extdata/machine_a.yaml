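# Generic fixture accelerator "A" (schema version 1; see machine-schema.md).
# Dimensions are plausible for a C-arm linac but deliberately NOT those of
# any vendor. Room frame: origin at isocenter, +Z up, +Y toward the gantry
# stand; component poses are given in the machine's zero state.
name: machine_a
version: 1
isocenter_clearance_mm: 420
default_margin_mm: 30
couch_top_mm: 0
gantry_angle_range_deg: [0, 360]
couch_angle_range_deg: [0, 360]
couch_height_range_mm: [-450, 50]
couch_shift_ranges_mm:
  lateral: [-200, 200]
  longitudinal: [-250, 250]
  vertical: [-450, 50]
components:
  - label: gantry_gun
    group: gantry_rotating
    primitives:
      - shape: cylinder
        radius_mm: 330
        height_mm: 450
        tessellation: 64
        pose: {translation_mm: [0, 0, 420]}
  - label: touch_guard
    group: gantry_rotating
    primitives:
      - shape: cylinder
        radius_mm: 350
        height_mm: 25
        tessellation: 64
        pose: {translation_mm: [0, 0, 395]}
  - label: gantry_arm
    group: gantry_rotating
    primitives:
      - shape: box
        width_mm: 450
        depth_mm: 700
        height_mm: 400
        pose: {translation_mm: [0, 600, 600]}
  - label: gantry_wall
    group: gantry_rotating
    primitives:
      - shape: box
        width_mm: 2600
        depth_mm: 500
        height_mm: 2600
        pose: {translation_mm: [0, 1450, 0]}
  - label: couch_plate
    group: couch_translating
    primitives:
      - shape: box
        width_mm: 530
        depth_mm: 2120
        height_mm: 55
        pose: {translation_mm: [0, -240, -27.5]}
  - label: couch_rotator
    group: couch_rotating
    primitives:
      - shape: extruded_polygon
        vertices_mm: [[350, 0], [247.49, 247.49], [0, 350], [-247.49, 247.49],
                      [-350, 0], [-247.49, -247.49], [0, -350], [247.49, -247.49]]
        length_mm: 60
        pose: {translation_mm: [0, -400, -120]}
  - label: couch_base
    group: couch_rotating
    primitives:
      - shape: box
        width_mm: 500
        depth_mm: 700
        height_mm: 600
        pose: {translation_mm: [0, -850, -450]}
collision_pairs:
  - {a: gantry_rotating, b: couch_translating, exclude: [touch_guard], margin_mm: 30}
  - {a: gantry_rotating, b: couch_rotating, exclude: [touch_guard], margin_mm: 30}
  - {a: gantry_rotating, b: patient, exclude: [touch_guard], margin_mm: 30}
  - {a: touch_guard, b: couch_translating, margin_mm: 0}
  - {a: touch_guard, b: couch_rotating, margin_mm: 0}
  - {a: touch_guard, b: patient, margin_mm: 0}
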