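# Generic fixture accelerator "B": larger head diameter and smaller
# face-to-isocenter clearance than machine_a, narrower couch plate.
name: machine_b
version: 1
isocenter_clearance_mm: 380
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
        radius_mm: 400
        height_mm: 430
        tessellation: 64
        pose: {translation_mm: [0, 0, 380]}
  - label: touch_guard
    group: gantry_rotating
    primitives:
      - shape: cylinder
        radius_mm: 420
        height_mm: 25
        tessellation: 64
        pose: {translation_mm: [0, 0, 355]}
  - label: gantry_arm
    group: gantry_rotating
    primitives:
      - shape: box
        width_mm: 500
        depth_mm: 700
        height_mm: 420
        pose: {translation_mm: [0, 620, 640]}
  - label: gantry_wall
    group: gantry_rotating
    primitives:
      - shape: box
        width_mm: 2700
        depth_mm: 500
        height_mm: 2700
        pose: {translation_mm: [0, 1500, 0]}
  - label: couch_plate
    group: couch_translating
    primitives:
      - shape: box
        width_mm: 500
        depth_mm: 2120
        height_mm: 50
        pose: {translation_mm: [0, -240, -25]}
  - label: couch_rotator
    group: couch_rotating
    primitives:
      - shape: extruded_polygon
        vertices_mm: [[360, 0], [254.56, 254.56], [0, 360], [-254.56, 254.56],
                      [-360, 0], [-254.56, -254.56], [0, -360], [254.56, -254.56]]
        length_mm: 70
        pose: {translation_mm: [0, -380, -130]}
  - label: couch_base
    group: couch_rotating
    primitives:
      - shape: box
        width_mm: 520
        depth_mm: 720
        height_mm: 620
        pose: {translation_mm: [0, -860, -460]}
collision_pairs:
  - {a: gantry_rotating, b: couch_translating, exclude: [touch_guard], margin_mm: 30}
  - {a: gantry_rotating, b: couch_rotating, exclude: [touch_guard], margin_mm: 30}
  - {a: gantry_rotating, b: patient, exclude: [touch_guard], margin_mm: 30}
  - {a: touch_guard, b: couch_translating, margin_mm: 0}
  - {a: touch_guard, b: couch_rotating, margin_mm: 0}
  - {a: touch_guard, b: patient, margin_mm: 0}
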