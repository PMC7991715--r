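# Coordinate conventions

All lengths mm, all angles degrees. One normative frame is shared by every
module.

## Room frame

Right-handed, origin at the isocenter (IEC-61217-like):

- **+Z** vertical, up.
- **+Y** horizontal, from the isocenter toward the gantry stand.
- **+X** completes the right-handed frame.

## Gantry

Rotates about **+Y** through the isocenter. 0° = head directly above the
isocenter (beam pointing down); at 90° the head reference point
`(0, 0, +d)` maps to `(+d, 0, 0)`. `d = isocenter_clearance_mm` is the
head-face-to-isocenter distance. Angles are normalized to `[0, 360)`;
"cw" in boundary searches means rotation with increasing angle.

## Couch

Rotates about **+Z** through the isocenter, counter-clockwise positive
seen from above; 0° = couch long axis pointing toward the gantry stand.
Shifts `(lateral, longitudinal, vertical)` are applied **in the couch
frame before the rotation** (translate-then-rotate). `couch_rotating`
components follow the rotation only (floor turntable); `couch_translating`
components and the patient follow shift + rotation.

## CT volume frame

`(x lateral, y vertical up, z slice position)`; voxel `(i, j, k)` is
centered at `(origin_x + (i-1) dx, origin_y + (j-1) dy, z_k)`. DICOM
files store patient coordinates with +y posterior (down for supine), so y
is negated on export and import.

## Patient placement

`place_patient()` maps CT `(x, y, z)` to couch-frame
`(x - ix, -(z - iz), y - iy)` for isocenter `(ix, iy, iz)` — a proper
rotation (no mirroring): the manually chosen isocenter lands on the room
origin at zero couch state, increasing slice position points away from
the gantry stand, and every point keeps its CT height above the couch
plate (the couch assembly is leveled so its top coincides with the CT
plate surface).
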