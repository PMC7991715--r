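test_that("the phantom generator honors requested dimensions and is seeded", {
  p <- phantom_params(nx = 80L, ny = 120L, n_slices = 20L,
                      pixel_spacing_mm = 2.5, slice_thickness_mm = 2.5,
                      body_semi_axes_mm = c(60, 45), noise_seed = 12L)
  v1 <- make_phantom_ct(p)
  expect_identical(dim(v1$voxels), c(80L, 120L, 20L))
  expect_equal(diff(v1$slice_positions[1:2]), 2.5)
  v2 <- make_phantom_ct(p)
  expect_identical(v1$voxels, v2$voxels)   # bit-identical for a fixed seed
  v3 <- make_phantom_ct(phantom_params(nx = 80L, ny = 120L, n_slices = 20L,
                                       pixel_spacing_mm = 2.5,
                                       body_semi_axes_mm = c(60, 45),
                                       noise_seed = 13L))
  expect_false(identical(v1$voxels, v3$voxels))
  # HU classes present: air, bag, body, plate
  expect_lt(min(v1$voxels), -999)
  expect_gt(max(v1$voxels), 150)
  expect_error(make_phantom_ct(phantom_params(body_semi_axes_mm = c(500, 80))),
               "field of view")
})

test_that("generator -> contouring -> meshing recovers the body geometry", {
  vol <- small_phantom(seed = 21L)
  truth <- attr(vol, "truth")
  stack <- contour_phantom(vol, threshold_hu = -300, window = c(-500, 300),
                           min_area_mm2 = 100)
  body <- contour_stack_label(stack, "body")
  pts <- do.call(rbind, lapply(body, function(cc) cc$points))
  a_hat <- (max(pts[, 1]) - min(pts[, 1])) / 2
  b_hat <- (max(pts[, 2]) - min(pts[, 2])) / 2
  vox <- vol$pixel_spacing[1]
  expect_lt(abs(a_hat - truth$body_semi_axes_mm[1]), 2 * vox)
  expect_lt(abs(b_hat - truth$body_semi_axes_mm[2]), 2 * vox)
  mesh <- loft_stack(body, n = 128)
  # truth$length_mm is the first-to-last slice span, i.e. the axial extent
  # the lofted surface actually covers
  analytic <- pi * prod(truth$body_semi_axes_mm) * truth$length_mm
  expect_lt(abs(mesh_volume(mesh) - analytic) / analytic, 0.03)
  # generator-written DICOM reloads voxel-identically
  d <- tempfile()
  write_ct_series(vol, d)
  v2 <- load_ct_series(d)
  expect_equal(v2$voxels, round(vol$voxels), ignore_attr = TRUE)
})

test_that("fixture machines assemble watertight components with stated clearance", {
  for (nm in c("machine_a", "machine_b")) {
    spec <- fixture_machine(nm)
    mm <- build_machine_meshes(spec)
    for (m in mm) expect_true(mesh_is_watertight(m))
    # head-face center distance to isocenter equals the configured clearance
    gun <- mm$gantry_gun
    expect_equal(min(sqrt(rowSums(gun$vertices^2))),
                 spec$isocenter_clearance_mm)
  }
  expect_error(fixture_machine("machine_c"), "arg")
})

test_that("fixture sweeps straddle the margin: colliding and clear cells exist", {
  for (nm in c("machine_a", "machine_b")) {
    spec <- fixture_machine(nm)
    map <- sweep_map(spec, couch_angles_deg = c(0, 330),
                     gantry_angles_deg = seq(0, 350, 30),
                     positions = list(c(0, 0, spec$couch_height_range_mm[1])))
    expect_gt(sum(map$colliding), 0)
    expect_gt(sum(!map$colliding), 0)
  }
})

test_that("the prone board raises the torso and cuts posterior-oblique clearance", {
  vol_b <- make_prone_breast_case(seed = 4L)
  truth <- attr(vol_b, "truth")
  expect_gt(truth$support_top_mm, truth$plate_height_mm)
  stack_b <- contour_phantom(vol_b)
  labs <- unique(vapply(stack_b$contours, function(cc) cc$label, ""))
  expect_true(length(labs) >= 2)  # body+bag collider and the board
  # board contour sits between plate and body
  acc <- contour_stack_label(stack_b, setdiff(labs, "body")[1])
  expect_lt(max(acc[[1]]$points[, 2]), truth$body_center_y)
  expect_gt(max(acc[[1]]$points[, 2]), truth$plate_height_mm)

  # with the couch top parked at the same height, the board lifts the torso
  # toward the head and cuts the posterior-oblique (gantry 310) clearance
  flat <- make_phantom_ct(phantom_params(ny = 240L, noise_seed = 4L))
  spec <- fixture_machine("machine_a")
  clearance_at <- function(vol) {
    stack <- contour_phantom(vol)
    meshes <- suppressWarnings(
      lapply(loft_colliders_for_test(stack), place_patient,
             isocenter_mm = stack$isocenter_mm,
             plate_height_mm = stack$plate_height_mm))
    shift <- c(0, 0, couch_shift_for_top(spec, -200, meshes))
    sc <- assemble_scene(spec, machine_state(310, 0, shift),
                         patient = meshes, check_limits = FALSE)
    collides(sc, spec)$min_clearance_mm
  }
  expect_lt(clearance_at(vol_b), clearance_at(flat))
  # seeded reproducibility
  expect_identical(make_prone_breast_case(seed = 4L)$voxels, vol_b$voxels)
})
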