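test_that("fixture machine files load with all required components and ranges", {
  for (nm in c("machine_a", "machine_b")) {
    spec <- fixture_machine(nm)
    labels <- vapply(spec$components, function(cc) cc$label, "")
    expect_setequal(labels, c("gantry_gun", "gantry_arm", "gantry_wall",
                              "touch_guard", "couch_plate", "couch_rotator",
                              "couch_base"))
    expect_equal(as.numeric(unlist(spec$gantry_angle_range_deg)), c(0, 360))
    expect_gt(length(spec$collision_pairs), 0L)
    expect_true(all(vapply(spec$collision_pairs, function(pp)
      is.null(pp$margin_mm) || pp$margin_mm >= 0, TRUE)))
  }
  spec_a <- fixture_machine("machine_a")
  spec_b <- fixture_machine("machine_b")
  # machine_b: larger head, smaller face clearance
  r_head <- function(s) s$components[[1]]$primitives[[1]]$radius_mm
  expect_gt(r_head(spec_b), r_head(spec_a))
  expect_lt(spec_b$isocenter_clearance_mm, spec_a$isocenter_clearance_mm)
})

test_that("machine file validation reports field paths", {
  tmp <- tempfile(fileext = ".yaml")
  base <- yaml::read_yaml(system.file("extdata", "machine_a.yaml",
                                      package = "rtclear"))
  bad <- base
  bad$components[[1]]$primitives[[1]]$radius_mm <- -5
  yaml::write_yaml(bad, tmp)
  expect_error(load_machine_spec(tmp), "gantry_gun.*radius_mm")

  bad <- base
  bad$components <- Filter(function(cc) cc$label != "touch_guard",
                           bad$components)
  yaml::write_yaml(bad, tmp)
  expect_error(load_machine_spec(tmp), "touch_guard")

  bad <- base
  bad$components[[2]]$primitives[[1]]$shape <- "sphere"
  yaml::write_yaml(bad, tmp)
  expect_error(load_machine_spec(tmp), "unknown shape")

  bad <- base
  bad$components[[3]]$group <- "flying"
  yaml::write_yaml(bad, tmp)
  expect_error(load_machine_spec(tmp), "unknown kinematic group")
})

test_that("primitive meshes are watertight with exact or near-exact volumes", {
  box <- build_primitive_mesh(list(shape = "box", width_mm = 100,
                                   depth_mm = 200, height_mm = 300))
  expect_identical(nrow(box$vertices), 8L)
  expect_identical(nrow(box$faces), 12L)
  expect_equal(mesh_volume(box), 6e6)
  expect_true(mesh_is_watertight(box))

  cyl <- build_primitive_mesh(list(shape = "cylinder", radius_mm = 100,
                                   height_mm = 50, tessellation = 64))
  expect_true(mesh_is_watertight(cyl))
  expect_lt(abs(mesh_volume(cyl) - pi * 100^2 * 50) / (pi * 100^2 * 50),
            0.005)

  hexv <- lapply(0:5, function(k) 10 * c(cos(k * pi / 3), sin(k * pi / 3)))
  hx <- build_primitive_mesh(list(shape = "extruded_polygon",
                                  vertices_mm = hexv, length_mm = 40))
  expect_equal(mesh_volume(hx), 3 * sqrt(3) / 2 * 10^2 * 40)
  expect_true(mesh_is_watertight(hx))

  expect_error(build_primitive_mesh(
    list(shape = "extruded_polygon",
         vertices_mm = list(c(0, 0), c(1, 0), c(2, 0)), length_mm = 10)),
    "degenerate")
})

test_that("facet subdivision refines meshes without changing the solid", {
  p <- list(shape = "box", width_mm = 2600, depth_mm = 500, height_mm = 2600)
  coarse <- build_primitive_mesh(p)
  fine <- build_primitive_mesh(p, max_facet_mm = 150)
  expect_gt(nrow(fine$faces), nrow(coarse$faces))
  expect_true(mesh_is_watertight(fine))
  expect_equal(mesh_volume(fine), mesh_volume(coarse))
  pc <- list(shape = "cylinder", radius_mm = 330, height_mm = 450,
             tessellation = 32)
  expect_equal(mesh_volume(build_primitive_mesh(pc, max_facet_mm = 80)),
               mesh_volume(build_primitive_mesh(pc)))
})

test_that("assembled scenes obey the kinematic conventions", {
  spec <- fixture_machine("machine_a")
  mm <- build_machine_meshes(spec)
  d <- spec$isocenter_clearance_mm

  head_face_center <- function(scene) {
    gun <- Filter(function(e) e$label == "gantry_gun", scene$elements)[[1]]
    v <- gun$mesh$vertices
    # face = ring nearest the isocenter; its centroid is the face center
    dist0 <- sqrt(rowSums(v^2))
    colMeans(v[abs(dist0 - min(dist0)) < 1e-6, , drop = FALSE])
  }
  sc0 <- assemble_scene(spec, machine_state(0), component_meshes = mm)
  expect_equal(head_face_center(sc0), c(0, 0, d), tolerance = 1e-9)
  sc180 <- assemble_scene(spec, machine_state(180), component_meshes = mm)
  expect_equal(head_face_center(sc180), c(0, 0, -d), tolerance = 1e-9)

  # couch shift moves couch_translating meshes only, not the gantry
  scs <- assemble_scene(spec, machine_state(0, 0, c(0, 0, -100)),
                        component_meshes = mm)
  plate0 <- Filter(function(e) e$label == "couch_plate", sc0$elements)[[1]]
  plates <- Filter(function(e) e$label == "couch_plate", scs$elements)[[1]]
  expect_equal(max(plates$mesh$vertices[, 3]),
               max(plate0$mesh$vertices[, 3]) - 100)
  gun0 <- Filter(function(e) e$label == "gantry_gun", sc0$elements)[[1]]
  guns <- Filter(function(e) e$label == "gantry_gun", scs$elements)[[1]]
  expect_equal(guns$mesh$vertices, gun0$mesh$vertices)

  expect_error(assemble_scene(spec, machine_state(0, 0, c(0, 0, -900)),
                              component_meshes = mm), "vertical")
})

test_that("assembly transforms are rigid and 360-degree periodic", {
  spec <- fixture_machine("machine_a")
  mm <- build_machine_meshes(spec)
  sc_a <- assemble_scene(spec, machine_state(37, 50, c(10, -20, -30)),
                         component_meshes = mm)
  sc_b <- assemble_scene(spec, machine_state(37 + 360, 50, c(10, -20, -30)),
                         component_meshes = mm)
  for (k in seq_along(sc_a$elements)) {
    va <- sc_a$elements[[k]]$mesh$vertices
    vb <- sc_b$elements[[k]]$mesh$vertices
    expect_lt(max(abs(va - vb)), 1e-9)
    # rigidity: pairwise distances preserved vs component frame
    v0 <- mm[[sc_a$elements[[k]]$label]]$vertices
    ii <- seq(1, nrow(v0), length.out = min(10, nrow(v0)))
    d0 <- dist(v0[ii, , drop = FALSE])
    da <- dist(va[ii, , drop = FALSE])
    expect_lt(max(abs(d0 - da)) / max(d0), 1e-9)
  }
})

test_that("scene export writes loadable OBJ meshes", {
  spec <- fixture_machine("machine_a")
  sc <- assemble_scene(spec, machine_state(30))
  dir <- tempfile()
  files <- export_scene(sc, dir, format = "obj")
  gun <- read_obj(file.path(dir, "gantry_gun.obj"))
  orig <- Filter(function(e) e$label == "gantry_gun", sc$elements)[[1]]$mesh
  expect_equal(nrow(gun$faces), nrow(orig$faces))
  expect_lt(max(abs(gun$vertices - orig$vertices)), 1e-6)
  stl <- export_scene(sc, dir, format = "stl")
  expect_true(file.size(file.path(dir, "couch_plate.stl")) > 0)
})
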