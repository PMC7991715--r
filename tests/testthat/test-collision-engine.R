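test_that("mesh distance matches axis-aligned constructions", {
  a <- box_mesh(20, 20, 20)
  b <- box_mesh(20, 20, 20, center = c(27, 0, 0))  # 7 mm face gap
  expect_equal(min_distance(a, b), 7, tolerance = 1e-9)
  expect_equal(brute_force_min_distance(a, b), 7, tolerance = 1e-12)
  overlapping <- box_mesh(20, 20, 20, center = c(15, 0, 0))
  expect_identical(min_distance(a, overlapping), 0)
  # touching faces count as distance 0
  touching <- box_mesh(20, 20, 20, center = c(20, 0, 0))
  expect_equal(min_distance(a, touching), 0, tolerance = 1e-12)
  expect_error(min_distance(a, tri_mesh(matrix(0, 0, 3),
                                        matrix(0L, 0, 3))), "empty")
})

test_that("accelerated distance equals the exhaustive oracle on random pairs", {
  set.seed(101)
  for (rep in 1:25) {
    a <- rand_mesh(40, center = stats::runif(3, -60, 60))
    b <- rand_mesh(40, center = stats::runif(3, -60, 60))
    expect_lt(abs(min_distance(a, b) - brute_force_min_distance(a, b)),
              1e-9)
  }
})

test_that("distance is symmetric and invariant under shared rigid motion", {
  set.seed(7)
  a <- rand_mesh(30)
  b <- rand_mesh(30, center = c(80, 10, -20))
  expect_equal(min_distance(a, b), min_distance(b, a), tolerance = 1e-12)
  rt <- rt_compose(gantry_transform(77), couch_transform(123, c(5, 6, 7)))
  expect_equal(min_distance(transform_mesh(a, rt), transform_mesh(b, rt)),
               min_distance(a, b), tolerance = 1e-9)
})

test_that("collision rule is boundary-inclusive and margin-monotone", {
  spec <- fixture_machine("machine_a")
  mm <- build_machine_meshes(spec)
  # patient box exactly 30 mm below the gun face at gantry 0
  pat <- box_mesh(200, 200, 100, center = c(0, 0, 340))
  sc <- assemble_scene(spec, machine_state(), patient = pat,
                       component_meshes = mm)
  res <- collides(sc, spec)
  row <- res$per_pair[res$per_pair$group_b == "patient" &
                        res$per_pair$group_a == "gantry_rotating", ]
  expect_equal(row$clearance_mm, 30, tolerance = 1e-9)
  expect_true(row$colliding)          # clearance == margin counts
  expect_true(res$colliding)
  # 1 mm lower: clear
  pat2 <- box_mesh(200, 200, 100, center = c(0, 0, 339))
  sc2 <- assemble_scene(spec, machine_state(), patient = pat2,
                        component_meshes = mm)
  expect_false(collides(sc2, spec)$colliding)
  # margin monotonicity: colliding at 30 implies colliding at any larger
  expect_true(collides(sc2, spec, margins = list(32))$colliding)
  r30 <- collides(sc, spec, margins = list(30))
  r50 <- collides(sc, spec, margins = list(50))
  expect_true(all(r30$per_pair$colliding <= r50$per_pair$colliding))
})

test_that("sweep cells agree with independent single-state queries", {
  spec <- fixture_machine("machine_a")
  mm <- build_machine_meshes(spec)
  couch <- c(0, 40, 330)
  gantry <- seq(0, 350, by = 50)
  pos <- list(c(0, 0, -100), c(0, 0, -400))
  map <- sweep_map(spec, couch_angles_deg = couch, gantry_angles_deg = gantry,
                   positions = pos, component_meshes = mm)
  expect_identical(dim(map$colliding),
                   c(length(couch), length(gantry), length(pos)))
  expect_true(any(map$colliding) && any(!map$colliding))
  set.seed(2)
  for (rep in 1:6) {
    i <- sample(length(couch), 1); j <- sample(length(gantry), 1)
    k <- sample(length(pos), 1)
    sc <- assemble_scene(spec, machine_state(gantry[j], couch[i], pos[[k]]),
                         component_meshes = mm)
    res <- collides(sc, spec)
    expect_identical(map$colliding[i, j, k], res$colliding)
    expect_equal(map$clearance_mm[i, j, k], min(res$min_clearance_mm, 200),
                 tolerance = 1e-9)
  }
  # flags equal the boundary-inclusive rule applied to the clearances
  # (margin 30 everywhere except the touch-guard pairs, which only fire on
  # contact and are strictly closer than the gun by construction)
  csv <- tempfile(fileext = ".csv")
  write_collision_map(map, csv)
  df <- utils::read.csv(csv)
  expect_identical(nrow(df), length(map$colliding))
  expect_identical(df$colliding, as.vector(map$colliding))
})

test_that("boundary gantry angle search matches a closed-form point obstacle", {
  spec <- fixture_machine("machine_a")
  mm <- build_machine_meshes(spec)
  # a pea-sized obstacle on the couch: closed-form distance from a point to
  # the gun solid (capped cylinder of radius R whose face sits at distance
  # D from the isocenter along the beam axis)
  q <- c(250, 0, -320)
  pea <- box_mesh(1, 1, 1, center = q)
  attr(pea, "couch_top_mm") <- NULL
  D <- spec$isocenter_clearance_mm
  R <- spec$components[[1]]$primitives[[1]]$radius_mm
  H <- spec$components[[1]]$primitives[[1]]$height_mm
  gun_point_dist <- function(theta_deg) {
    th <- theta_deg * pi / 180
    axis <- c(sin(th), 0, cos(th))
    t_ <- sum(q * axis)                      # axial coordinate
    r_ <- sqrt(max(sum(q^2) - t_^2, 0))      # radial coordinate
    dt <- max(D - t_, t_ - (D + H), 0)
    dr <- max(r_ - R, 0)
    sqrt(dt^2 + dr^2)
  }
  margin <- spec$default_margin_mm
  # oracle: first angle (1-degree grid, cw) with distance <= margin + pea size
  ds <- vapply(0:359, gun_point_dist, 0)
  oracle_cw <- (0:359)[min(which(ds - sqrt(3) / 2 <= margin))]
  found <- boundary_gantry_angles(spec, pea, couch_angle_deg = 0,
                                  position = c(0, 0, 0), direction = "cw",
                                  step_deg = 1, component_meshes = mm)
  # the pea has finite extent (half-diagonal sqrt(3)/2): allow 1 step
  expect_lt(abs(found$rotation_deg - oracle_cw), 1.5)
  # empty room at safe height: no boundary
  none <- boundary_gantry_angles(spec, NULL, couch_angle_deg = 0,
                                 position = c(0, 0, 0), direction = "cw",
                                 step_deg = 10, component_meshes = mm)
  expect_true(is.na(none$angle_deg))
  # halving the step never moves the answer away from the fine answer
  fine <- boundary_gantry_angles(spec, pea, 0, c(0, 0, 0), "cw", 0.25,
                                 component_meshes = mm)
  for (st in c(4, 2, 1)) {
    got <- boundary_gantry_angles(spec, pea, 0, c(0, 0, 0), "cw", st,
                                  component_meshes = mm)
    expect_lte(abs(got$rotation_deg - fine$rotation_deg), st)
  }
})

test_that("trajectory events fire enter/stay/exit in order", {
  spec <- fixture_machine("machine_a")
  # low couch: a gantry path that crosses one colliding arc
  path <- seq(60, 200, by = 10)
  ev <- trajectory_events(spec, NULL,
                          couch_state = machine_state(0, 0, c(0, 0, -450)),
                          gantry_path = path)
  plate_ev <- ev[ev$pair == "gantry_rotating|couch_translating", ]
  if (nrow(plate_ev) > 0) {
    expect_identical(plate_ev$event[1], "enter")
    enters <- which(plate_ev$event == "enter")
    exits <- which(plate_ev$event == "exit")
    if (length(exits) > 0) expect_true(min(enters) < min(exits))
    # stay only between enter and exit
    expect_true(all(diff(plate_ev$index) >= 0))
  }
  # fully clear path -> no events
  ev2 <- trajectory_events(spec, NULL,
                           couch_state = machine_state(0, 0, c(0, 0, 0)),
                           gantry_path = c(350, 0, 10))
  expect_identical(nrow(ev2), 0L)
  # entirely colliding path: one enter at the first sample, stays, no exit
  pat <- box_mesh(600, 600, 40, center = c(0, 0, 400))
  ev3 <- trajectory_events(spec, pat, couch_state = machine_state(),
                           gantry_path = c(355, 0, 5))
  pe <- ev3[ev3$pair == "gantry_rotating|patient", ]
  expect_identical(pe$event, c("enter", "stay", "stay"))
  expect_identical(pe$index[1], 1L)
})
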