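#' Load a parametric machine description
#'
#' Reads a YAML machine file describing one linear accelerator as a set of
#' labelled polygonal components (each a list of solid primitives in its
#' component frame), kinematic group assignments, travel limits, and the
#' monitored collision pairs. The file schema is documented in
#' `inst/extdata/machine-schema.md`; two generic fixture machines ship with
#' the package (see [fixture_machine()]).
#'
#' Required component labels: `gantry_gun`, `gantry_arm`, `gantry_wall`,
#' `touch_guard`, `couch_plate`, `couch_rotator`, `couch_base`.
#'
#' @param path YAML machine description file.
#' @return a validated object of class `machine_spec`.
#' @export
load_machine_spec <- function(path) {
  if (!file.exists(path)) stop("machine file not found: ", path)
  raw <- yaml::read_yaml(path)
  validate_machine_spec(raw, src = path)
}

required_labels <- c("gantry_gun", "gantry_arm", "gantry_wall", "touch_guard",
                     "couch_plate", "couch_rotator", "couch_base")
known_groups <- c("gantry_rotating", "couch_rotating", "couch_translating", "static")
known_shapes <- c("box", "cylinder", "truncated_cone", "extruded_polygon")

validate_machine_spec <- function(raw, src = "machine spec") {
  fail <- function(field, msg) stop(src, ": ", field, ": ", msg, call. = FALSE)
  if (is.null(raw$name)) fail("name", "missing")
  comps <- raw$components
  if (is.null(comps) || length(comps) == 0L) fail("components", "missing")
  labels <- vapply(comps, function(cc) cc$label %||% NA_character_, "")
  missing_req <- setdiff(required_labels, labels)
  if (length(missing_req) > 0L)
    fail("components", paste("missing required component(s):",
                             paste(missing_req, collapse = ", ")))
  for (cc in comps) {
    where <- paste0("components/", cc$label)
    if (!(cc$group %in% known_groups))
      fail(paste0(where, "/group"), paste("unknown kinematic group:", cc$group))
    if (is.null(cc$primitives) || length(cc$primitives) == 0L)
      fail(where, "no primitives")
    for (k in seq_along(cc$primitives)) {
      pr <- cc$primitives[[k]]
      pwhere <- paste0(where, "/primitives[", k, "]")
      if (is.null(pr$shape) || !(pr$shape %in% known_shapes))
        fail(pwhere, paste("unknown shape:", pr$shape %||% "<missing>"))
      dims <- switch(pr$shape,
        box = c(width_mm = pr$width_mm, depth_mm = pr$depth_mm,
                height_mm = pr$height_mm),
        cylinder = c(radius_mm = pr$radius_mm, height_mm = pr$height_mm),
        truncated_cone = c(r_bottom_mm = pr$r_bottom_mm,
                           r_top_mm = pr$r_top_mm, height_mm = pr$height_mm),
        extruded_polygon = c(length_mm = pr$length_mm))
      bad <- names(dims)[!vapply(dims, function(d)
        !is.null(d) && is.finite(d) && d > 0, TRUE)]
      if (length(bad) > 0L)
        fail(paste0(pwhere, "/", bad[1]), "non-positive or missing dimension")
      if (pr$shape == "extruded_polygon") {
        vv <- pr$vertices_mm
        if (is.null(vv) || length(vv) < 3L)
          fail(pwhere, "polygon needs >= 3 vertices")
      }
      if (!is.null(pr$tessellation) && pr$tessellation < 8L)
        fail(paste0(pwhere, "/tessellation"), "must be >= 8")
    }
  }
  gr <- raw$gantry_angle_range_deg %||% c(0, 360)
  if (gr[1] > 0 || gr[2] < 360)
    fail("gantry_angle_range_deg", "gantry range must cover 360 degrees")
  pairs <- raw$collision_pairs
  if (is.null(pairs) || length(pairs) == 0L) fail("collision_pairs", "empty")
  valid_refs <- c(known_groups, labels, "patient")
  for (k in seq_along(pairs)) {
    pp <- pairs[[k]]
    for (side in c("a", "b"))
      if (!(pp[[side]] %in% valid_refs))
        fail(paste0("collision_pairs[", k, "]/", side),
             paste("unknown group or label:", pp[[side]]))
    if (!is.null(pp$margin_mm) && pp$margin_mm < 0)
      fail(paste0("collision_pairs[", k, "]/margin_mm"), "must be >= 0")
  }
  if ((raw$default_margin_mm %||% 30) < 0) fail("default_margin_mm", "must be >= 0")
  spec <- list(
    name = raw$name,
    components = comps,
    isocenter_clearance_mm = raw$isocenter_clearance_mm %||%
      fail("isocenter_clearance_mm", "missing"),
    default_margin_mm = raw$default_margin_mm %||% 30,
    couch_top_mm = raw$couch_top_mm %||% 0,
    gantry_angle_range_deg = gr,
    couch_angle_range_deg = raw$couch_angle_range_deg %||% c(0, 360),
    couch_height_range_mm = raw$couch_height_range_mm %||% c(-450, 50),
    couch_shift_ranges_mm = list(
      lateral = raw$couch_shift_ranges_mm$lateral %||% c(-200, 200),
      longitudinal = raw$couch_shift_ranges_mm$longitudinal %||% c(-250, 250),
      vertical = raw$couch_shift_ranges_mm$vertical %||%
        raw$couch_height_range_mm %||% c(-450, 50)),
    collision_pairs = pairs
  )
  structure(spec, class = "machine_spec")
}

#' @export
print.machine_spec <- function(x, ...) {
  cat(sprintf("<machine_spec '%s': %d components, clearance %g mm, margin %g mm>\n",
              x$name, length(x$components), x$isocenter_clearance_mm,
              x$default_margin_mm))
  invisible(x)
}

#' Build all component meshes of a machine
#'
#' Each component's primitives are meshed in the component frame and merged;
#' multi-primitive components remain unions of watertight solids.
#'
#' @param spec a [load_machine_spec()] result.
#' @param tessellation optional override of every curved primitive's segment
#'   count (used by the validation harness to build coarse/fine variants).
#' @param max_facet_mm facet-size bound passed to [build_primitive_mesh()].
#' @return named list of [tri_mesh()], one per component, each with
#'   attribute `group`.
#' @export
build_machine_meshes <- function(spec, tessellation = NULL,
                                 max_facet_mm = 150) {
  out <- list()
  for (cc in spec$components) {
    meshes <- lapply(cc$primitives, function(pr) {
      if (!is.null(tessellation) && pr$shape %in% c("cylinder", "truncated_cone"))
        pr$tessellation <- tessellation
      build_primitive_mesh(pr, max_facet_mm = max_facet_mm)
    })
    m <- merge_meshes(meshes)
    attr(m, "group") <- cc$group
    out[[cc$label]] <- m
  }
  out
}

merge_meshes <- function(meshes) {
  if (length(meshes) == 1L) return(meshes[[1L]])
  off <- 0L
  v <- list(); f <- list()
  for (m in meshes) {
    v[[length(v) + 1L]] <- m$vertices
    f[[length(f) + 1L]] <- m$faces + off
    off <- off + nrow(m$vertices)
  }
  tri_mesh(do.call(rbind, v), do.call(rbind, f))
}

check_state_limits <- function(spec, state) {
  s <- state$couch_shift_mm
  lims <- list(lateral = spec$couch_shift_ranges_mm$lateral,
               longitudinal = spec$couch_shift_ranges_mm$longitudinal,
               vertical = spec$couch_shift_ranges_mm$vertical)
  for (i in 1:3) {
    axis <- names(lims)[i]
    r <- lims[[i]]
    if (s[i] < r[1] - 1e-9 || s[i] > r[2] + 1e-9)
      stop("couch ", axis, " shift ", s[i], " mm outside travel limits [",
           r[1], ", ", r[2], "]", call. = FALSE)
  }
  invisible(TRUE)
}

#' Assemble the treatment-room scene at one machine state
#'
#' Applies the gantry rotation to every `gantry_rotating` component, the
#' couch rotation to `couch_rotating` components, the full couch transform
#' (shift then rotation) to `couch_translating` components and to the
#' patient colliders, and leaves `static` components unchanged. When a
#' patient is present the couch assembly is leveled so the couch-plate top
#' coincides with the patient's CT plate surface (attribute `couch_top_mm`
#' set by [place_patient()]), which keeps the patient isocenter on the room
#' isocenter at zero couch state.
#'
#' @param spec a [load_machine_spec()] result.
#' @param state a [machine_state()].
#' @param patient optional patient collider: a [tri_mesh()] in the couch
#'   frame (from [place_patient()]) or a named list of such meshes.
#' @param component_meshes optional precomputed [build_machine_meshes()]
#'   result (rebuilt from `spec` when omitted).
#' @param check_limits stop when the state lies outside travel limits
#'   (set `FALSE` to override).
#' @return object of class `scene`: list of elements, each
#'   `list(label, group, mesh)` with the mesh in the room frame.
#' @export
assemble_scene <- function(spec, state = machine_state(), patient = NULL,
                           component_meshes = NULL, check_limits = TRUE) {
  if (check_limits) check_state_limits(spec, state)
  if (is.null(component_meshes)) component_meshes <- build_machine_meshes(spec)
  g_rt <- gantry_transform(state$gantry_angle_deg)
  c_full <- couch_transform(state$couch_angle_deg, state$couch_shift_mm)
  c_rot <- couch_transform(state$couch_angle_deg, c(0, 0, 0))

  patient_list <- NULL
  level_dz <- 0
  if (!is.null(patient)) {
    if (inherits(patient, "tri_mesh")) patient_list <- list(patient = patient)
    else patient_list <- patient
    tops <- vapply(patient_list, function(m)
      attr(m, "couch_top_mm") %||% NA_real_, 0)
    top <- tops[!is.na(tops)]
    if (length(top) > 0L) level_dz <- top[[1L]] - spec$couch_top_mm
  }

  elements <- list()
  for (label in names(component_meshes)) {
    m <- component_meshes[[label]]
    group <- attr(m, "group")
    m2 <- switch(group,
      gantry_rotating = transform_mesh(m, g_rt, frame = "room"),
      couch_translating = transform_mesh(
        if (level_dz != 0) translate_mesh(m, c(0, 0, level_dz)) else m,
        c_full, frame = "room"),
      couch_rotating = transform_mesh(
        if (level_dz != 0) translate_mesh(m, c(0, 0, level_dz)) else m,
        c_rot, frame = "room"),
      static = m)
    elements[[length(elements) + 1L]] <-
      list(label = label, group = group, mesh = m2)
  }
  for (label in names(patient_list)) {
    m2 <- transform_mesh(patient_list[[label]], c_full, frame = "room")
    elements[[length(elements) + 1L]] <-
      list(label = label, group = "patient", mesh = m2)
  }
  structure(list(elements = elements, state = state, machine = spec$name),
            class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene: machine '%s', %d meshes>\n", x$machine,
              length(x$elements)))
  for (e in x$elements)
    cat(sprintf("  %-14s %-18s %6d tris\n", e$label, e$group,
                nrow(e$mesh$faces)))
  invisible(x)
}

#' Export every mesh of a scene
#'
#' Writes one STL or OBJ file per scene element into a directory.
#'
#' @param scene an [assemble_scene()] result.
#' @param dir output directory (created if needed).
#' @param format `"stl"` or `"obj"`.
#' @return character vector of files written, invisibly.
#' @export
export_scene <- function(scene, dir, format = c("stl", "obj")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writer <- if (format == "stl") write_stl else write_obj
  paths <- character(0)
  for (e in scene$elements) {
    p <- file.path(dir, paste0(e$label, ".", format))
    writer(e$mesh, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
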