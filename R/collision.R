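#' Minimum distance between two mesh surfaces
#'
#' Euclidean minimum distance between triangle surfaces; 0 when they
#' intersect or touch. BVH-accelerated; agrees with the exhaustive
#' [brute_force_min_distance()] oracle to 1e-9 mm.
#'
#' @param a,b [tri_mesh()]es (non-empty).
#' @return distance in mm.
#' @export
min_distance <- function(a, b) {
  if (nrow(a$faces) == 0L || nrow(b$faces) == 0L) stop("empty mesh")
  cpp_mesh_distance(a$vertices, a$faces, b$vertices, b$faces)
}

# Resolve the monitored pairs of a scene: for each collision_pairs entry,
# the scene elements whose group or label matches each side, minus any
# excluded labels. Returns a list of list(a_idx, b_idx, margin, name_a,
# name_b).
resolve_pairs <- function(spec, scene, margins = NULL) {
  labs <- vapply(scene$elements, function(e) e$label, "")
  grps <- vapply(scene$elements, function(e) e$group, "")
  out <- list()
  for (pp in spec$collision_pairs) {
    sel <- function(ref) which(labs == ref | grps == ref)
    ia <- sel(pp$a)
    ib <- sel(pp$b)
    excl <- unlist(pp$exclude)
    if (!is.null(excl)) {
      ia <- ia[!(labs[ia] %in% excl)]
      ib <- ib[!(labs[ib] %in% excl)]
    }
    if (length(ia) == 0L || length(ib) == 0L) next
    margin <- pp$margin_mm %||% spec$default_margin_mm
    if (!is.null(margins)) {
      key <- paste(pp$a, pp$b, sep = "|")
      if (!is.null(margins[[key]])) margin <- margins[[key]]
      else if (length(margins) == 1L && is.null(names(margins)))
        margin <- margins[[1L]]
    }
    out[[length(out) + 1L]] <-
      list(a = ia, b = ib, margin = margin, name_a = pp$a, name_b = pp$b)
  }
  if (length(out) == 0L) stop("no monitored collision pair present in scene")
  out
}

#' Collision query on an assembled scene
#'
#' A monitored pair collides when its clearance (minimum surface distance
#' over all component combinations of the pair) is less than or equal to
#' its margin; the boundary counts as a collision (conservative). The
#' default margin is the machine's `default_margin_mm` (30 mm safety zone);
#' touch-guard pairs in the fixture machines use margin 0 because the guard
#' itself is the buffer.
#'
#' @param scene an [assemble_scene()] result.
#' @param spec the machine spec the scene was assembled from.
#' @param margins optional override: a single unnamed value applied to
#'   every pair, or a named list `"groupA|groupB" = margin`.
#' @return object of class `collision_result`: `colliding` flag, data frame
#'   `per_pair` (group_a, group_b, clearance_mm, margin_mm, colliding), and
#'   `min_clearance_mm`.
#' @export
collides <- function(scene, spec, margins = NULL) {
  pairs <- resolve_pairs(spec, scene, margins)
  meshes <- lapply(scene$elements, function(e) e$mesh)
  rows <- lapply(pairs, function(pp) {
    d <- Inf
    for (i in pp$a) for (j in pp$b) {
      if (i == j) next
      d <- min(d, min_distance(meshes[[i]], meshes[[j]]))
    }
    data.frame(group_a = pp$name_a, group_b = pp$name_b,
               clearance_mm = d, margin_mm = pp$margin,
               colliding = d <= pp$margin)
  })
  per_pair <- do.call(rbind, rows)
  structure(list(colliding = any(per_pair$colliding),
                 per_pair = per_pair,
                 min_clearance_mm = min(per_pair$clearance_mm)),
            class = "collision_result")
}

#' @export
print.collision_result <- function(x, ...) {
  cat(sprintf("<collision_result: %s, min clearance %.2f mm>\n",
              if (x$colliding) "COLLIDING" else "clear", x$min_clearance_mm))
  print(x$per_pair, row.names = FALSE)
  invisible(x)
}

# Fast path for sweeps: pre-transformed couch-side meshes fixed, gantry
# meshes rotated per angle; pair clearances via one grouped BVH query.
sweep_couch_state <- function(spec, component_meshes, patient_list,
                              couch_angle, shift, gantry_angles,
                              margins = NULL, clearance_cap_mm = 200) {
  c_full <- couch_transform(couch_angle, shift)
  c_rot <- couch_transform(couch_angle, c(0, 0, 0))
  level_dz <- 0
  if (length(patient_list) > 0L) {
    tops <- vapply(patient_list, function(m) attr(m, "couch_top_mm") %||% NA_real_, 0)
    top <- tops[!is.na(tops)]
    if (length(top) > 0L) level_dz <- top[[1L]] - spec$couch_top_mm
  }
  fixed <- list(); fixed_labs <- character(); fixed_grps <- character()
  gantry <- list(); gantry_labs <- character()
  for (label in names(component_meshes)) {
    m <- component_meshes[[label]]
    group <- attr(m, "group")
    if (group == "gantry_rotating") {
      gantry[[length(gantry) + 1L]] <- m
      gantry_labs <- c(gantry_labs, label)
    } else {
      m2 <- switch(group,
        couch_translating = transform_mesh(
          if (level_dz != 0) translate_mesh(m, c(0, 0, level_dz)) else m, c_full),
        couch_rotating = transform_mesh(
          if (level_dz != 0) translate_mesh(m, c(0, 0, level_dz)) else m, c_rot),
        static = m)
      fixed[[length(fixed) + 1L]] <- m2
      fixed_labs <- c(fixed_labs, label)
      fixed_grps <- c(fixed_grps, group)
    }
  }
  for (label in names(patient_list)) {
    fixed[[length(fixed) + 1L]] <-
      transform_mesh(patient_list[[label]], c_full)
    fixed_labs <- c(fixed_labs, label)
    fixed_grps <- c(fixed_grps, "patient")
  }
  # resolve pairs once against the label/group tables
  pairs <- list()
  for (pp in spec$collision_pairs) {
    excl <- unlist(pp$exclude)
    side <- function(ref, labs, grps) {
      ix <- which(labs == ref | grps == ref)
      if (!is.null(excl)) ix <- ix[!(labs[ix] %in% excl)]
      ix
    }
    ga <- side(pp$a, gantry_labs, rep("gantry_rotating", length(gantry_labs)))
    fb <- side(pp$b, fixed_labs, fixed_grps)
    gb <- side(pp$b, gantry_labs, rep("gantry_rotating", length(gantry_labs)))
    fa <- side(pp$a, fixed_labs, fixed_grps)
    # keep only gantry-vs-fixed pairs (gantry-gantry and fixed-fixed do not
    # change along a gantry sweep and are not monitored by the fixtures)
    gi <- if (length(ga) > 0L && length(fb) > 0L) list(g = ga, f = fb)
      else if (length(gb) > 0L && length(fa) > 0L) list(g = gb, f = fa)
      else next
    margin <- pp$margin_mm %||% spec$default_margin_mm
    if (!is.null(margins)) {
      key <- paste(pp$a, pp$b, sep = "|")
      if (!is.null(margins[[key]])) margin <- margins[[key]]
      else if (length(margins) == 1L && is.null(names(margins)))
        margin <- margins[[1L]]
    }
    pairs[[length(pairs) + 1L]] <- c(gi, list(margin = margin,
                                              name_a = pp$a, name_b = pp$b))
  }
  if (length(pairs) == 0L) stop("no monitored collision pair present in scene")
  FV <- lapply(fixed, function(m) m$vertices)
  FF <- lapply(fixed, function(m) m$faces)
  GV <- lapply(gantry, function(m) m$vertices)
  GF <- lapply(gantry, function(m) m$faces)
  n_g <- length(gantry_angles)
  na <- length(gantry)
  # (na*nb) x n_angles distance matrix, fixed trees built once in C++
  dall <- cpp_sweep_gantry(GV, GF, FV, FF, as.numeric(gantry_angles),
                           clearance_cap_mm)
  clearance <- rep(Inf, n_g)
  colliding <- logical(n_g)
  for (pp in pairs) {
    rows <- as.vector(outer(pp$g, (pp$f - 1L) * na, "+"))
    d <- if (length(rows) == 1L) dall[rows, ] else
      apply(dall[rows, , drop = FALSE], 2, min)
    clearance <- pmin(clearance, d)
    colliding <- colliding | (d <= pp$margin)
  }
  list(clearance = clearance, colliding = colliding)
}

#' Sweep the configuration space into a collision map
#'
#' Evaluates [collides()] on the cartesian grid couch angle x gantry angle
#' x couch position. Cells are independent (the map does not depend on
#' evaluation order); the default grids mirror the clinical validation
#' layout: couch 0-90 and 270-350 in 10-degree steps (19 values), gantry
#' 0-350 in 10-degree steps (36 values).
#'
#' @param spec a [load_machine_spec()] result.
#' @param patient optional placed patient collider(s) (see
#'   [place_patient()]); `NULL` for an empty couch.
#' @param couch_angles_deg,gantry_angles_deg angle grids, degrees.
#' @param positions list of couch shift triples (lateral, longitudinal,
#'   vertical), mm.
#' @param margins optional margin override (see [collides()]).
#' @param component_meshes optional precomputed [build_machine_meshes()].
#' @param check_limits verify every position against travel limits.
#' @param clearance_cap_mm clearances are reported exactly up to this cap
#'   and saturate at it beyond (far pairs are pruned early); must exceed
#'   every monitored margin. `Inf` for fully exact clearances.
#' @return object of class `collision_map`: grids plus arrays `colliding`
#'   and `clearance_mm`, both `|couch| x |gantry| x |positions|`.
#' @export
sweep_map <- function(spec, patient = NULL,
                      couch_angles_deg = default_couch_angles(),
                      gantry_angles_deg = seq(0, 350, by = 10),
                      positions = list(c(0, 0, 0)),
                      margins = NULL, component_meshes = NULL,
                      check_limits = TRUE, clearance_cap_mm = 200) {
  stopifnot(length(couch_angles_deg) > 0, length(gantry_angles_deg) > 0,
            length(positions) > 0)
  if (is.null(component_meshes)) component_meshes <- build_machine_meshes(spec)
  patient_list <- if (is.null(patient)) list()
    else if (inherits(patient, "tri_mesh")) list(patient = patient)
    else patient
  if (check_limits)
    for (s in positions)
      check_state_limits(spec, machine_state(0, 0, s))
  nc <- length(couch_angles_deg); ng <- length(gantry_angles_deg)
  np <- length(positions)
  colliding <- array(NA, dim = c(nc, ng, np))
  clearance <- array(NA_real_, dim = c(nc, ng, np))
  for (k in seq_len(np)) {
    for (i in seq_len(nc)) {
      res <- sweep_couch_state(spec, component_meshes, patient_list,
                               couch_angles_deg[i], positions[[k]],
                               gantry_angles_deg, margins, clearance_cap_mm)
      colliding[i, , k] <- res$colliding
      clearance[i, , k] <- res$clearance
    }
  }
  structure(list(machine = spec$name,
                 couch_angles_deg = couch_angles_deg,
                 gantry_angles_deg = gantry_angles_deg,
                 positions = positions,
                 colliding = colliding,
                 clearance_mm = clearance),
            class = "collision_map")
}

#' The 19 clinically swept couch angles
#'
#' 0-90 counter-clockwise and 270-350 clockwise in 10-degree steps.
#' @return numeric vector of 19 angles.
#' @export
default_couch_angles <- function() c(seq(0, 90, 10), seq(270, 350, 10))

#' @export
print.collision_map <- function(x, ...) {
  n <- length(x$colliding)
  cat(sprintf(
    "<collision_map '%s': %d couch x %d gantry x %d positions = %d cells, %d colliding>\n",
    x$machine, length(x$couch_angles_deg), length(x$gantry_angles_deg),
    length(x$positions), n, sum(x$colliding)))
  invisible(x)
}

#' Write a collision map as CSV
#'
#' One row per cell: machine, couch angle, gantry angle, shift triple,
#' colliding flag, minimum clearance.
#'
#' @param map a [sweep_map()] result.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_collision_map <- function(map, path) {
  grid <- expand.grid(ci = seq_along(map$couch_angles_deg),
                      gi = seq_along(map$gantry_angles_deg),
                      pi = seq_along(map$positions))
  shifts <- do.call(rbind, map$positions)
  df <- data.frame(
    machine = map$machine,
    couch_deg = map$couch_angles_deg[grid$ci],
    gantry_deg = map$gantry_angles_deg[grid$gi],
    shift_x_mm = shifts[grid$pi, 1],
    shift_y_mm = shifts[grid$pi, 2],
    shift_z_mm = shifts[grid$pi, 3],
    colliding = map$colliding[cbind(grid$ci, grid$gi, grid$pi)],
    min_clearance_mm = map$clearance_mm[cbind(grid$ci, grid$gi, grid$pi)])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Heatmap of one couch position of a collision map
#'
#' @param x a [sweep_map()] result.
#' @param position_index which couch position to draw.
#' @param ... unused.
#' @return the map, invisibly.
#' @export
plot.collision_map <- function(x, position_index = 1L, ...) {
  m <- x$colliding[, , position_index]
  graphics::image(x = seq_along(x$couch_angles_deg),
                  y = seq_along(x$gantry_angles_deg), z = m * 1,
                  col = c("#2b6cb0", "#c53030"), axes = FALSE,
                  xlab = "couch angle (deg)", ylab = "gantry angle (deg)",
                  main = sprintf("%s, position %d", x$machine, position_index))
  graphics::axis(1, at = seq_along(x$couch_angles_deg),
                 labels = x$couch_angles_deg, las = 2, cex.axis = 0.6)
  graphics::axis(2, at = seq_along(x$gantry_angles_deg),
                 labels = x$gantry_angles_deg, las = 1, cex.axis = 0.6)
  invisible(x)
}

#' First colliding gantry angle from 0 in a given direction
#'
#' Rotates the gantry from 0 degrees in steps of `step_deg`, clockwise
#' (increasing angle) or counter-clockwise (decreasing), and reports the
#' first colliding angle, i.e. the collision-boundary angle quantized to
#' the step. `NA` when the full rotation is clear.
#'
#' @param spec machine spec.
#' @param patient optional placed patient collider(s).
#' @param couch_angle_deg couch angle.
#' @param position couch shift triple, mm.
#' @param direction `"cw"` (angle increasing from 0) or `"ccw"`.
#' @param step_deg angular step (> 0).
#' @param margins optional margin override.
#' @param component_meshes optional precomputed machine meshes.
#' @details Only the colliding flag matters here, so distance queries are
#' capped just above the largest monitored margin and the rotation is
#' scanned outward in chunks with early exit.
#' @return list with `angle_deg` (normalized colliding angle or `NA`) and
#'   `rotation_deg` (magnitude of rotation from 0, or `NA`).
#' @export
boundary_gantry_angles <- function(spec, patient = NULL, couch_angle_deg = 0,
                                   position = c(0, 0, 0),
                                   direction = c("cw", "ccw"), step_deg = 1,
                                   margins = NULL, component_meshes = NULL) {
  direction <- match.arg(direction)
  stopifnot(step_deg > 0)
  if (is.null(component_meshes)) component_meshes <- build_machine_meshes(spec)
  patient_list <- if (is.null(patient)) list()
    else if (inherits(patient, "tri_mesh")) list(patient = patient)
    else patient
  cap <- max_monitored_margin(spec, margins) + 1
  rotations <- seq(0, 360 - step_deg / 2, by = step_deg)
  chunk <- 45L
  for (start in seq(1L, length(rotations), by = chunk)) {
    rot <- rotations[start:min(start + chunk - 1L, length(rotations))]
    angles <- if (direction == "cw") rot else normalize_angle(-rot)
    res <- sweep_couch_state(spec, component_meshes, patient_list,
                             couch_angle_deg, position, angles, margins,
                             clearance_cap_mm = cap)
    hit <- which(res$colliding)
    if (length(hit) > 0L)
      return(list(angle_deg = angles[hit[1L]], rotation_deg = rot[hit[1L]]))
  }
  list(angle_deg = NA_real_, rotation_deg = NA_real_)
}

# Largest margin among the spec's monitored pairs under an override.
max_monitored_margin <- function(spec, margins = NULL) {
  ms <- vapply(spec$collision_pairs, function(pp) {
    margin <- pp$margin_mm %||% spec$default_margin_mm
    if (!is.null(margins)) {
      key <- paste(pp$a, pp$b, sep = "|")
      if (!is.null(margins[[key]])) margin <- margins[[key]]
      else if (length(margins) == 1L && is.null(names(margins)))
        margin <- margins[[1L]]
    }
    margin
  }, 0)
  max(ms)
}

#' Trigger-style events along a gantry trajectory
#'
#' Walks an ordered gantry angle path at a fixed couch state and emits, per
#' monitored pair, `enter` on the clear-to-colliding transition, `stay`
#' while colliding persists, and `exit` on colliding-to-clear; a path that
#' starts inside a collision arc opens with `enter` at its first sample.
#'
#' @param spec machine spec.
#' @param patient optional placed patient collider(s).
#' @param couch_state a [machine_state()] providing couch angle and shift
#'   (its gantry angle is ignored).
#' @param gantry_path ordered gantry angle samples, degrees (>= 2).
#' @param margins optional margin override.
#' @return data frame with columns `index`, `gantry_deg`, `pair`, `event`.
#' @export
trajectory_events <- function(spec, patient = NULL,
                              couch_state = machine_state(),
                              gantry_path, margins = NULL) {
  stopifnot(length(gantry_path) >= 2L)
  component_meshes <- build_machine_meshes(spec)
  patient_list <- if (is.null(patient)) list()
    else if (inherits(patient, "tri_mesh")) list(patient = patient)
    else patient
  # per-pair colliding flags along the path
  meshes_states <- lapply(gantry_path, function(g) {
    sc <- assemble_scene(spec, machine_state(g, couch_state$couch_angle_deg,
                                             couch_state$couch_shift_mm),
                         patient = if (length(patient_list)) patient_list else NULL,
                         component_meshes = component_meshes,
                         check_limits = FALSE)
    collides(sc, spec, margins)$per_pair
  })
  pairs <- paste(meshes_states[[1]]$group_a, meshes_states[[1]]$group_b, sep = "|")
  events <- list()
  for (p in seq_along(pairs)) {
    prev <- FALSE
    for (t in seq_along(gantry_path)) {
      cur <- meshes_states[[t]]$colliding[p]
      ev <- if (cur && !prev) "enter" else if (cur && prev) "stay"
        else if (!cur && prev) "exit" else NA_character_
      if (!is.na(ev))
        events[[length(events) + 1L]] <-
          data.frame(index = t, gantry_deg = gantry_path[t],
                     pair = pairs[p], event = ev)
      prev <- cur
    }
  }
  if (length(events) == 0L)
    return(data.frame(index = integer(), gantry_deg = numeric(),
                      pair = character(), event = character()))
  out <- do.call(rbind, events)
  out[order(out$index, out$pair), , drop = FALSE]
}
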