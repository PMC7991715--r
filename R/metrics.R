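#' Confusion-matrix summary of a predicted collision map against truth
#'
#' Positive = collision. Accuracy = (TP + TN) / (TP + TN + FP + FN),
#' TPR = TP / (TP + FN), TNR = TN / (TN + FP); a rate with a zero
#' denominator is reported as `NA`, never as 0 or 1.
#'
#' @param pred,truth [sweep_map()] results on identical grids, or bare
#'   logical arrays of equal shape.
#' @return object of class `confusion_summary` with counts `tp`, `tn`,
#'   `fp`, `fn` and rates `accuracy`, `tpr`, `tnr`.
#' @export
confusion_summary <- function(pred, truth) {
  as_flags <- function(x) if (inherits(x, "collision_map")) x$colliding else x
  check_grids <- function(a, b) {
    if (inherits(a, "collision_map") && inherits(b, "collision_map")) {
      if (!isTRUE(all.equal(a$couch_angles_deg, b$couch_angles_deg)) ||
          !isTRUE(all.equal(a$gantry_angles_deg, b$gantry_angles_deg)) ||
          length(a$positions) != length(b$positions))
        stop("prediction and truth grids differ")
    }
  }
  check_grids(pred, truth)
  p <- as_flags(pred)
  t_ <- as_flags(truth)
  if (!identical(dim(p), dim(t_)) || length(p) != length(t_))
    stop("prediction and truth grids differ")
  tp <- sum(p & t_); tn <- sum(!p & !t_)
  fp <- sum(p & !t_); fn <- sum(!p & t_)
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 accuracy = rate(tp + tn, tp + tn + fp + fn),
                 tpr = rate(tp, tp + fn),
                 tnr = rate(tn, tn + fp)),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf(
    "<confusion_summary: tp %d, tn %d, fp %d, fn %d | accuracy %.3f, tpr %s, tnr %s>\n",
    x$tp, x$tn, x$fp, x$fn, x$accuracy,
    ifelse(is.na(x$tpr), "NA", sprintf("%.3f", x$tpr)),
    ifelse(is.na(x$tnr), "NA", sprintf("%.3f", x$tnr))))
  invisible(x)
}

#' Exhaustive mesh-mesh distance oracle
#'
#' Exact minimum over all triangle pairs (covering point-point, point-edge,
#' point-face and edge-edge closest-feature cases, and 0 for piercing
#' triangles). Quadratic cost; guarded by a triangle budget. This is the
#' reference that the accelerated [min_distance()] is validated against.
#'
#' @param a,b [tri_mesh()]es.
#' @param max_triangles budget per mesh.
#' @return distance in mm.
#' @export
brute_force_min_distance <- function(a, b, max_triangles = 2000L) {
  if (nrow(a$faces) > max_triangles || nrow(b$faces) > max_triangles)
    stop("triangle budget exceeded (", max_triangles, ")")
  cpp_brute_distance(a$vertices, a$faces, b$vertices, b$faces)
}

#' Production configuration of the collision predictor
#'
#' Tessellation 32 for curved machine primitives, 200 mm facet bound,
#' patient rings of 64 points, every second CT slice.
#' @return a config list for [digital_twin_validation()].
#' @export
coarse_config <- function() {
  list(tessellation = 32L, max_facet_mm = 200, ring_n = 64L,
       slice_stride = 2L, verify_n = 0L)
}

#' Fine in-silico oracle configuration
#'
#' Tessellation 128, 100 mm facet bound, patient rings of 128 points,
#' every CT slice, and brute-force verification of the engine's distances
#' on a sample of cells.
#' @return a config list for [digital_twin_validation()].
#' @export
fine_config <- function() {
  list(tessellation = 128L, max_facet_mm = 100, ring_n = 128L,
       slice_stride = 1L, verify_n = 8L)
}

build_case_patient <- function(stack, config) {
  if (is.null(stack)) return(NULL)
  meshes <- loft_colliders(stack, n = config$ring_n,
                           slice_stride = config$slice_stride)
  placed <- Map(function(m, label) {
    if (label == "body")
      place_patient(m, isocenter_mm = stack$isocenter_mm,
                    plate_height_mm = stack$plate_height_mm)
    else   # accessories rarely contain the isocenter; that is not suspicious
      suppressWarnings(
        place_patient(m, isocenter_mm = stack$isocenter_mm,
                      plate_height_mm = stack$plate_height_mm))
  }, meshes, names(meshes))
  placed
}

#' Digital-twin validation: coarse predictor vs fine in-silico oracle
#'
#' Runs the production (coarse) predictor and a strictly finer oracle run
#' (full tessellation, all CT slices, spot brute-force-verified distances)
#' over the same configuration grid and summarizes their agreement as a
#' confusion matrix, with the fine run as ground truth. Optionally also
#' compares the collision-boundary gantry angle (first colliding angle from
#' 0, both directions, 1-degree steps) per couch angle.
#'
#' The paper-scale physical ground truth (on-site measurement) is not
#' reproducible at desk scale; this harness reinterprets the printed
#' accuracy/TPR/TNR as floors for the in-silico twin.
#'
#' @param spec machine spec.
#' @param case a `contour_stack` (patient/phantom case) or `NULL` for an
#'   empty couch.
#' @param coarse,fine config lists ([coarse_config()], [fine_config()]).
#' @param couch_angles_deg,gantry_angles_deg,positions sweep grids.
#' @param margins optional margin override.
#' @param boundary_positions positions at which boundary angles are
#'   compared (`NULL` to skip), with `boundary_step_deg` resolution.
#' @param boundary_step_deg step for the boundary comparison.
#' @return list with `summary` (a [confusion_summary()]), `pred` and
#'   `truth` maps (clearances saturated just above the margin; flags
#'   exact), `boundary` (data frame of per-couch-angle boundary
#'   rotations, both directions) and `max_boundary_err_deg`, plus
#'   `verified` (brute-force spot-check result of the fine run).
#' @export
digital_twin_validation <- function(spec, case = NULL,
                                    coarse = coarse_config(),
                                    fine = fine_config(),
                                    couch_angles_deg = default_couch_angles(),
                                    gantry_angles_deg = seq(0, 350, by = 10),
                                    positions = list(c(0, 0, 0)),
                                    margins = NULL,
                                    boundary_positions = NULL,
                                    boundary_step_deg = 1) {
  meshes_c <- build_machine_meshes(spec, tessellation = coarse$tessellation,
                                   max_facet_mm = coarse$max_facet_mm %||% 150)
  meshes_f <- build_machine_meshes(spec, tessellation = fine$tessellation,
                                   max_facet_mm = fine$max_facet_mm %||% 150)
  pat_c <- build_case_patient(case, coarse)
  pat_f <- build_case_patient(case, fine)
  # only the colliding flags enter the confusion matrix: cap distance
  # queries just above the largest monitored margin (flags stay exact)
  cap <- max_monitored_margin(spec, margins) + 1
  pred <- sweep_map(spec, pat_c, couch_angles_deg, gantry_angles_deg,
                    positions, margins, component_meshes = meshes_c,
                    clearance_cap_mm = cap)
  truth <- sweep_map(spec, pat_f, couch_angles_deg, gantry_angles_deg,
                     positions, margins, component_meshes = meshes_f,
                     clearance_cap_mm = cap)
  summary <- confusion_summary(pred, truth)
  verified <- NULL
  if ((fine$verify_n %||% 0L) > 0L)
    verified <- verify_against_oracle(spec, pat_f, truth, meshes_f,
                                      n = fine$verify_n)
  boundary <- NULL
  max_err <- NULL
  if (!is.null(boundary_positions)) {
    rows <- list()
    for (pos in boundary_positions) {
      for (ca in couch_angles_deg) {
        for (dir in c("cw", "ccw")) {
          bp <- boundary_gantry_angles(spec, pat_c, ca, pos, dir,
                                       boundary_step_deg, margins,
                                       component_meshes = meshes_c)
          bt <- boundary_gantry_angles(spec, pat_f, ca, pos, dir,
                                       boundary_step_deg, margins,
                                       component_meshes = meshes_f)
          rows[[length(rows) + 1L]] <- data.frame(
            couch_deg = ca, direction = dir,
            pred_rotation_deg = bp$rotation_deg,
            truth_rotation_deg = bt$rotation_deg)
        }
      }
    }
    boundary <- do.call(rbind, rows)
    err <- abs(boundary$pred_rotation_deg - boundary$truth_rotation_deg)
    # a boundary found by one run only counts as a full miss
    err[xor(is.na(boundary$pred_rotation_deg),
            is.na(boundary$truth_rotation_deg))] <- Inf
    err <- err[!is.na(err)]
    max_err <- if (length(err) == 0L) NA_real_ else max(err)
  }
  list(summary = summary, pred = pred, truth = truth,
       boundary = boundary, max_boundary_err_deg = max_err,
       verified = verified)
}

# Spot-check the engine against the exhaustive oracle on a deterministic
# sample of map cells (those whose pair meshes fit the triangle budget).
verify_against_oracle <- function(spec, patient_list, map, component_meshes,
                                  n = 8L, budget = 2000L) {
  nc <- length(map$couch_angles_deg); ng <- length(map$gantry_angles_deg)
  np <- length(map$positions)
  total <- nc * ng * np
  take <- unique(round(seq(1, total, length.out = min(n, total))))
  checked <- 0L
  max_dev <- 0
  for (cell in take) {
    k <- (cell - 1L) %/% (nc * ng) + 1L
    r <- (cell - 1L) %% (nc * ng)
    i <- r %% nc + 1L
    j <- r %/% nc + 1L
    st <- machine_state(map$gantry_angles_deg[j], map$couch_angles_deg[i],
                        map$positions[[k]])
    sc <- assemble_scene(spec, st,
                         patient = if (length(patient_list %||% list())) patient_list else NULL,
                         component_meshes = component_meshes,
                         check_limits = FALSE)
    # accelerated vs exhaustive distance, per monitored element pair that
    # fits the oracle's triangle budget
    pairs <- resolve_pairs(spec, sc)
    meshes <- lapply(sc$elements, function(e) e$mesh)
    for (pp in pairs) {
      for (ia in pp$a) for (ib in pp$b) {
        if (ia == ib) next
        if (nrow(meshes[[ia]]$faces) > budget ||
            nrow(meshes[[ib]]$faces) > budget) next
        d_fast <- cpp_mesh_distance(
          meshes[[ia]]$vertices, meshes[[ia]]$faces,
          meshes[[ib]]$vertices, meshes[[ib]]$faces)
        d_ref <- cpp_brute_distance(
          meshes[[ia]]$vertices, meshes[[ia]]$faces,
          meshes[[ib]]$vertices, meshes[[ib]]$faces)
        checked <- checked + 1L
        max_dev <- max(max_dev, abs(d_fast - d_ref))
      }
    }
  }
  list(pairs_checked = checked, max_deviation_mm = max_dev)
}
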