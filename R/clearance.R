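#' Minimal isocenter shift that clears every planned beam
#'
#' Searches shifts `s = k * step_mm * direction` (k = 0, 1, ...) along each
#' candidate direction and returns the smallest-magnitude shift for which
#' every beam in the plan is collision-free; ties across directions break
#' toward the direction listed first. Shifting the isocenter within the
#' patient is applied as the equal-and-opposite couch/patient translation,
#' which is how the correction is executed at the machine; both views are
#' reported.
#'
#' @param spec machine spec.
#' @param patient placed patient collider(s) (see [place_patient()]), or
#'   `NULL` for couch-only plans.
#' @param beams list of [machine_state()]s, one per planned beam.
#' @param directions list of length-3 unit vectors in room coordinates;
#'   default is couch-down only, the clinically reported correction.
#' @param step_mm search grid step (> 0); shifts are applied in discrete
#'   millimeter steps clinically, so the search is a grid, not a
#'   continuous optimization.
#' @param max_mm largest shift magnitude to try per direction.
#' @param margins optional margin override (see [collides()]).
#' @return object of class `shift_solution`. When a clearing shift exists
#'   `found` is `TRUE` with `shift_mm` (couch/patient translation),
#'   `isocenter_shift_mm` (the equal-and-opposite view),
#'   `clearance_after_mm` (minimum clearance over all beams and monitored
#'   pairs after the shift; the touch-guard pairs monitor at margin 0, so
#'   this can be well below the safety margin while every pair is clear),
#'   `per_beam_clearance_mm` and `evaluated_count`. When nothing clears
#'   within `max_mm`, `found` is `FALSE` and `diagnostics` carries the
#'   best (largest-clearance) candidate tested.
#' @export
find_min_shift <- function(spec, patient, beams,
                           directions = list(c(0, 0, -1)),
                           step_mm = 5, max_mm = 100, margins = NULL) {
  stopifnot(step_mm > 0, max_mm >= step_mm, length(beams) >= 1L)
  component_meshes <- build_machine_meshes(spec)
  patient_list <- if (is.null(patient)) list()
    else if (inherits(patient, "tri_mesh")) list(patient = patient)
    else patient
  eval_shift <- function(s) {
    per_beam <- numeric(length(beams))
    all_clear <- TRUE
    for (bi in seq_along(beams)) {
      b <- beams[[bi]]
      st <- machine_state(b$gantry_angle_deg, b$couch_angle_deg,
                          b$couch_shift_mm + s)
      sc <- assemble_scene(spec, st,
                           patient = if (length(patient_list)) patient_list else NULL,
                           component_meshes = component_meshes,
                           check_limits = FALSE)
      res <- collides(sc, spec, margins)
      per_beam[bi] <- res$min_clearance_mm
      if (res$colliding) all_clear <- FALSE
    }
    list(clear = all_clear, per_beam = per_beam,
         min_clearance = min(per_beam))
  }
  evaluated <- 0L
  ks <- 0:floor(max_mm / step_mm + 1e-9)
  best_mag <- Inf
  best <- NULL
  diag_best <- NULL
  for (di in seq_along(directions)) {
    u <- as.numeric(directions[[di]])
    u <- u / sqrt(sum(u^2))
    for (k in ks) {
      mag <- k * step_mm
      if (mag > best_mag - 1e-9 && k > 0L) break  # cannot beat current best
      s <- mag * u
      r <- eval_shift(s)
      evaluated <- evaluated + 1L
      if (is.null(diag_best) || r$min_clearance > diag_best$min_clearance)
        diag_best <- c(r, list(shift_mm = s))
      if (r$clear) {
        if (mag < best_mag - 1e-9) {
          best_mag <- mag
          best <- list(shift_mm = s, per_beam = r$per_beam,
                       clearance_after_mm = r$min_clearance)
        }
        break
      }
    }
  }
  if (is.null(best)) {
    return(structure(list(found = FALSE, diagnostics = diag_best,
                          evaluated_count = evaluated),
                     class = "shift_solution"))
  }
  structure(list(found = TRUE,
                 shift_mm = best$shift_mm,
                 isocenter_shift_mm = -best$shift_mm,
                 clearance_after_mm = best$clearance_after_mm,
                 per_beam_clearance_mm = best$per_beam,
                 evaluated_count = evaluated),
            class = "shift_solution")
}

#' @export
print.shift_solution <- function(x, ...) {
  if (!x$found) {
    cat(sprintf(
      "<shift_solution: no clearing shift found (%d states tested; best clearance %.1f mm)>\n",
      x$evaluated_count, x$diagnostics$min_clearance))
  } else {
    cat(sprintf(
      "<shift_solution: couch shift (%g, %g, %g) mm, clearance after %.1f mm, %d states tested>\n",
      x$shift_mm[1], x$shift_mm[2], x$shift_mm[3],
      x$clearance_after_mm, x$evaluated_count))
  }
  invisible(x)
}
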