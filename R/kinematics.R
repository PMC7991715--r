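#' Rigid transform (rotation + translation)
#'
#' The room frame is right-handed with its origin at the isocenter:
#' +Z vertical up, +Y horizontal from the isocenter toward the gantry stand,
#' +X completing the frame (IEC-61217-like). The gantry rotates about +Y,
#' the couch about +Z; angles are degrees throughout the API.
#'
#' @param rotation 3x3 orthonormal matrix with det +1.
#' @param translation length-3 numeric, mm.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  translation <- as.numeric(translation)
  stopifnot(identical(dim(rotation), c(3L, 3L)), length(translation) == 3L)
  if (abs(det(rotation) - 1) > 1e-9 ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation must be orthonormal with det +1")
  structure(list(R = rotation, t = translation), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n")
  print(cbind(x$R, x$t))
  invisible(x)
}

#' Compose two rigid transforms (`a` applied after `b`)
#' @param a,b [rigid_transform()]s.
#' @return their composition `a %then% b` as a `rigid_transform`.
#' @export
rt_compose <- function(a, b) {
  rigid_transform(a$R %*% b$R, as.vector(a$R %*% b$t) + a$t)
}

#' Invert a rigid transform
#' @param rt a [rigid_transform()].
#' @return the inverse transform.
#' @export
rt_inverse <- function(rt) {
  rigid_transform(t(rt$R), as.vector(-t(rt$R) %*% rt$t))
}

#' Apply a rigid transform to points
#' @param rt a [rigid_transform()].
#' @param points N x 3 matrix or length-3 vector, mm.
#' @return transformed points, same shape.
#' @export
rt_apply <- function(rt, points) {
  if (is.null(dim(points))) {
    as.vector(rt$R %*% as.numeric(points)) + rt$t
  } else {
    sweep(points %*% t(rt$R), 2, rt$t, "+")
  }
}

rot_axis <- function(axis, angle_deg) {
  th <- angle_deg * pi / 180
  c_ <- cos(th); s <- sin(th)
  switch(axis,
         x = matrix(c(1, 0, 0, 0, c_, -s, 0, s, c_), 3, byrow = TRUE),
         y = matrix(c(c_, 0, s, 0, 1, 0, -s, 0, c_), 3, byrow = TRUE),
         z = matrix(c(c_, -s, 0, s, c_, 0, 0, 0, 1), 3, byrow = TRUE))
}

#' Normalize an angle to [0, 360)
#' @param angle_deg numeric, degrees.
#' @return numeric in `[0, 360)`.
#' @export
normalize_angle <- function(angle_deg) {
  a <- angle_deg %% 360
  a[a < 0] <- a[a < 0] + 360
  a
}

#' Machine state: one gantry/couch configuration
#'
#' @param gantry_angle_deg gantry rotation, degrees (normalized to `[0,360)`);
#'   0 = head directly above the isocenter, increasing toward +X.
#' @param couch_angle_deg couch rotation about the vertical axis, degrees,
#'   counter-clockwise positive seen from above; 0 = couch long axis toward
#'   the gantry stand.
#' @param couch_shift_mm length-3 (lateral x, longitudinal y, vertical z)
#'   couch translation in mm, applied in the couch frame before the rotation.
#' @return object of class `machine_state`.
#' @export
machine_state <- function(gantry_angle_deg = 0, couch_angle_deg = 0,
                          couch_shift_mm = c(0, 0, 0)) {
  couch_shift_mm <- as.numeric(couch_shift_mm)
  stopifnot(length(couch_shift_mm) == 3L, all(is.finite(couch_shift_mm)))
  structure(list(gantry_angle_deg = normalize_angle(gantry_angle_deg),
                 couch_angle_deg = normalize_angle(couch_angle_deg),
                 couch_shift_mm = couch_shift_mm),
            class = "machine_state")
}

#' @export
print.machine_state <- function(x, ...) {
  cat(sprintf("<machine_state: gantry %.1f deg, couch %.1f deg, shift (%g, %g, %g) mm>\n",
              x$gantry_angle_deg, x$couch_angle_deg,
              x$couch_shift_mm[1], x$couch_shift_mm[2], x$couch_shift_mm[3]))
  invisible(x)
}

#' Gantry rotation transform
#'
#' Rotation about the horizontal +Y axis through the isocenter. At 0 degrees
#' the head reference point (0, 0, +d) stays put; at 90 degrees it maps to
#' (+d, 0, 0).
#'
#' @param angle_deg gantry angle in degrees (any real; normalized).
#' @return a [rigid_transform()].
#' @export
gantry_transform <- function(angle_deg) {
  rigid_transform(rot_axis("y", angle_deg))
}

#' Couch transform (translate in couch frame, then rotate about +Z)
#'
#' @param angle_deg couch angle in degrees, counter-clockwise positive from
#'   above.
#' @param shift_mm length-3 couch translation (lateral, longitudinal,
#'   vertical) in mm.
#' @return a [rigid_transform()].
#' @export
couch_transform <- function(angle_deg, shift_mm = c(0, 0, 0)) {
  Rz <- rot_axis("z", angle_deg)
  rigid_transform(Rz, as.vector(Rz %*% as.numeric(shift_mm)))
}

#' Place a patient surface on the treatment couch
#'
#' Expresses a CT-frame collider mesh in the couch frame so that (a) the
#' manually defined isocenter coincides with the room isocenter at zero couch
#' state and (b) every point keeps its CT-measured height above the couch
#' plate (the CT plate surface is mapped onto the treatment couch top).
#'
#' CT volume coordinates are (x lateral, y vertical up, z slice position);
#' the couch frame is room-aligned at zero state. The mapping sends
#' x -> +X, y -> +Z, slice position -> -Y (superior ends away from the
#' gantry stand), a proper rotation so the patient is never mirrored.
#'
#' @param x a [tri_mesh()] in CT coordinates or a contour stack from
#'   [extract_slice_contours()] (lofted with default settings first).
#' @param isocenter_mm length-3 isocenter in CT coordinates (defaults to the
#'   stack's stored isocenter).
#' @param plate_height_mm vertical coordinate of the CT couch-plate top
#'   surface (defaults to the stack's stored plate height).
#' @return `tri_mesh` in the couch frame with attribute `couch_top_mm`, the
#'   vertical coordinate the treatment couch top must take so the plate
#'   surfaces coincide (consumed by [assemble_scene()]).
#' @export
place_patient <- function(x, isocenter_mm = NULL, plate_height_mm = NULL) {
  if (inherits(x, "contour_stack")) {
    if (is.null(isocenter_mm)) isocenter_mm <- x$isocenter_mm
    if (is.null(plate_height_mm)) plate_height_mm <- x$plate_height_mm
    x <- loft_stack(contour_stack_label(x, "body"))
  }
  stopifnot(inherits(x, "tri_mesh"))
  if (is.null(isocenter_mm) || is.null(plate_height_mm))
    stop("isocenter_mm and plate_height_mm must be set")
  isocenter_mm <- as.numeric(isocenter_mm)
  v <- mesh_bounds_contains(x, isocenter_mm)
  if (!v)
    warning("isocenter lies outside the patient bounding box")
  # CT (x, y_up, z_slice) -> couch (x, -z_slice, y_up), centered on isocenter
  R <- matrix(c(1, 0, 0,
                0, 0, -1,
                0, 1, 0), 3, byrow = TRUE)
  rt <- rigid_transform(R, as.vector(-R %*% isocenter_mm))
  out <- transform_mesh(x, rt, frame = "couch")
  attr(out, "couch_top_mm") <- plate_height_mm - isocenter_mm[2]
  out
}

mesh_bounds_contains <- function(mesh, p) {
  lo <- apply(mesh$vertices, 2, min)
  hi <- apply(mesh$vertices, 2, max)
  all(p >= lo - 1e-9) && all(p <= hi + 1e-9)
}
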