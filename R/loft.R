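# Lofting: planar CT contours -> watertight triangle meshes.
#
# The surface between adjacent slices is built by resampling each closed
# contour to a common point count by arc length, rotating the start index so
# corresponding points line up (least-squares over all cyclic offsets after
# centroid alignment), optionally densifying with linearly interpolated
# intermediate rings, and stitching consecutive rings with triangle strips.
# The first and last rings are capped by ear-clipping triangulation.

#' One planar contour on a CT slice
#'
#' @param points k x 2 matrix of (x, y) mm in the slice plane; closed
#'   polygon, first point not repeated, counter-clockwise.
#' @param z_mm slice position in mm.
#' @param label collider name (`body`, `accessory_1`, ..., `plate`).
#' @return object of class `slice_contour`.
#' @export
slice_contour <- function(points, z_mm, label = "body") {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2L, nrow(points) >= 3L)
  if (isTRUE(all.equal(points[1, ], points[nrow(points), ], tolerance = 1e-12)))
    points <- points[-nrow(points), , drop = FALSE]
  if (polygon_signed_area(points) < 0)
    points <- points[rev(seq_len(nrow(points))), , drop = FALSE]
  structure(list(points = points, z_mm = z_mm, label = label),
            class = "slice_contour")
}

contour_perimeter <- function(points) {
  d <- points[c(2:nrow(points), 1L), , drop = FALSE] - points
  sum(sqrt(rowSums(d^2)))
}

#' Resample a closed contour to n equally spaced points
#'
#' Points are spaced uniformly by arc length along the polygon, starting at
#' the contour's first point; orientation is preserved.
#'
#' @param contour a [slice_contour()] (or bare k x 2 matrix).
#' @param n number of output points (>= 3).
#' @return same type as the input, with n points.
#' @export
resample_contour <- function(contour, n) {
  stopifnot(n >= 3L)
  p <- if (inherits(contour, "slice_contour")) contour$points else as.matrix(contour)
  k <- nrow(p)
  seg <- p[c(2:k, 1L), , drop = FALSE] - p
  len <- sqrt(rowSums(seg^2))
  total <- sum(len)
  if (total <= 0) stop("degenerate (zero-perimeter) contour")
  ends <- cumsum(len)
  starts <- c(0, ends[-k])
  s <- (seq_len(n) - 1L) / n * total
  idx <- findInterval(s, starts, rightmost.closed = FALSE)
  frac <- (s - starts[idx]) / len[idx]
  frac[!is.finite(frac)] <- 0
  out <- p[idx, , drop = FALSE] + seg[idx, , drop = FALSE] * frac
  if (inherits(contour, "slice_contour")) {
    contour$points <- out
    contour
  } else out
}

#' Best cyclic start-index offset between two equally sampled contours
#'
#' Returns the offset `k` (0-based) minimizing the sum of squared distances
#' between `a[i]` and `b[i + k mod n]` after centroid alignment; ties break
#' toward the smallest `k`. Used to line up corresponding points on adjacent
#' slices before interpolation and lofting.
#'
#' @param a,b [slice_contour()]s (or k x 2 matrices) with equal point counts.
#' @return integer offset in `0:(n-1)`.
#' @export
correspondence_offset <- function(a, b) {
  pa <- if (inherits(a, "slice_contour")) a$points else as.matrix(a)
  pb <- if (inherits(b, "slice_contour")) b$points else as.matrix(b)
  n <- nrow(pa)
  if (nrow(pb) != n) stop("contours must have equal point counts")
  pa <- sweep(pa, 2, colMeans(pa))
  pb <- sweep(pb, 2, colMeans(pb))
  # ssd(k) = const - 2 * cross-correlation(k); evaluate directly (n is small)
  ssd <- vapply(0:(n - 1L), function(k) {
    ix <- ((seq_len(n) - 1L + k) %% n) + 1L
    sum((pa - pb[ix, , drop = FALSE])^2)
  }, 0)
  which.min(ssd) - 1L
}

shift_start <- function(points, k) {
  n <- nrow(points)
  ix <- ((seq_len(n) - 1L + k) %% n) + 1L
  points[ix, , drop = FALSE]
}

#' Linear interpolation between two corresponding contours
#'
#' Pointwise linear blend at target height z between contours at z1 <= z <= z2.
#' Contours must already be resampled to the same count and
#' correspondence-aligned.
#'
#' @param ca,cb [slice_contour()]s at heights `z1 < z2`.
#' @param z target height, mm, inside `[z1, z2]`.
#' @return interpolated `slice_contour` at z.
#' @export
interpolate_contours <- function(ca, cb, z) {
  z1 <- ca$z_mm; z2 <- cb$z_mm
  if (z < min(z1, z2) - 1e-9 || z > max(z1, z2) + 1e-9)
    stop("z outside [z1, z2]")
  if (nrow(ca$points) != nrow(cb$points))
    stop("contours must have equal point counts")
  w <- if (z2 == z1) 0 else (z - z1) / (z2 - z1)
  slice_contour((1 - w) * ca$points + w * cb$points, z_mm = z, label = ca$label)
}

#' Loft a stack of slice contours into a watertight solid
#'
#' @param contours list of [slice_contour()]s for one collider, one per
#'   slice (any order; sorted by z internally).
#' @param n ring sampling (points per contour after resampling).
#' @param interp_substeps number of interpolated rings inserted between
#'   adjacent slices, or `"auto"` to keep the effective axial step at or
#'   below `max_step_mm`.
#' @param max_step_mm axial step target for `interp_substeps = "auto"`.
#' @param frame frame name of the result.
#' @return watertight outward-oriented [tri_mesh()] with vertices
#'   (x, y, z_mm).
#' @export
loft_stack <- function(contours, n = 128L, interp_substeps = "auto",
                       max_step_mm = 5, frame = "component") {
  if (length(contours) < 2L) stop("need >= 2 slices to loft a collider")
  z <- vapply(contours, function(cc) cc$z_mm, 0)
  contours <- contours[order(z)]
  z <- sort(z)
  rings <- lapply(contours, function(cc) resample_contour(cc, n)$points)
  # align ring j to ring j-1
  for (j in 2:length(rings)) {
    k <- correspondence_offset(rings[[j - 1L]], rings[[j]])
    rings[[j]] <- shift_start(rings[[j]], k)
  }
  # densify with interpolated rings
  all_rings <- list(rings[[1L]])
  all_z <- z[1L]
  for (j in 2:length(rings)) {
    gap <- z[j] - z[j - 1L]
    sub <- if (identical(interp_substeps, "auto"))
      max(0L, ceiling(gap / max_step_mm) - 1L) else as.integer(interp_substeps)
    if (sub > 0L) {
      for (s in seq_len(sub)) {
        w <- s / (sub + 1)
        all_rings[[length(all_rings) + 1L]] <-
          (1 - w) * rings[[j - 1L]] + w * rings[[j]]
        all_z <- c(all_z, (1 - w) * z[j - 1L] + w * z[j])
      }
    }
    all_rings[[length(all_rings) + 1L]] <- rings[[j]]
    all_z <- c(all_z, z[j])
  }
  m <- length(all_rings)
  verts <- do.call(rbind, Map(function(r, zz) cbind(r, zz), all_rings, all_z))
  i <- seq_len(n)
  j2 <- c(2:n, 1L)
  side <- list()
  for (r in seq_len(m - 1L)) {
    lo <- (r - 1L) * n
    hi <- r * n
    side[[2L * r - 1L]] <- cbind(lo + i, lo + j2, hi + j2)
    side[[2L * r]] <- cbind(lo + i, hi + j2, hi + i)
  }
  cap_lo <- triangulate_polygon(all_rings[[1L]])
  cap_hi <- triangulate_polygon(all_rings[[m]])
  faces <- rbind(do.call(rbind, side),
                 cap_lo[, c(1L, 3L, 2L), drop = FALSE],
                 cap_hi + (m - 1L) * n)
  mesh <- tri_mesh(verts, faces, frame = frame)
  if (!mesh_is_watertight(mesh))
    stop("loft produced a non-watertight mesh")
  if (mesh_volume(mesh) < 0) mesh <- flip_mesh(mesh)
  mesh
}

# Loft every collider of a contour stack; returns a named list of meshes in
# CT coordinates (x, y_up, z).
loft_colliders <- function(stack, n = 128L, slice_stride = 1L,
                           interp_substeps = "auto", max_step_mm = 5) {
  out <- list()
  for (label in unique(vapply(stack$contours, function(cc) cc$label, ""))) {
    cs <- contour_stack_label(stack, label)
    if (slice_stride > 1L && length(cs) > 3L) {
      keep <- unique(c(seq(1L, length(cs), by = slice_stride), length(cs)))
      cs <- cs[keep]
    }
    if (length(cs) < 2L) next
    out[[label]] <- loft_stack(cs, n = n, interp_substeps = interp_substeps,
                               max_step_mm = max_step_mm)
  }
  if (length(out) == 0L) stop("no collider has >= 2 slices")
  out
}
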