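#' Calibrated CT volume
#'
#' Voxels hold Hounsfield units in an `[nx, ny, nz]` array. Volume
#' coordinates are (x lateral, y vertical up, z slice position), all mm:
#' voxel `(i, j, k)` is centered at
#' `(origin[1] + (i-1) * pixel_spacing[1], origin[2] + (j-1) * pixel_spacing[2],
#' slice_positions[k])`. The couch-plate top height and the isocenter (both
#' defined manually, mirroring clinical practice) live in the same frame.
#'
#' @param voxels 3D numeric array of HU, dimensions `[nx, ny, nz]`.
#' @param pixel_spacing length-2 in-plane spacing (x, y), mm.
#' @param slice_positions strictly increasing slice z positions, mm, with
#'   uniform spacing (tolerance `1e-3` mm).
#' @param origin length-2 (x, y) coordinate of voxel (1, 1), mm.
#' @param plate_height_mm vertical (y) coordinate of the CT couch-plate top
#'   surface, or `NULL` if not yet set.
#' @param isocenter_mm length-3 isocenter (x, y, z) in volume coordinates,
#'   or `NULL` if not yet set.
#' @return object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, pixel_spacing, slice_positions, origin = c(0, 0),
                      plate_height_mm = NULL, isocenter_mm = NULL) {
  stopifnot(length(dim(voxels)) == 3L, length(pixel_spacing) == 2L,
            all(pixel_spacing > 0), length(origin) == 2L)
  nz <- dim(voxels)[3]
  if (length(slice_positions) != nz)
    stop("slice_positions length must match the slice count")
  if (nz > 1L) {
    gaps <- diff(slice_positions)
    if (any(gaps <= 0)) stop("slice_positions must be strictly increasing")
    if (diff(range(gaps)) > 1e-3)
      stop("non-uniform slice spacing (max deviation ",
           format(diff(range(gaps))), " mm)")
  }
  vol <- structure(list(voxels = voxels,
                        pixel_spacing = as.numeric(pixel_spacing),
                        slice_positions = as.numeric(slice_positions),
                        origin = as.numeric(origin),
                        plate_height_mm = plate_height_mm,
                        isocenter_mm = isocenter_mm),
                   class = "ct_volume")
  if (!is.null(isocenter_mm)) check_isocenter(vol, isocenter_mm)
  vol
}

check_isocenter <- function(vol, iso) {
  stopifnot(length(iso) == 3L)
  d <- dim(vol$voxels)
  xr <- vol$origin[1] + c(0, (d[1] - 1) * vol$pixel_spacing[1])
  yr <- vol$origin[2] + c(0, (d[2] - 1) * vol$pixel_spacing[2])
  zr <- range(vol$slice_positions)
  if (iso[1] < xr[1] || iso[1] > xr[2] || iso[2] < yr[1] || iso[2] > yr[2] ||
      iso[3] < zr[1] || iso[3] > zr[2])
    stop("isocenter outside volume bounds")
  invisible(TRUE)
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume: %d x %d x %d voxels, %g x %g mm pixels, %d slices>\n",
              d[1], d[2], d[3], x$pixel_spacing[1], x$pixel_spacing[2], d[3]))
  invisible(x)
}

ct_x_coords <- function(vol) vol$origin[1] +
  (seq_len(dim(vol$voxels)[1]) - 1) * vol$pixel_spacing[1]
ct_y_coords <- function(vol) vol$origin[2] +
  (seq_len(dim(vol$voxels)[2]) - 1) * vol$pixel_spacing[2]

#' Set the isocenter and plate height on a volume
#'
#' Both are user inputs (the isocenter is defined manually on the simulation
#' CT; the plate height is read off the couch surface).
#'
#' @param vol a [ct_volume()].
#' @param isocenter_mm length-3 (x, y, z) mm, or `NULL` to keep.
#' @param plate_height_mm vertical coordinate of the plate top, mm, or
#'   `NULL` to keep.
#' @return the updated volume.
#' @export
set_reference_geometry <- function(vol, isocenter_mm = NULL,
                                   plate_height_mm = NULL) {
  if (!is.null(isocenter_mm)) {
    check_isocenter(vol, isocenter_mm)
    vol$isocenter_mm <- as.numeric(isocenter_mm)
  }
  if (!is.null(plate_height_mm)) vol$plate_height_mm <- plate_height_mm
  vol
}

#' Linear intensity window: HU to 8-bit grayscale
#'
#' Maps `[window_low, window_high]` HU linearly onto `[0, 255]`, clamping
#' outside the window; values are rounded half-up to integers. The window is
#' a user choice; the package default `(-500, 300)` puts the soft-tissue
#' body surface well inside the ramp.
#'
#' @param vol a [ct_volume()].
#' @param window_low,window_high window bounds in HU, `low < high`.
#' @return integer array (same dimensions) of gray values 0-255.
#' @export
intensity_transform <- function(vol, window_low = -500, window_high = 300) {
  if (window_low >= window_high) stop("window_low must be < window_high")
  g <- (vol$voxels - window_low) / (window_high - window_low) * 255
  g[g < 0] <- 0
  g[g > 255] <- 255
  array(as.integer(floor(g + 0.5)), dim = dim(vol$voxels))
}

#' Gray value of an HU threshold under a window
#'
#' Converts an HU cut to the 0-255 gray cut that [segment_mask()] consumes,
#' so thresholds can be stated in calibrated units.
#'
#' @param hu threshold in HU.
#' @inheritParams intensity_transform
#' @return gray level (numeric, 0-255 scale).
#' @export
hu_to_gray <- function(hu, window_low = -500, window_high = 300) {
  pmin(pmax((hu - window_low) / (window_high - window_low) * 255, 0), 255)
}

#' Threshold and morphological closing: binary collider mask
#'
#' Per slice: gray >= threshold, then binary closing (dilation followed by
#' erosion) with a disc structuring element of the given radius. The closing
#' is the pipeline's smoothing step; it fills notches and pinholes narrower
#' than about twice the radius and is idempotent.
#'
#' @param gray integer array from [intensity_transform()] (or any numeric
#'   stack).
#' @param threshold gray cut in 0-255 (see [hu_to_gray()]); default 64
#'   places the cut at -300 HU under the default window.
#' @param closing_radius_px disc radius in pixels (0 disables closing).
#' @return logical array of the same dimensions.
#' @export
segment_mask <- function(gray, threshold = 64, closing_radius_px = 2) {
  stopifnot(closing_radius_px >= 0)
  mask <- gray >= threshold
  if (closing_radius_px > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(closing_radius_px) + 1L,
                                shape = "disc")
    for (k in seq_len(dim(mask)[3])) {
      sl <- EBImage::Image(mask[, , k] * 1)
      mask[, , k] <- EBImage::closing(sl, brush)@.Data > 0.5
    }
  }
  mask
}

#' Extract per-slice collider contours from a mask stack
#'
#' Connected components are labelled per slice; components lying entirely
#' below the plate height (the couch plate itself and anything under it) and
#' components with polygon area below `min_area_mm2` are discarded. Each
#' surviving component contributes one closed outer contour, traced at the
#' 0.5 iso-level of the binary mask (vertices at pixel resolution, midway
#' between inside and outside pixel centers; the morphological closing is
#' the only smoothing). Components are tracked across slices by maximal
#' pixel overlap into labelled colliders; the collider with the largest
#' total volume is `body`, the others `accessory_1`, `accessory_2`, ... in
#' decreasing volume order.
#'
#' @param mask logical array from [segment_mask()].
#' @param vol the source [ct_volume()] (must carry isocenter and plate
#'   height).
#' @param min_area_mm2 minimum polygon area per retained component.
#' @return object of class `contour_stack`: list with `contours` (list of
#'   [slice_contour()]), `isocenter_mm`, `plate_height_mm`.
#' @export
extract_slice_contours <- function(mask, vol, min_area_mm2 = 100) {
  if (is.null(vol$isocenter_mm) || is.null(vol$plate_height_mm))
    stop("isocenter and plate height must be set on the volume (see set_reference_geometry)")
  xs <- ct_x_coords(vol)
  ys <- ct_y_coords(vol)
  nz <- dim(mask)[3]
  contours <- list()
  comp_of_prev <- NULL      # label matrix of previous slice
  track_of_prev <- integer() # component id -> track id, previous slice
  tracks_volume <- numeric() # per track, accumulated area * slice gap
  track_contours <- list()
  gap <- if (nz > 1L) diff(vol$slice_positions[1:2]) else 1
  next_track <- 0L
  for (k in seq_len(nz)) {
    sl <- mask[, , k]
    if (!any(sl)) { comp_of_prev <- NULL; track_of_prev <- integer(); next }
    lab <- EBImage::bwlabel(EBImage::Image(sl * 1))@.Data
    ncomp <- max(lab)
    track_of <- integer(ncomp)
    used_this_slice <- integer(0)
    for (cid in seq_len(ncomp)) {
      sel <- lab == cid
      jidx <- which(sel, arr.ind = TRUE)[, 2]
      if (max(ys[jidx]) < vol$plate_height_mm) next  # entirely below the plate
      poly <- trace_component(sel, xs, ys)
      if (is.null(poly)) next
      area <- polygon_signed_area(poly)
      if (area < min_area_mm2) next
      # match to a previous-slice component by maximal overlap, ties by
      # centroid distance
      tid <- 0L
      if (!is.null(comp_of_prev)) {
        prev_ids <- comp_of_prev[sel]
        prev_ids <- prev_ids[prev_ids > 0L]
        if (length(prev_ids) > 0L) {
          tab <- sort(table(prev_ids), decreasing = TRUE)
          best <- as.integer(names(tab)[tab == tab[1L]])
          if (length(best) > 1L) {
            cen <- colMeans(which(sel, arr.ind = TRUE))
            dd <- vapply(best, function(b) {
              sum((colMeans(which(comp_of_prev == b, arr.ind = TRUE)) - cen)^2)
            }, 0)
            best <- best[which.min(dd)]
          } else best <- best[1L]
          if (best <= length(track_of_prev) && track_of_prev[best] > 0L)
            tid <- track_of_prev[best]
        }
      }
      if (tid %in% used_this_slice) tid <- 0L  # branching: cap, new collider
      if (tid == 0L) {
        next_track <- next_track + 1L
        tid <- next_track
        tracks_volume[tid] <- 0
        track_contours[[tid]] <- list()
      }
      track_of[cid] <- tid
      used_this_slice <- c(used_this_slice, tid)
      tracks_volume[tid] <- tracks_volume[tid] + area * gap
      track_contours[[tid]][[length(track_contours[[tid]]) + 1L]] <-
        slice_contour(poly, z_mm = vol$slice_positions[k])
    }
    comp_of_prev <- lab
    track_of_prev <- track_of
  }
  if (next_track == 0L)
    stop("no component survives on any slice (empty contour stack)")
  ord <- order(tracks_volume, decreasing = TRUE)
  labels <- c("body", paste0("accessory_", seq_len(max(0L, next_track - 1L))))
  contours <- list()
  for (r in seq_along(ord)) {
    for (cc in track_contours[[ord[r]]]) {
      cc$label <- labels[r]
      contours[[length(contours) + 1L]] <- cc
    }
  }
  structure(list(contours = contours,
                 isocenter_mm = vol$isocenter_mm,
                 plate_height_mm = vol$plate_height_mm),
            class = "contour_stack")
}

# Outer 0.5-level contour of one component mask (nx x ny logical matrix).
trace_component <- function(sel, xs, ys) {
  # pad with a zero frame so border-touching components still close
  dx <- xs[2] - xs[1]; dy <- ys[2] - ys[1]
  padded <- matrix(0, nrow(sel) + 2L, ncol(sel) + 2L)
  padded[2:(nrow(sel) + 1L), 2:(ncol(sel) + 1L)] <- sel * 1
  cl <- grDevices::contourLines(x = c(xs[1] - dx, xs, xs[length(xs)] + dx),
                                y = c(ys[1] - dy, ys, ys[length(ys)] + dy),
                                z = padded, levels = 0.5)
  if (length(cl) == 0L) return(NULL)
  # outer contour = largest absolute area
  areas <- vapply(cl, function(cc)
    abs(polygon_signed_area(cbind(cc$x, cc$y))), 0)
  cc <- cl[[which.max(areas)]]
  p <- cbind(cc$x, cc$y)
  if (nrow(p) >= 2L && isTRUE(all.equal(p[1, ], p[nrow(p), ], tolerance = 1e-9)))
    p <- p[-nrow(p), , drop = FALSE]
  if (nrow(p) < 3L) return(NULL)
  if (polygon_signed_area(p) < 0) p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
  p
}

#' @export
print.contour_stack <- function(x, ...) {
  labs <- vapply(x$contours, function(cc) cc$label, "")
  cat(sprintf("<contour_stack: %d contours (%s), plate %g mm>\n",
              length(x$contours),
              paste(sprintf("%s x%d", names(table(labs)), table(labs)),
                    collapse = ", "),
              x$plate_height_mm))
  invisible(x)
}

#' Contours of one collider, ordered by slice position
#' @param stack a `contour_stack`.
#' @param label collider label.
#' @return list of [slice_contour()]s.
#' @export
contour_stack_label <- function(stack, label) {
  cs <- Filter(function(cc) cc$label == label, stack$contours)
  if (length(cs) == 0L) stop("no contours with label '", label, "'")
  cs[order(vapply(cs, function(cc) cc$z_mm, 0))]
}

#' Write a contour stack as per-slice CSV (debug aid)
#' @param stack a `contour_stack`.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_contours_csv <- function(stack, path) {
  rows <- do.call(rbind, lapply(stack$contours, function(cc) {
    data.frame(label = cc$label, z_mm = cc$z_mm,
               x_mm = cc$points[, 1], y_mm = cc$points[, 2])
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
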