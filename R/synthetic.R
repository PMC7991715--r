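#' Parameters of the synthetic torso phantom
#'
#' The generator emulates a thorax-scale radiotherapy phantom immobilized
#' with a vacuum bag on a flat CT couch plate: an elliptical-cylinder body
#' of soft-tissue HU with Gaussian noise, an optional bag shell hugging the
#' lower half of the body, the plate slab, air elsewhere. The geometry is
#' analytic on purpose: every downstream stage (contouring, lofting,
#' collision sweeps) can be checked against closed-form truth.
#'
#' Default HU: body 30 +/- 15, bag -650, plate 200, air -1000, chosen so
#' one window/threshold pair separates the body cut (-300 HU) and a lower
#' cut (-700 HU) additionally captures the bag. A small air gap (12 mm) is
#' kept between bag and plate so the body+bag collider and the plate stay
#' distinct connected components.
#'
#' @param body_semi_axes_mm ellipse semi-axes (a lateral, b vertical), mm.
#' @param n_slices,slice_thickness_mm axial extent.
#' @param nx,ny,pixel_spacing_mm in-plane grid.
#' @param body_hu_mean,body_hu_sd body HU distribution.
#' @param bag logical: include the vacuum-bag shell.
#' @param bag_thickness_mm,bag_hu bag shell parameters.
#' @param plate_thickness_mm,plate_hu couch-plate slab parameters.
#' @param plate_gap_mm air gap between bag (or body) bottom and plate top (wide enough that the default closing cannot bridge it).
#' @param prone_board optional board height, mm (0 = none): a slab between
#'   plate and body that raises the torso (prone breast setups).
#' @param noise_seed RNG seed for the HU noise; a fixed seed gives
#'   bit-identical volumes.
#' @return a `phantom_params` list.
#' @export
phantom_params <- function(body_semi_axes_mm = c(170, 110),
                           n_slices = 50L, slice_thickness_mm = 4,
                           nx = 192L, ny = 176L, pixel_spacing_mm = 2,
                           body_hu_mean = 30, body_hu_sd = 15,
                           bag = TRUE, bag_thickness_mm = 16, bag_hu = -650,
                           plate_thickness_mm = 50, plate_hu = 200,
                           plate_gap_mm = 12,
                           prone_board = 0, noise_seed = 1L) {
  p <- list(body_semi_axes_mm = body_semi_axes_mm, n_slices = n_slices,
            slice_thickness_mm = slice_thickness_mm, nx = nx, ny = ny,
            pixel_spacing_mm = pixel_spacing_mm,
            body_hu_mean = body_hu_mean, body_hu_sd = body_hu_sd,
            bag = bag, bag_thickness_mm = bag_thickness_mm, bag_hu = bag_hu,
            plate_thickness_mm = plate_thickness_mm, plate_hu = plate_hu,
            plate_gap_mm = plate_gap_mm,
            prone_board = prone_board, noise_seed = noise_seed)
  stopifnot(all(p$body_semi_axes_mm > 0), p$slice_thickness_mm > 0,
            p$pixel_spacing_mm > 0, p$plate_thickness_mm > 0)
  structure(p, class = "phantom_params")
}

#' Generate the synthetic phantom CT volume
#'
#' Deterministic for a fixed `noise_seed`. Vertical layout (y up, mm):
#' plate top at `plate_height`, optional prone board on the plate, the bag
#' shell above an air gap, the body on top; the isocenter defaults to the
#' body center (the "manual" isocenter choice) and the plate height is
#' recorded on the volume.
#'
#' @param p a [phantom_params()].
#' @param dicom_dir optional directory: also write the volume as a DICOM
#'   CT series ([write_ct_series()]).
#' @return a [ct_volume()] with isocenter and plate height set, and
#'   attribute `truth` carrying the generating geometry.
#' @export
make_phantom_ct <- function(p = phantom_params(), dicom_dir = NULL) {
  a <- p$body_semi_axes_mm[1]; b <- p$body_semi_axes_mm[2]
  dx <- p$pixel_spacing_mm
  xs <- (seq_len(p$nx) - (p$nx + 1) / 2) * dx
  fov_y <- p$ny * dx
  # stack from the bottom: margin, plate, (board), gap, bag, body, headroom
  plate_height <- -fov_y / 2 + 40 + p$plate_thickness_mm
  support_top <- plate_height + p$prone_board
  bag_bottom <- support_top + p$plate_gap_mm
  body_center_y <- bag_bottom +
    (if (p$bag) p$bag_thickness_mm else 0) + b
  ys <- seq(-fov_y / 2 + dx / 2, by = dx, length.out = p$ny)
  if (body_center_y + b > max(ys) - 2 * dx)
    stop("body exceeds the field of view")
  if (a * 2 > (max(xs) - min(xs)) - 4 * dx)
    stop("body exceeds the field of view")
  zs <- seq(0, by = p$slice_thickness_mm, length.out = p$n_slices)
  X <- matrix(xs, p$nx, p$ny)
  Y <- matrix(ys, p$nx, p$ny, byrow = TRUE)
  r2 <- (X / a)^2 + ((Y - body_center_y) / b)^2
  body <- r2 <= 1
  slice <- matrix(-1000, p$nx, p$ny)
  if (p$bag) {
    ab <- a + p$bag_thickness_mm
    bb <- b + p$bag_thickness_mm
    shell <- ((X / ab)^2 + ((Y - body_center_y) / bb)^2 <= 1) & !body &
      (Y <= body_center_y)
    slice[shell] <- p$bag_hu
  }
  slice[body] <- p$body_hu_mean
  plate <- (Y <= plate_height) & (Y > plate_height - p$plate_thickness_mm)
  slice[plate] <- p$plate_hu
  if (p$prone_board > 0) {
    board <- (Y > plate_height) & (Y <= support_top) & (abs(X) <= a)
    slice[board] <- 150
  }
  vox <- array(rep(slice, p$n_slices), dim = c(p$nx, p$ny, p$n_slices))
  set.seed(p$noise_seed)
  noise <- array(stats::rnorm(length(vox), 0, p$body_hu_sd), dim = dim(vox))
  vox <- vox + noise * (vox > -1000)   # noise on solids, clean air
  iso <- c(0, body_center_y, stats::median(zs))
  vol <- ct_volume(vox, pixel_spacing = c(dx, dx), slice_positions = zs,
                   origin = c(xs[1], ys[1]),
                   plate_height_mm = plate_height, isocenter_mm = iso)
  attr(vol, "truth") <- list(body_semi_axes_mm = c(a, b),
                             body_center_y = body_center_y,
                             plate_height_mm = plate_height,
                             support_top_mm = support_top,
                             # axial extent of the lofted surface: the span
                             # between first and last slice centers
                             length_mm = p$slice_thickness_mm * (p$n_slices - 1L))
  if (!is.null(dicom_dir))
    write_ct_series(vol, dicom_dir,
                    series_tag = as.character(p$noise_seed))
  vol
}

#' Prone-breast collision case
#'
#' Phantom variant with a prone board on the couch plate that raises the
#' torso, reproducing the reduced posterior-oblique gantry clearance of a
#' high prone setup.
#'
#' @param seed RNG seed for the HU noise.
#' @param board_height_mm board step height.
#' @return a [ct_volume()] (see [make_phantom_ct()]).
#' @export
make_prone_breast_case <- function(seed = 1L, board_height_mm = 120) {
  make_phantom_ct(phantom_params(prone_board = board_height_mm,
                                 ny = 240L, noise_seed = seed))
}

#' Contour a phantom volume with the pipeline defaults
#'
#' Window (-800, 300) with the cut at -700 HU so the vacuum-bag shell is
#' part of the external collider surface, closing radius 2 px.
#'
#' @param vol a phantom [ct_volume()].
#' @param threshold_hu segmentation cut, HU.
#' @param window window bounds, HU.
#' @param closing_radius_px disc radius for the morphological closing.
#' @param min_area_mm2 dust filter.
#' @return a `contour_stack`.
#' @export
contour_phantom <- function(vol, threshold_hu = -700,
                            window = c(-800, 300), closing_radius_px = 2,
                            min_area_mm2 = 400) {
  gray <- intensity_transform(vol, window[1], window[2])
  thr <- hu_to_gray(threshold_hu, window[1], window[2])
  mask <- segment_mask(gray, threshold = thr,
                       closing_radius_px = closing_radius_px)
  extract_slice_contours(mask, vol, min_area_mm2 = min_area_mm2)
}

#' Load one of the generic fixture machines
#'
#' Two generic accelerators ship with the package: `machine_a` and
#' `machine_b`. They are NOT vendor models (vendor dimensions are
#' proprietary); `machine_b` has a larger head diameter and a smaller
#' face-to-isocenter clearance than `machine_a`, mirroring how two real
#' vendors differ.
#'
#' @param name `"machine_a"` or `"machine_b"`.
#' @return a [load_machine_spec()] result.
#' @export
fixture_machine <- function(name = c("machine_a", "machine_b")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".yaml"), package = "rtclear")
  if (path == "") stop("fixture machine file not found: ", name)
  load_machine_spec(path)
}
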