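test_that("intensity windowing maps endpoints, midpoint and clamps", {
  vox <- array(c(-500, 300, -100, -600, 500, 0), dim = c(1, 2, 3))
  vol <- ct_volume(vox, c(1, 1), c(0, 10, 20))
  g <- intensity_transform(vol, -500, 300)
  expect_identical(g[1, 1, 1], 0L)      # low endpoint
  expect_identical(g[1, 2, 1], 255L)    # high endpoint
  expect_identical(g[1, 1, 2], 128L)    # midpoint, rounded half-up
  expect_identical(g[1, 2, 2], 0L)      # below window clamps
  expect_identical(g[1, 1, 3], 255L)    # above window clamps
  expect_error(intensity_transform(vol, 100, 100), "window_low")
})

test_that("morphological closing fills notches and is idempotent", {
  # disk with a 2-px-wide notch
  n <- 64
  xs <- seq_len(n) - 32.5
  m <- outer(xs, xs, function(x, y) x^2 + y^2 <= 20^2)
  notch <- m
  notch[abs(xs) <= 1, xs > 0] <- FALSE
  g <- array(notch * 255, dim = c(n, n, 1))
  closed <- segment_mask(g, threshold = 128, closing_radius_px = 3)
  # the notch interior is filled again
  expect_true(all(closed[abs(xs) <= 1, xs > 5 & xs < 15, 1]))
  # idempotence: closing the closed mask changes nothing
  twice <- segment_mask(array(closed * 255, dim = dim(g)),
                        threshold = 128, closing_radius_px = 3)
  expect_identical(twice, closed)
  # all-air slice -> empty mask
  empty <- segment_mask(array(0L, dim = c(16, 16, 2)), threshold = 64,
                        closing_radius_px = 2)
  expect_false(any(empty))
})

test_that("extracted contour area matches the rasterization oracle", {
  n <- 128
  xs <- seq_len(n) - 64.5
  disk <- outer(xs, xs, function(x, y) x^2 + y^2 <= 50^2)
  mask <- array(disk, dim = c(n, n, 3))
  vol <- ct_volume(array(0, dim = c(n, n, 3)), c(1, 1), c(0, 5, 10),
                   origin = c(0, 0))
  vol <- set_reference_geometry(vol, isocenter_mm = c(64, 64, 5),
                                plate_height_mm = 0.5)
  stack <- extract_slice_contours(mask, vol, min_area_mm2 = 10)
  body <- contour_stack_label(stack, "body")
  area <- rtclear:::polygon_signed_area(body[[2]]$points)
  # oracle 1: pixel count of the same mask
  expect_lt(abs(area - sum(disk)) / sum(disk), 0.005)
  # oracle 2: analytic disk area
  expect_lt(abs(area - pi * 50^2) / (pi * 50^2), 0.02)
})

test_that("components are filtered by plate height and area, and labelled by volume", {
  n <- 96
  xs <- seq_len(n)
  ys <- seq_len(n)
  sl <- matrix(FALSE, n, n)
  disk <- function(cx, cy, r) outer(xs, ys, function(x, y)
    (x - cx)^2 + (y - cy)^2 <= r^2)
  sl <- disk(40, 60, 20) | disk(80, 55, 8) | disk(48, 10, 12)
  mask <- array(sl, dim = c(n, n, 4))
  vol <- ct_volume(array(0, dim = c(n, n, 4)), c(1, 1), c(0, 4, 8, 12))
  vol <- set_reference_geometry(vol, isocenter_mm = c(40, 60, 6),
                                plate_height_mm = 30)  # third disk is below
  stack <- extract_slice_contours(mask, vol, min_area_mm2 = 50)
  labs <- unique(vapply(stack$contours, function(cc) cc$label, ""))
  expect_setequal(labs, c("body", "accessory_1"))
  # body = the larger disk
  body <- contour_stack_label(stack, "body")
  expect_gt(abs(rtclear:::polygon_signed_area(body[[1]]$points)), 1000)
  acc <- contour_stack_label(stack, "accessory_1")
  expect_lt(abs(rtclear:::polygon_signed_area(acc[[1]]$points)), 300)
  # everything below the plate is gone: no contour near y = 10
  all_y <- unlist(lapply(stack$contours, function(cc) cc$points[, 2]))
  expect_gt(min(all_y), 30)
  # all polygons CCW and simple
  for (cc in stack$contours) {
    expect_gt(rtclear:::polygon_signed_area(cc$points), 0)
    expect_true(rtclear:::polygon_is_simple(cc$points))
  }
  # nothing above threshold anywhere -> empty-stack error
  expect_error(extract_slice_contours(array(FALSE, dim = dim(mask)), vol),
               "no component")
})

test_that("contour areas are invariant to the window when the HU cut is fixed", {
  vol <- small_phantom()
  s1 <- contour_phantom(vol, threshold_hu = -300, window = c(-500, 300))
  s2 <- contour_phantom(vol, threshold_hu = -300, window = c(-1000, 1000))
  b1 <- contour_stack_label(s1, "body")
  b2 <- contour_stack_label(s2, "body")
  a1 <- vapply(b1, function(cc) rtclear:::polygon_signed_area(cc$points), 0)
  a2 <- vapply(b2, function(cc) rtclear:::polygon_signed_area(cc$points), 0)
  # same HU cut through different windows: identical masks up to the 8-bit
  # quantization of the two ramps
  expect_lt(max(abs(a1 - a2)) / max(a1), 0.01)
})

test_that("volume construction validates slice geometry", {
  expect_error(ct_volume(array(0, c(4, 4, 3)), c(1, 1), c(0, 2, 3)),
               "non-uniform")
  expect_error(ct_volume(array(0, c(4, 4, 3)), c(1, 1), c(0, -1, -2)),
               "increasing")
  vol <- ct_volume(array(0, c(4, 4, 3)), c(1, 1), c(0, 2, 4))
  expect_error(set_reference_geometry(vol, isocenter_mm = c(100, 0, 0)),
               "outside")
})
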