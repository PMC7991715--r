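# Shared geometry fixtures, built in code.

# Random small watertight mesh: a lofted blob (two to four random convex
# rings) or a tetrahedron, rigidly placed.
rand_mesh <- function(max_radius = 50, center = c(0, 0, 0)) {
  kind <- sample(c("blob", "tet"), 1)
  if (kind == "tet") {
    v <- matrix(stats::runif(12, -max_radius, max_radius), 4, 3)
    v <- sweep(v, 2, center, "+")
    f <- rbind(c(1, 2, 3), c(1, 4, 2), c(1, 3, 4), c(2, 4, 3))
    m <- tri_mesh(v, f)
    if (mesh_volume(m) < 0) m <- flip_mesh(m)
    return(m)
  }
  n_rings <- sample(2:4, 1)
  n <- sample(c(8L, 12L, 16L), 1)
  zs <- sort(stats::runif(n_rings, -max_radius, max_radius))
  zs <- zs + seq(0, 1e-3, length.out = n_rings)  # ensure distinct
  rings <- lapply(zs, function(z) {
    r <- stats::runif(1, max_radius / 4, max_radius)
    cx <- stats::runif(2, -max_radius / 4, max_radius / 4)
    th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
    slice_contour(cbind(cx[1] + r * cos(th), cx[2] + r * sin(th)), z_mm = z)
  })
  m <- loft_stack(rings, n = n, interp_substeps = 0)
  translate_mesh(m, center)
}

# Axis-aligned box mesh helper (exact, minimal tessellation).
box_mesh <- function(w, d, h, center = c(0, 0, 0)) {
  translate_mesh(
    build_primitive_mesh(list(shape = "box", width_mm = w, depth_mm = d,
                              height_mm = h)),
    center)
}

# Circle contour
circle_contour <- function(r, z, n = 64, center = c(0, 0), label = "body") {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  slice_contour(cbind(center[1] + r * cos(th), center[2] + r * sin(th)),
                z_mm = z, label = label)
}

loft_colliders_for_test <- function(stack)
  rtclear:::loft_colliders(stack, n = 64L, slice_stride = 2L)

# Small phantom volume for fast pipeline tests
small_phantom <- function(seed = 3L, ...) {
  make_phantom_ct(phantom_params(nx = 96L, ny = 96L, n_slices = 12L,
                                 pixel_spacing_mm = 4,
                                 body_semi_axes_mm = c(120, 80),
                                 noise_seed = seed, ...))
}
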