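# Polygonal solid primitives used to delineate machine components, and the
# ear-clipping triangulation shared with contour lofting.

polygon_signed_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  n <- nrow(p)
  j <- c(2:n, 1L)
  sum(x * y[j] - x[j] * y) / 2
}

polygon_is_simple <- function(p, tol = 1e-9) {
  n <- nrow(p)
  if (n < 3L) return(FALSE)
  segs <- cbind(p, p[c(2:n, 1L), , drop = FALSE])
  inter <- function(a1, a2, b1, b2) {
    d1 <- a2 - a1; d2 <- b2 - b1
    den <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(den) < tol) return(FALSE)
    t <- ((b1[1] - a1[1]) * d2[2] - (b1[2] - a1[2]) * d2[1]) / den
    u <- ((b1[1] - a1[1]) * d1[2] - (b1[2] - a1[2]) * d1[1]) / den
    t > tol && t < 1 - tol && u > tol && u < 1 - tol
  }
  for (i in seq_len(n - 1L)) {
    for (k in seq((i + 1L), n)) {
      if (k == i || k == i %% n + 1L || i == k %% n + 1L) next
      if (inter(segs[i, 1:2], segs[i, 3:4], segs[k, 1:2], segs[k, 3:4]))
        return(FALSE)
    }
  }
  TRUE
}

# Ear-clipping triangulation of a simple polygon (handles non-convex body
# outlines; collinear vertices are clipped as zero-area ears, which keeps the
# combinatorics watertight). Returns an (n-2) x 3 matrix of indices into p.
triangulate_polygon <- function(p) {
  n <- nrow(p)
  if (n < 3L) stop("polygon needs at least 3 vertices")
  if (n == 3L) return(matrix(1:3, 1))
  if (polygon_signed_area(p) < 0) stop("polygon must be counter-clockwise")
  idx <- seq_len(n)
  tris <- matrix(0L, n - 2L, 3L)
  scale <- max(apply(p, 2, function(v) diff(range(v))))
  eps <- 1e-12 * scale^2
  cross2 <- function(o, a, b)
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  in_tri <- function(q, a, b, c_) {
    d1 <- cross2(a, b, q); d2 <- cross2(b, c_, q); d3 <- cross2(c_, a, q)
    d1 > eps && d2 > eps && d3 > eps
  }
  k <- 0L
  guard <- 0L
  while (length(idx) > 3L) {
    m <- length(idx)
    clipped <- FALSE
    for (i in seq_len(m)) {
      ia <- idx[(i - 2L) %% m + 1L]
      ib <- idx[(i - 1L) %% m + 1L]
      ic <- idx[i %% m + 1L]
      a <- p[ia, ]; b <- p[ib, ]; c_ <- p[ic, ]
      cr <- cross2(a, b, c_)
      if (cr < -eps) next                      # reflex corner
      ok <- TRUE
      if (cr > eps) {                          # proper ear: must be empty
        for (j in idx) {
          if (j %in% c(ia, ib, ic)) next
          if (in_tri(p[j, ], a, b, c_)) { ok <- FALSE; break }
        }
      }
      if (ok) {
        k <- k + 1L
        tris[k, ] <- c(ia, ib, ic)
        idx <- idx[idx != ib]
        clipped <- TRUE
        break
      }
    }
    if (!clipped) {
      guard <- guard + 1L
      if (guard > 2L) stop("polygon triangulation failed (self-intersecting cap?)")
      eps <- eps * 100                         # retry with a looser tolerance
    }
  }
  k <- k + 1L
  tris[k, ] <- idx
  tris[seq_len(k), , drop = FALSE]
}

#' Build the mesh of one machine primitive
#'
#' Supported shapes: `box` (width x/depth y/height z, centered on the
#' origin), `cylinder` (radius, height; base in the z = 0 plane), `
#' truncated_cone` (r_bottom at z = 0, r_top at z = height), and
#' `extruded_polygon` (simple CCW cross-section in the x-y plane extruded
#' from z = 0 to z = length). Curved shapes are tessellated with
#' `tessellation` segments (inscribed prisms). The optional pose rotates
#' (XYZ Euler, degrees) then translates the solid in its component frame.
#'
#' @param p a primitive description: list with `shape`, per-shape dimension
#'   fields (`width_mm`/`depth_mm`/`height_mm`, `radius_mm`,
#'   `r_bottom_mm`/`r_top_mm`, `vertices_mm` + `length_mm`), optional
#'   `tessellation` (default 32, minimum 8) and `pose`
#'   (`rotation_deg`, `translation_mm`).
#' @param max_facet_mm facet-size bound: flat faces and walls are
#'   subdivided so no facet edge along a straight direction exceeds this
#'   (keeps bounding-volume pruning effective against large flat parts; it
#'   does not change the represented solid). Default `Inf`: the minimal
#'   exact tessellation; [build_machine_meshes()] applies an engine-level
#'   bound.
#' @return a watertight, outward-oriented [tri_mesh()] in the component
#'   frame.
#' @export
build_primitive_mesh <- function(p, max_facet_mm = Inf) {
  shape <- p$shape
  if (is.null(shape)) stop("primitive has no shape")
  mesh <- switch(shape,
    box = prim_box(p, max_facet_mm),
    cylinder = prim_cone(p, p$radius_mm, p$radius_mm, max_facet_mm),
    truncated_cone = prim_cone(p, p$r_bottom_mm, p$r_top_mm, max_facet_mm),
    extruded_polygon = prim_extrusion(p, max_facet_mm),
    stop("unknown shape '", shape, "'")
  )
  pose <- p$pose
  if (!is.null(pose)) {
    R <- diag(3)
    rot <- pose$rotation_deg
    if (!is.null(rot) && any(rot != 0))
      R <- rot_axis("z", rot[3]) %*% rot_axis("y", rot[2]) %*% rot_axis("x", rot[1])
    tr <- pose$translation_mm
    if (is.null(tr)) tr <- c(0, 0, 0)
    mesh <- transform_mesh(mesh, rigid_transform(R, tr))
  }
  if (mesh_volume(mesh) <= 0) mesh <- flip_mesh(mesh)
  mesh
}

check_dim <- function(x, what) {
  if (is.null(x) || !is.finite(x) || x <= 0)
    stop("non-positive or missing dimension: ", what)
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Box with each face subdivided into a grid so no facet exceeds max_facet.
prim_box <- function(p, max_facet = 150) {
  w <- check_dim(p$width_mm, "width_mm")
  d <- check_dim(p$depth_mm, "depth_mm")
  h <- check_dim(p$height_mm, "height_mm")
  ns <- pmax(1L, ceiling(c(w, d, h) / max_facet))
  cs <- list(seq(-w / 2, w / 2, length.out = ns[1] + 1L),
             seq(-d / 2, d / 2, length.out = ns[2] + 1L),
             seq(-h / 2, h / 2, length.out = ns[3] + 1L))
  env <- new.env(parent = emptyenv())
  verts <- list()
  get_v <- function(i, j, k) {
    key <- paste(i, j, k)
    id <- env[[key]]
    if (is.null(id)) {
      id <- length(verts) + 1L
      verts[[id]] <<- c(cs[[1]][i + 1L], cs[[2]][j + 1L], cs[[3]][k + 1L])
      env[[key]] <- id
    }
    id
  }
  faces <- list()
  # face: lattice point function of (u, v) grid + outward normal axis sign
  add_face <- function(nu, nv, point, outward) {
    for (u in seq_len(nu) - 1L) for (vv in seq_len(nv) - 1L) {
      a <- do.call(get_v, as.list(point(u, vv)))
      b <- do.call(get_v, as.list(point(u + 1L, vv)))
      c_ <- do.call(get_v, as.list(point(u + 1L, vv + 1L)))
      dd <- do.call(get_v, as.list(point(u, vv + 1L)))
      # orientation from the first cell of the face
      if (u == 0L && vv == 0L) {
        e1 <- verts[[b]] - verts[[a]]
        e2 <- verts[[dd]] - verts[[a]]
        n_ <- c(e1[2] * e2[3] - e1[3] * e2[2],
                e1[3] * e2[1] - e1[1] * e2[3],
                e1[1] * e2[2] - e1[2] * e2[1])
        flip_face <<- sum(n_ * outward) < 0
      }
      tri <- if (flip_face) rbind(c(a, dd, c_), c(a, c_, b))
        else rbind(c(a, b, c_), c(a, c_, dd))
      faces[[length(faces) + 1L]] <<- tri
    }
  }
  flip_face <- FALSE
  nx <- ns[1]; nyy <- ns[2]; nz <- ns[3]
  add_face(nyy, nz, function(u, v) c(0L, u, v), c(-1, 0, 0))
  add_face(nyy, nz, function(u, v) c(nx, u, v), c(1, 0, 0))
  add_face(nx, nz, function(u, v) c(u, 0L, v), c(0, -1, 0))
  add_face(nx, nz, function(u, v) c(u, nyy, v), c(0, 1, 0))
  add_face(nx, nyy, function(u, v) c(u, v, 0L), c(0, 0, -1))
  add_face(nx, nyy, function(u, v) c(u, v, nz), c(0, 0, 1))
  tri_mesh(do.call(rbind, verts), do.call(rbind, faces))
}

# Cylinder / truncated cone: n angular segments, axial bands and concentric
# cap rings bounded by max_facet.
prim_cone <- function(p, r_bottom, r_top, max_facet = 150) {
  r_bottom <- check_dim(r_bottom, "radius")
  r_top <- check_dim(r_top, "radius")
  h <- check_dim(p$height_mm, "height_mm")
  n <- p$tessellation %||% 32L
  if (n < 8L) stop("tessellation must be >= 8")
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  ct <- cos(th); st <- sin(th)
  m <- max(1L, ceiling(h / max_facet))
  zl <- seq(0, h, length.out = m + 1L)
  rl <- r_bottom + (r_top - r_bottom) * zl / h
  v <- do.call(rbind, lapply(seq_len(m + 1L), function(l)
    cbind(rl[l] * ct, rl[l] * st, zl[l])))
  i <- seq_len(n); j <- c(2:n, 1L)
  f <- list()
  for (l in seq_len(m)) {
    lo <- (l - 1L) * n; hi <- l * n
    f[[length(f) + 1L]] <- cbind(lo + i, lo + j, hi + j)
    f[[length(f) + 1L]] <- cbind(lo + i, hi + j, hi + i)
  }
  nv <- nrow(v)
  add_cap <- function(r_cap, z_cap, outer_ring, up) {
    mc <- max(1L, ceiling(r_cap / max_facet))
    rings <- list(outer_ring)   # indices of radius r_cap ring
    if (mc > 1L) for (q in (mc - 1L):1L) {
      rq <- r_cap * q / mc
      v <<- rbind(v, cbind(rq * ct, rq * st, z_cap))
      rings[[length(rings) + 1L]] <- nv + seq_len(n)
      nv <<- nv + n
    }
    v <<- rbind(v, c(0, 0, z_cap))
    centre <- nv + 1L
    nv <<- nv + 1L
    for (q in seq_len(length(rings) - 1L)) {
      a <- rings[[q]]; b <- rings[[q + 1L]]   # a outer, b inner
      if (up) {
        f[[length(f) + 1L]] <<- cbind(b[i], a[i], a[j])
        f[[length(f) + 1L]] <<- cbind(b[i], a[j], b[j])
      } else {
        f[[length(f) + 1L]] <<- cbind(b[i], a[j], a[i])
        f[[length(f) + 1L]] <<- cbind(b[i], b[j], a[j])
      }
    }
    inner <- rings[[length(rings)]]
    f[[length(f) + 1L]] <<- if (up) cbind(centre, inner[i], inner[j])
      else cbind(centre, inner[j], inner[i])
  }
  add_cap(r_bottom, 0, i, up = FALSE)
  add_cap(r_top, h, m * n + i, up = TRUE)
  tri_mesh(v, do.call(rbind, f))
}

# Split every polygon edge longer than max_facet into equal pieces.
densify_polygon <- function(pts, max_facet) {
  n <- nrow(pts)
  out <- list()
  for (k in seq_len(n)) {
    a <- pts[k, ]; b <- pts[k %% n + 1L, ]
    len <- sqrt(sum((b - a)^2))
    s <- max(1L, ceiling(len / max_facet))
    for (q in seq_len(s) - 1L)
      out[[length(out) + 1L]] <- a + (b - a) * q / s
  }
  do.call(rbind, out)
}

prim_extrusion <- function(p, max_facet = 150) {
  pts <- p$vertices_mm
  if (is.list(pts)) pts <- do.call(rbind, lapply(pts, as.numeric))
  pts <- as.matrix(pts)
  if (nrow(pts) < 3L) stop("extruded polygon needs >= 3 vertices")
  len <- check_dim(p$length_mm, "length_mm")
  if (abs(polygon_signed_area(pts)) < 1e-9)
    stop("degenerate polygon (zero area)")
  if (polygon_signed_area(pts) < 0) pts <- pts[rev(seq_len(nrow(pts))), ]
  if (!polygon_is_simple(pts)) stop("polygon must be simple (non-self-intersecting)")
  pts <- densify_polygon(pts, max_facet)
  n <- nrow(pts)
  m <- max(1L, ceiling(len / max_facet))
  zl <- seq(0, len, length.out = m + 1L)
  v <- do.call(rbind, lapply(zl, function(z) cbind(pts, z)))
  i <- seq_len(n); j <- c(2:n, 1L)
  f <- list()
  for (l in seq_len(m)) {
    lo <- (l - 1L) * n; hi <- l * n
    f[[length(f) + 1L]] <- cbind(lo + i, lo + j, hi + j)
    f[[length(f) + 1L]] <- cbind(lo + i, hi + j, hi + i)
  }
  caps <- triangulate_polygon(pts)
  f[[length(f) + 1L]] <- caps[, c(1L, 3L, 2L), drop = FALSE]  # bottom, -z
  f[[length(f) + 1L]] <- caps + m * n                         # top, +z
  tri_mesh(v, do.call(rbind, f))
}
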