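#' Triangle surface mesh
#'
#' Minimal indexed triangle-mesh container used for machine components,
#' lofted patient surfaces, and all proximity queries. Vertices are in mm in
#' a named frame (`"component"`, `"couch"`, or `"room"`).
#'
#' @param vertices numeric matrix, one row per vertex (x, y, z) in mm.
#' @param faces integer matrix, one row per triangle of 1-based vertex
#'   indices; consistent counter-clockwise winding seen from outside.
#' @param frame name of the coordinate frame the vertices live in.
#' @return an object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces, frame = "component") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an N x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an M x 3 matrix")
  if (nrow(faces) > 0L &&
      (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range [1, N]")
  if (!all(is.finite(vertices))) stop("vertex coordinates must be finite")
  structure(list(vertices = vertices, faces = faces, frame = frame),
            class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh: %d vertices, %d triangles, frame '%s'>\n",
              nrow(x$vertices), nrow(x$faces), x$frame))
  invisible(x)
}

#' Enclosed volume of a closed mesh
#'
#' Signed volume by the divergence theorem (sum of signed tetrahedra against
#' the origin). Positive for a watertight, outward-oriented mesh.
#'
#' @param mesh a [tri_mesh()].
#' @param signed return the signed value (default) or its absolute value.
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh, signed = TRUE) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  # scalar triple product a . (b x c) per face
  cx <- b[, 2] * c_[, 3] - b[, 3] * c_[, 2]
  cy <- b[, 3] * c_[, 1] - b[, 1] * c_[, 3]
  cz <- b[, 1] * c_[, 2] - b[, 2] * c_[, 1]
  vol <- sum(a[, 1] * cx + a[, 2] * cy + a[, 3] * cz) / 6
  if (signed) vol else abs(vol)
}

# Undirected edge table: each row one half-edge (i, j) as emitted by winding.
mesh_halfedges <- function(mesh) {
  f <- mesh$faces
  rbind(cbind(f[, 1], f[, 2]),
        cbind(f[, 2], f[, 3]),
        cbind(f[, 3], f[, 1]))
}

#' Watertightness check
#'
#' A mesh is accepted as watertight when every undirected edge is shared by
#' exactly two triangles with opposite orientation (each directed half-edge
#' appears exactly once).
#'
#' @param mesh a [tri_mesh()].
#' @return `TRUE`/`FALSE`.
#' @export
mesh_is_watertight <- function(mesh) {
  if (nrow(mesh$faces) == 0L) return(FALSE)
  he <- mesh_halfedges(mesh)
  dir_key <- paste(he[, 1], he[, 2])
  if (anyDuplicated(dir_key) > 0L) return(FALSE)
  und_key <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  all(table(und_key) == 2L)
}

#' Euler characteristic V - E + F
#'
#' Computed over the whole mesh; equals 2 per sphere-topology connected
#' component (so exactly 2 for one closed solid).
#'
#' @param mesh a [tri_mesh()].
#' @return integer.
#' @export
mesh_euler_characteristic <- function(mesh) {
  he <- mesh_halfedges(mesh)
  und_key <- unique(paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2])))
  used <- sort(unique(as.vector(mesh$faces)))
  length(used) - length(und_key) + nrow(mesh$faces)
}

#' Apply a rigid transform to a mesh
#'
#' @param mesh a [tri_mesh()].
#' @param rt a [rigid_transform()].
#' @param frame frame name of the result (default: keep).
#' @return transformed `tri_mesh`.
#' @export
transform_mesh <- function(mesh, rt, frame = mesh$frame) {
  v <- rt_apply(rt, mesh$vertices)
  out <- tri_mesh(v, mesh$faces, frame = frame)
  attrs <- attributes(mesh)
  for (nm in setdiff(names(attrs), c("names", "class")))
    attr(out, nm) <- attrs[[nm]]
  out
}

# Translate every vertex by a 3-vector.
translate_mesh <- function(mesh, t, frame = mesh$frame) {
  transform_mesh(mesh, rigid_transform(diag(3), t), frame = frame)
}

# Reverse triangle winding in place.
flip_mesh <- function(mesh) {
  mesh$faces <- mesh$faces[, c(1L, 3L, 2L), drop = FALSE]
  mesh
}

#' Write a mesh as ASCII STL
#'
#' @param mesh a [tri_mesh()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid rtclear", con)
  for (i in seq_len(nrow(f))) {
    a <- v[f[i, 1], ]; b <- v[f[i, 2], ]; c_ <- v[f[i, 3], ]
    n <- c((b[2] - a[2]) * (c_[3] - a[3]) - (b[3] - a[3]) * (c_[2] - a[2]),
           (b[3] - a[3]) * (c_[1] - a[1]) - (b[1] - a[1]) * (c_[3] - a[3]),
           (b[1] - a[1]) * (c_[2] - a[2]) - (b[2] - a[2]) * (c_[1] - a[1]))
    nn <- sqrt(sum(n^2))
    if (nn > 0) n <- n / nn
    writeLines(c(sprintf("  facet normal %.9g %.9g %.9g", n[1], n[2], n[3]),
                 "    outer loop",
                 sprintf("      vertex %.9g %.9g %.9g", a[1], a[2], a[3]),
                 sprintf("      vertex %.9g %.9g %.9g", b[1], b[2], b[3]),
                 sprintf("      vertex %.9g %.9g %.9g", c_[1], c_[2], c_[3]),
                 "    endloop",
                 "  endfacet"), con)
  }
  writeLines("endsolid rtclear", con)
  invisible(path)
}

#' Write a mesh as Wavefront OBJ
#'
#' @inheritParams write_stl
#' @return `path`, invisibly.
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g",
                     mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d",
                     mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]), con)
  invisible(path)
}

#' Read a Wavefront OBJ written by [write_obj()]
#'
#' Supports the plain `v`/`f` triangle subset this package emits.
#'
#' @param path OBJ file.
#' @param frame frame name for the result.
#' @return a [tri_mesh()].
#' @export
read_obj <- function(path, frame = "component") {
  lines <- readLines(path)
  vl <- grep("^v ", lines, value = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  if (length(vl) == 0L || length(fl) == 0L) stop("not a mesh OBJ file: ", path)
  v <- do.call(rbind, lapply(strsplit(sub("^v ", "", vl), "\\s+"),
                             function(x) as.numeric(x[1:3])))
  f <- do.call(rbind, lapply(strsplit(sub("^f ", "", fl), "\\s+"), function(x) {
    as.integer(sub("/.*$", "", x[1:3]))
  }))
  tri_mesh(v, f, frame = frame)
}
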