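#' Triangular surface mesh
#'
#' Construct a triangle mesh from a vertex matrix and a face index matrix.
#' Derived per-face unit normals, per-face areas and per-vertex unit
#' normals are computed eagerly and stored with the mesh; any function in
#' this package that modifies geometry rebuilds the mesh through this
#' constructor so derived quantities never go stale.
#'
#' Coordinates are in millimetres throughout the package (sections are
#' nominally 10 mm across).
#'
#' @param vertices numeric matrix with 3 columns (x, y, z), one row per
#'   vertex, in mm.
#' @param faces integer matrix with 3 columns of 1-based vertex indices,
#'   one row per triangle.
#' @return An object of class `triangle_mesh`: a list with elements
#'   `vertices`, `faces`, `face_normals`, `face_areas` (mm^2) and
#'   `vertex_normals` (angle-weighted average of incident face normals).
#'   Degenerate (zero-area) faces carry a zero normal and are skipped by
#'   the metric functions.
#' @examples
#' m <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
#'                    rbind(c(1, 2, 3)))
#' mesh_area(m)
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L)
    stop("`vertices` must have 3 columns (x, y, z)", call. = FALSE)
  if (nrow(vertices) == 0L)
    stop("empty mesh: no vertices", call. = FALSE)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(faces) != 3L)
    stop("`faces` must have 3 columns of vertex indices", call. = FALSE)
  if (nrow(faces) == 0L)
    stop("empty mesh: no faces", call. = FALSE)
  if (anyNA(vertices)) stop("`vertices` contains NA", call. = FALSE)
  if (anyNA(faces)) stop("`faces` contains NA", call. = FALSE)
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("face indices out of range [1, ", nrow(vertices), "]", call. = FALSE)
  dimnames(vertices) <- list(NULL, c("x", "y", "z"))
  dimnames(faces) <- NULL

  d <- .mesh_derived(vertices, faces)
  structure(
    list(vertices = vertices, faces = faces,
         face_normals = d$face_normals, face_areas = d$face_areas,
         vertex_normals = d$vertex_normals),
    class = "triangle_mesh")
}

# face normals / areas and angle-weighted vertex normals, vectorised
.mesh_derived <- function(V, F) {
  p1 <- V[F[, 1L], , drop = FALSE]
  p2 <- V[F[, 2L], , drop = FALSE]
  p3 <- V[F[, 3L], , drop = FALSE]
  u <- p2 - p1
  w <- p3 - p1
  cr <- cbind(u[, 2L] * w[, 3L] - u[, 3L] * w[, 2L],
              u[, 3L] * w[, 1L] - u[, 1L] * w[, 3L],
              u[, 1L] * w[, 2L] - u[, 2L] * w[, 1L])
  nrm2 <- sqrt(rowSums(cr^2))
  areas <- nrm2 / 2
  fn <- cr
  ok <- nrm2 > 0
  fn[ok, ] <- cr[ok, , drop = FALSE] / nrm2[ok]
  fn[!ok, ] <- 0

  # interior angle of each face at each of its three corners
  ang <- function(a, b) {
    na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
    cosv <- rowSums(a * b) / pmax(na * nb, .Machine$double.xmin)
    acos(pmin(1, pmax(-1, cosv)))
  }
  a1 <- ang(p2 - p1, p3 - p1)
  a2 <- ang(p1 - p2, p3 - p2)
  a3 <- ang(p1 - p3, p2 - p3)
  a1[!ok] <- 0; a2[!ok] <- 0; a3[!ok] <- 0

  vn <- matrix(0, nrow(V), 3L)
  for (j in 1:3) {
    wgt <- switch(j, a1, a2, a3)
    for (k in 1:3) {
      acc <- rowsum(wgt * fn[, k], F[, j], reorder = FALSE)
      idx <- as.integer(rownames(acc))
      vn[idx, k] <- vn[idx, k] + acc[, 1L]
    }
  }
  vlen <- sqrt(rowSums(vn^2))
  vok <- vlen > 0
  vn[vok, ] <- vn[vok, , drop = FALSE] / vlen[vok]
  dimnames(fn) <- NULL
  names(areas) <- NULL
  dimnames(vn) <- NULL
  list(face_normals = fn, face_areas = areas, vertex_normals = vn)
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh> %d vertices, %d faces, area %.4f mm^2\n",
              nrow(x$vertices), nrow(x$faces), mesh_area(x)))
  bb <- apply(x$vertices, 2L, range)
  cat(sprintf("  bbox x [%.3f, %.3f]  y [%.3f, %.3f]  z [%.3f, %.3f]\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

#' Mesh size and area helpers
#'
#' @param mesh a [triangle_mesh()].
#' @return `n_vertices()` and `n_faces()` return integer counts;
#'   `mesh_area()` the total surface area in mm^2 (sum of face areas);
#'   `face_centroids()` a matrix of per-face centroids.
#' @export
mesh_area <- function(mesh) sum(mesh$face_areas)

#' @rdname mesh_area
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' @rdname mesh_area
#' @export
n_faces <- function(mesh) nrow(mesh$faces)

#' @rdname mesh_area
#' @export
face_centroids <- function(mesh) {
  (mesh$vertices[mesh$faces[, 1L], , drop = FALSE] +
   mesh$vertices[mesh$faces[, 2L], , drop = FALSE] +
   mesh$vertices[mesh$faces[, 3L], , drop = FALSE]) / 3
}

#' Rotate a mesh about the vertical (Z) axis
#'
#' Rotation is counterclockwise when seen from +Z.  Angles that are
#' multiples of 90 degrees are applied exactly (no floating point residue
#' in the rotation matrix), which matters when testing the antisymmetry of
#' the orientation metric.
#'
#' @param mesh a [triangle_mesh()].
#' @param degrees rotation angle in degrees.
#' @return the rotated `triangle_mesh`.
#' @export
rotate_mesh_z <- function(mesh, degrees) {
  co <- cospi(degrees / 180)
  si <- sinpi(degrees / 180)
  R <- rbind(c(co, -si, 0), c(si, co, 0), c(0, 0, 1))
  triangle_mesh(mesh$vertices %*% t(R), mesh$faces)
}

#' Standardized surface section with provenance metadata
#'
#' A `surface_section` wraps a standardized mesh (aligned so the best-fit
#' plane normal is +Z) together with the metadata the comparison pipeline
#' needs: specimen, egg, zone along the egg long axis, and the in-plane
#' azimuth of the egg's pole-to-pole direction.
#'
#' @param mesh a [triangle_mesh()].
#' @param specimen_id,egg_id character identifiers.
#' @param zone integer zone 1-5 along the egg long axis (1 = acute pole).
#' @param long_axis_azimuth azimuth in degrees (counterclockwise from +X,
#'   within the X-Y plane) of the egg's pole-to-pole direction. Default 90
#'   (the +Y axis).
#' @param section_diameter nominal section diameter in mm.
#' @param section_id character identifier for the section.
#' @return an object of class `surface_section`.
#' @export
surface_section <- function(mesh, specimen_id = "unknown",
                            egg_id = "unknown", zone = 1L,
                            long_axis_azimuth = 90,
                            section_diameter = 10,
                            section_id = "s1") {
  stopifnot(inherits(mesh, "triangle_mesh"))
  zone <- as.integer(zone)
  if (length(zone) != 1L || is.na(zone) || !(zone %in% 1:5))
    stop("`zone` must be an integer in 1..5", call. = FALSE)
  if (!is.numeric(section_diameter) || section_diameter <= 0)
    stop("`section_diameter` must be > 0", call. = FALSE)
  structure(
    list(mesh = mesh,
         specimen_id = as.character(specimen_id),
         egg_id = as.character(egg_id),
         zone = zone,
         long_axis_azimuth = as.numeric(long_axis_azimuth),
         section_diameter = as.numeric(section_diameter),
         section_id = as.character(section_id)),
    class = "surface_section")
}

#' @export
print.surface_section <- function(x, ...) {
  cat(sprintf(
    "<surface_section> %s / %s / zone %d / %s  (%.1f mm, %d faces)\n",
    x$specimen_id, x$egg_id, x$zone, x$section_id,
    x$section_diameter, n_faces(x$mesh)))
  invisible(x)
}
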