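#' Detect boundary edges, vertices and faces
#'
#' An edge is a boundary edge when it is used by exactly one face.  Every
#' vertex on a boundary edge is flagged.  A face is flagged as boundary
#' under one of two policies: the `"vertex"` rule (default; the face
#' contains at least one boundary vertex -- the stricter discard used
#' before computing DNE) or the `"edge"` rule (the face owns a boundary
#' edge itself).
#'
#' @param mesh a [triangle_mesh()].
#' @param face_rule `"vertex"` or `"edge"`.
#' @return an object of class `boundary_info`: list with logical vectors
#'   `boundary_vertex_flags` (per vertex) and `boundary_face_flags` (per
#'   face), plus the `face_rule` used.
#' @export
detect_boundary <- function(mesh, face_rule = c("vertex", "edge")) {
  face_rule <- match.arg(face_rule)
  F <- mesh$faces
  e <- rbind(F[, c(1L, 2L)], F[, c(2L, 3L)], F[, c(3L, 1L)])
  lo <- pmin(e[, 1L], e[, 2L])
  hi <- pmax(e[, 1L], e[, 2L])
  key <- (as.double(lo) - 1) * nrow(mesh$vertices) + as.double(hi)
  cnt <- table(key)
  b_edge_key <- as.double(names(cnt)[cnt == 1L])
  edge_is_boundary <- key %in% b_edge_key

  vflag <- logical(nrow(mesh$vertices))
  vflag[c(lo[edge_is_boundary], hi[edge_is_boundary])] <- TRUE

  if (face_rule == "vertex") {
    fflag <- vflag[F[, 1L]] | vflag[F[, 2L]] | vflag[F[, 3L]]
  } else {
    m <- matrix(edge_is_boundary, ncol = 3L)  # columns: edges 12, 23, 31
    fflag <- m[, 1L] | m[, 2L] | m[, 3L]
  }
  structure(list(boundary_vertex_flags = vflag,
                 boundary_face_flags = fflag,
                 face_rule = face_rule),
            class = "boundary_info")
}

#' Align a mesh to the X-Y plane
#'
#' Rigidly rotates and translates the mesh so that the least-squares
#' best-fit plane of its vertices becomes the X-Y plane (plane normal
#' mapped to +Z, with the sign chosen so the mean face normal points up),
#' the vertex centroid sits at the origin, and the projection of
#' `long_axis_hint` into the plane maps to the +Y axis.  After alignment
#' the egg's pole-to-pole direction is therefore +Y (azimuth 90), the
#' convention the orientation metric defaults to.
#'
#' The hint is interpreted in the mesh's current coordinates, so applying
#' the function a second time with the default hint `c(0, 1, 0)` leaves an
#' already-aligned mesh unchanged (up to numerical noise).
#'
#' @param mesh a [triangle_mesh()].
#' @param long_axis_hint length-3 direction whose in-plane projection
#'   defines the egg long axis. Default `c(0, 1, 0)`.
#' @return the aligned `triangle_mesh`.
#' @export
align_to_xy <- function(mesh, long_axis_hint = c(0, 1, 0)) {
  V <- mesh$vertices
  if (nrow(V) < 3L)
    stop("alignment needs at least 3 vertices", call. = FALSE)
  ctr <- colMeans(V)
  Vc <- sweep(V, 2L, ctr)
  cv <- crossprod(Vc) / nrow(Vc)
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[2L] < 1e-12 * max(eg$values[1L], 1e-300))
    stop("degenerate vertex set: vertices are collinear", call. = FALSE)
  nrm <- eg$vectors[, 3L]
  # orient the plane normal with the surface's mean (area-weighted) normal
  mean_fn <- colSums(mesh$face_normals * mesh$face_areas)
  if (sum(mean_fn^2) > 0 && sum(mean_fn * nrm) < 0) nrm <- -nrm

  hint <- as.numeric(long_axis_hint)
  if (length(hint) != 3L || !all(is.finite(hint)))
    stop("`long_axis_hint` must be a finite length-3 direction", call. = FALSE)
  yb <- hint - sum(hint * nrm) * nrm
  if (sum(yb^2) < 1e-24)
    stop("`long_axis_hint` is parallel to the plane normal", call. = FALSE)
  yb <- yb / sqrt(sum(yb^2))
  xb <- c(yb[2L] * nrm[3L] - yb[3L] * nrm[2L],
          yb[3L] * nrm[1L] - yb[1L] * nrm[3L],
          yb[1L] * nrm[2L] - yb[2L] * nrm[1L])
  R <- rbind(xb, yb, nrm)
  triangle_mesh(Vc %*% t(R), mesh$faces)
}

#' Extract a circular surface section
#'
#' Selects the sub-mesh of faces whose centroids lie within
#' `diameter / 2` of `center`, with distance measured in the local
#' tangent plane (the X-Y plane for an aligned mesh).  The extracted
#' section is re-indexed and self-contained.
#'
#' @param mesh an aligned [triangle_mesh()].
#' @param center length-3 point (only x, y are used for the in-plane
#'   distance).
#' @param diameter section diameter in mm (the standardized sections are
#'   10 mm across).
#' @param ... metadata passed to [surface_section()] (`specimen_id`,
#'   `egg_id`, `zone`, `long_axis_azimuth`, `section_id`).
#' @return a [surface_section()].
#' @export
extract_section <- function(mesh, center = c(0, 0, 0), diameter = 10, ...) {
  if (!is.numeric(diameter) || diameter <= 0)
    stop("`diameter` must be > 0", call. = FALSE)
  center <- as.numeric(center)
  bb <- apply(mesh$vertices, 2L, range)
  if (center[1L] < bb[1L, 1L] || center[1L] > bb[2L, 1L] ||
      center[2L] < bb[1L, 2L] || center[2L] > bb[2L, 2L])
    stop("`center` lies outside the mesh bounding region", call. = FALSE)
  cen <- face_centroids(mesh)
  d2 <- (cen[, 1L] - center[1L])^2 + (cen[, 2L] - center[2L])^2
  keep <- d2 <= (diameter / 2)^2
  if (!any(keep))
    stop("empty section: no face centroid within ", diameter / 2,
         " mm of the given center", call. = FALSE)
  if (all(keep))
    warning("section diameter covers the whole mesh; returning it unchanged")
  sub <- .subset_faces(mesh, keep)
  surface_section(sub, section_diameter = diameter, ...)
}

# keep a logical subset of faces, dropping unused vertices
.subset_faces <- function(mesh, keep) {
  F <- mesh$faces[keep, , drop = FALSE]
  used <- sort(unique(as.vector(F)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  triangle_mesh(mesh$vertices[used, , drop = FALSE],
                matrix(remap[F], ncol = 3L))
}
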