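#' Decimate a mesh to an exact face count
#'
#' Quadric edge-collapse decimation.  Vertex quadrics accumulate the
#' area-weighted planes of incident faces; boundary edges contribute
#' perpendicular constraint planes (so the rim of an open section is
#' preserved) and collapses that would pinch or fold the surface are
#' rejected.  Interior collapses remove two faces and boundary-edge
#' collapses one, and the loop stops exactly at `target_faces`.  The
#' standardized sections used by the scoring pipeline are decimated to
#' 5000 faces.
#'
#' On a closed mesh every collapse removes two faces, so a target whose
#' parity differs from the input cannot be reached exactly; the function
#' then stops one face above the target with a warning.
#'
#' @param mesh a [triangle_mesh()].
#' @param target_faces desired face count (>= 4).
#' @param boundary_weight weight multiplier for the boundary constraint
#'   planes; larger values pin the rim harder.
#' @return the decimated `triangle_mesh`.  If the mesh already has
#'   `target_faces` faces or fewer it is returned unchanged (with a
#'   warning when it is strictly smaller).
#' @export
decimate <- function(mesh, target_faces = 5000, boundary_weight = 100) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  target_faces <- as.integer(target_faces)
  if (is.na(target_faces) || target_faces < 4L)
    stop("`target_faces` must be at least 4", call. = FALSE)
  nf <- n_faces(mesh)
  if (nf < target_faces) {
    warning("mesh has ", nf, " faces, fewer than the target ",
            target_faces, "; returning it unchanged")
    return(mesh)
  }
  if (nf == target_faces) return(mesh)
  res <- .decimate_qem_cpp(mesh$vertices, mesh$faces, target_faces,
                           boundary_weight)
  if (res$achieved != target_faces)
    warning("decimation stopped at ", res$achieved,
            " faces (target ", target_faces,
            "): no further collapse was admissible")
  triangle_mesh(res$vertices, res$faces)
}
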