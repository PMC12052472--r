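#' Settings shared by the topographic metrics
#'
#' @param dne_outlier_fraction fraction of the highest per-face energy
#'   contributions (e x A) discarded before summing DNE.  Default 0.001
#'   (the top 0.1 percent), which suppresses the occasional near-singular
#'   face without touching the signal.
#' @param boundary_discard how faces at the open rim of a section are
#'   excluded before DNE and Slope: `"vertex"` (default; any face with a
#'   vertex on a boundary edge), `"edge"` (only faces owning a boundary
#'   edge) or `"none"`.
#' @param slope_weighting `"unweighted"` (default; plain mean over faces)
#'   or `"area"` (area-weighted mean).
#' @param along_axis_bins which of the eight 45-degree azimuth bins count
#'   as facing *along* the egg long axis.  With the long axis on +Y the
#'   flank normals of pole-to-pole ridges point towards +X or -X, so the
#'   default is bins 1, 4, 5 and 8 (azimuths within 45 degrees of 0 or
#'   180); the complementary bins 2, 3, 6, 7 face around the short axis.
#' @param long_axis_azimuth azimuth (degrees counterclockwise from +X) of
#'   the egg's pole-to-pole direction in the section frame.  Default 90
#'   (+Y).  Azimuth bins are always taken in the rotated frame in which
#'   the long axis is +Y, so the bin set keeps its meaning whatever the
#'   azimuth.
#' @param vertical_tolerance if the X-Y projection of a face normal is
#'   shorter than this, the face counts as flat-on (normal vertical) and
#'   its area is excluded from the azimuth bins.
#' @return an object of class `metric_settings` (a list).  `bin_count`
#'   (8) and `bin_width` (45 degrees) are fixed.
#' @export
metric_settings <- function(dne_outlier_fraction = 0.001,
                            boundary_discard = c("vertex", "edge", "none"),
                            slope_weighting = c("unweighted", "area"),
                            along_axis_bins = c(1L, 4L, 5L, 8L),
                            long_axis_azimuth = 90,
                            vertical_tolerance = 1e-9) {
  boundary_discard <- match.arg(boundary_discard)
  slope_weighting <- match.arg(slope_weighting)
  if (dne_outlier_fraction < 0 || dne_outlier_fraction >= 1)
    stop("`dne_outlier_fraction` must be in [0, 1)", call. = FALSE)
  along_axis_bins <- sort(unique(as.integer(along_axis_bins)))
  if (!all(along_axis_bins %in% 1:8) || length(along_axis_bins) %in% c(0L, 8L))
    stop("`along_axis_bins` must be a proper non-empty subset of 1..8",
         call. = FALSE)
  structure(list(dne_outlier_fraction = dne_outlier_fraction,
                 boundary_discard = boundary_discard,
                 slope_weighting = slope_weighting,
                 bin_count = 8L, bin_width = 45,
                 along_axis_bins = along_axis_bins,
                 long_axis_azimuth = as.numeric(long_axis_azimuth),
                 vertical_tolerance = vertical_tolerance),
            class = "metric_settings")
}

# logical vector: faces retained after boundary discard (TRUE = keep);
# degenerate zero-area faces are always dropped
.retained_faces <- function(mesh, settings) {
  keep <- mesh$face_areas > 0
  if (settings$boundary_discard != "none") {
    bi <- detect_boundary(mesh, face_rule = settings$boundary_discard)
    keep <- keep & !bi$boundary_face_flags
  }
  keep
}

#' Surface complexity: Dirichlet normal energy
#'
#' For each face with vertices v1, v2, v3 and unit vertex normals n1, n2,
#' n3, let u = v2 - v1, w = v3 - v1, nu = n2 - n1, nw = n3 - n1, and form
#' the first fundamental form G = \[\[u.u, u.w\], \[u.w, w.w\]\] and the
#' normal-variation form H = \[\[nu.nu, nu.nw\], \[nu.nw, nw.nw\]\].  The
#' Dirichlet energy density is e = tr(G^-1 H), and the mesh DNE is the
#' sum of e x A over retained faces, after discarding boundary faces and
#' the top `dne_outlier_fraction` of contributions.  A flat surface has
#' e = 0 everywhere; a sphere has e = 2 / r^2 so its total DNE is 8 * pi
#' whatever the radius, which also makes the metric invariant under
#' uniform scaling.
#'
#' @param mesh an aligned [triangle_mesh()].
#' @param settings a [metric_settings()].
#' @return an object of class `dne_result`: list with `total` (the DNE
#'   value), `faces` (data frame of per-face energy densities, areas and
#'   contributions with a `retained` flag and `skip_reason`), and
#'   `n_skipped` (degenerate faces with singular G).
#' @export
dne <- function(mesh, settings = metric_settings()) {
  keep <- .retained_faces(mesh, settings)
  V <- mesh$vertices; F <- mesh$faces; N <- mesh$vertex_normals
  u <- V[F[, 2L], , drop = FALSE] - V[F[, 1L], , drop = FALSE]
  w <- V[F[, 3L], , drop = FALSE] - V[F[, 1L], , drop = FALSE]
  nu <- N[F[, 2L], , drop = FALSE] - N[F[, 1L], , drop = FALSE]
  nw <- N[F[, 3L], , drop = FALSE] - N[F[, 1L], , drop = FALSE]
  guu <- rowSums(u * u); guw <- rowSums(u * w); gww <- rowSums(w * w)
  huu <- rowSums(nu * nu); huw <- rowSums(nu * nw); hww <- rowSums(nw * nw)
  det <- guu * gww - guw^2
  singular <- det <= .Machine$double.eps * pmax(guu * gww, 1e-300)
  e <- ifelse(singular, NA_real_,
              (gww * huu - 2 * guw * huw + guu * hww) / det)
  A <- mesh$face_areas
  contrib <- e * A

  reason <- rep(NA_character_, nrow(F))
  reason[!keep] <- "boundary"
  reason[keep & singular] <- "degenerate"
  retained <- keep & !singular
  if (!any(retained))
    stop("DNE undefined: no non-degenerate interior face", call. = FALSE)

  # outlier trim: drop the top fraction of contributions among retained faces
  n_drop <- floor(settings$dne_outlier_fraction * sum(retained))
  if (n_drop > 0) {
    idx <- which(retained)
    ord <- idx[order(contrib[idx], decreasing = TRUE)]
    drop_idx <- ord[seq_len(n_drop)]
    retained[drop_idx] <- FALSE
    reason[drop_idx] <- "energy_outlier"
  }
  faces_df <- data.frame(face = seq_len(nrow(F)), energy_density = e,
                         area = A, contribution = contrib,
                         retained = retained, skip_reason = reason)
  structure(list(total = sum(contrib[retained]),
                 faces = faces_df,
                 n_skipped = sum(singular & keep)),
            class = "dne_result")
}

#' @export
print.dne_result <- function(x, ...) {
  cat(sprintf("DNE = %.6g over %d retained faces (%d skipped)\n",
              x$total, sum(x$faces$retained), x$n_skipped))
  invisible(x)
}

#' Surface relief: mean face slope
#'
#' The slope of a face is the angle of its plane from the horizontal,
#' `acos(|n_z|)` in degrees, using the undirected normal so the value
#' always lies in \[0, 90\].  The relief metric is the mean slope over
#' faces retained after boundary discard -- unweighted by default, or
#' area-weighted via `slope_weighting = "area"`.
#'
#' @inheritParams dne
#' @return an object of class `slope_result`: list with `mean` (degrees)
#'   and `face_slopes` (per-face degrees, `NA` for discarded faces).
#' @export
slope <- function(mesh, settings = metric_settings()) {
  keep <- .retained_faces(mesh, settings)
  if (!any(keep))
    stop("slope undefined: no retained face", call. = FALSE)
  theta <- acos(pmin(1, abs(mesh$face_normals[, 3L]))) * 180 / pi
  m <- if (settings$slope_weighting == "area") {
    sum(theta[keep] * mesh$face_areas[keep]) / sum(mesh$face_areas[keep])
  } else {
    mean(theta[keep])
  }
  theta[!keep] <- NA_real_
  structure(list(mean = m, face_slopes = theta), class = "slope_result")
}

#' @export
print.slope_result <- function(x, ...) {
  cat(sprintf("mean slope = %.4f degrees over %d faces\n",
              x$mean, sum(!is.na(x$face_slopes))))
  invisible(x)
}

#' Surface area per 45-degree azimuth bin
#'
#' Each face normal is projected into the X-Y plane and its azimuth
#' (counterclockwise from +X, in the rotated frame where the egg long
#' axis is +Y) assigns the face to one of eight 45-degree bins: bin k
#' covers \[45(k-1), 45k) degrees.  Face area accumulates into the bin;
#' faces whose normal projection is shorter than `vertical_tolerance`
#' (flat-on faces) accumulate into the excluded area instead.  Bin areas
#' plus the excluded area always equal the total retained face area.
#'
#' @inheritParams dne
#' @return an object of class `bin_areas`: list with `areas` (numeric
#'   length 8, mm^2), `excluded_area`, and `total_area`.
#' @export
bin_areas <- function(mesh, settings = metric_settings()) {
  keep <- mesh$face_areas > 0
  N <- mesh$face_normals
  proj <- sqrt(N[, 1L]^2 + N[, 2L]^2)
  vertical <- proj < settings$vertical_tolerance
  phi <- atan2(N[, 2L], N[, 1L]) * 180 / pi
  phi <- (phi - (settings$long_axis_azimuth - 90)) %% 360
  bin <- pmin(floor(phi / settings$bin_width) + 1L, settings$bin_count)

  areas <- numeric(settings$bin_count)
  sel <- keep & !vertical
  if (any(sel)) {
    acc <- rowsum(mesh$face_areas[sel], bin[sel])
    areas[as.integer(rownames(acc))] <- acc[, 1L]
  }
  structure(list(areas = areas,
                 excluded_area = sum(mesh$face_areas[keep & vertical]),
                 total_area = sum(mesh$face_areas[keep])),
            class = "bin_areas")
}

#' Surface directionality: the orientation score
#'
#' Splits the binned surface area of [bin_areas()] into the area facing
#' along the egg long axis (`along_axis_bins`, default 1, 4, 5, 8) and
#' the area facing around the short axis (the complementary bins), and
#' maps their ratio onto a bounded scale:
#'
#'   Omega = 100 * (SA_along - SA_across) / (SA_along + SA_across)
#'
#' equivalently `100 * (R - 1) / (R + 1)` for the ratio
#' `R = SA_along / SA_across`.  Omega is +100 when every non-flat face
#' is in the along-axis bins (ornamentation running pole-to-pole), -100
#' when everything faces around the short axis, and 0 for a rotationally
#' symmetric surface.  The transform is isolated here so an alternative
#' mapping of the ratio can be swapped in.
#'
#' @inheritParams dne
#' @return the orientation score, a number in \[-100, 100\].
#' @export
orientation <- function(mesh, settings = metric_settings()) {
  ba <- bin_areas(mesh, settings)
  along <- sum(ba$areas[settings$along_axis_bins])
  across <- sum(ba$areas[-settings$along_axis_bins])
  if (along + across <= 0)
    stop("orientation undefined: no non-vertical surface area",
         call. = FALSE)
  100 * (along - across) / (along + across)
}

#' Score a standardized section: complexity, relief, orientation
#'
#' Computes the three topographic metrics for one [surface_section()] and
#' assembles them with the section metadata into a one-row data frame
#' (the row format of the SCORE CSV export).  The section's
#' `long_axis_azimuth` overrides the one in `settings`.  A metric that
#' fails (e.g. orientation on a perfectly flat section) yields `NA` with
#' a warning tagged with the section id; the other metrics are kept.
#'
#' @param section a [surface_section()].
#' @param settings a [metric_settings()].
#' @return a one-row data frame with columns `specimen_id`, `egg_id`,
#'   `zone`, `section_id`, `complexity`, `relief`, `orientation`.
#' @export
score <- function(section, settings = metric_settings()) {
  stopifnot(inherits(section, "surface_section"))
  settings$long_axis_azimuth <- section$long_axis_azimuth
  grab <- function(expr, what) {
    tryCatch(expr, error = function(e) {
      warning(sprintf("section %s: %s failed: %s",
                      section$section_id, what, conditionMessage(e)),
              call. = FALSE)
      NA_real_
    })
  }
  data.frame(specimen_id = section$specimen_id,
             egg_id = section$egg_id,
             zone = section$zone,
             section_id = section$section_id,
             complexity = grab(dne(section$mesh, settings)$total, "complexity"),
             relief = grab(slope(section$mesh, settings)$mean, "relief"),
             orientation = grab(orientation(section$mesh, settings),
                                "orientation"),
             stringsAsFactors = FALSE)
}

#' Score a batch of sections
#'
#' @param sections list of [surface_section()] objects.
#' @param settings a [metric_settings()].
#' @return data frame with one row per section, in input order.
#' @export
score_batch <- function(sections, settings = metric_settings()) {
  do.call(rbind, lapply(sections, score, settings = settings))
}

#' Write the SCORE CSV
#'
#' One row per section with the three metrics; the metric settings are
#' echoed as `#`-prefixed comment lines above the header for provenance.
#'
#' @param records data frame from [score_batch()].
#' @param path output path.
#' @param settings the [metric_settings()] used (echoed as comments).
#' @return `path`, invisibly.
#' @export
write_score_csv <- function(records, path, settings = metric_settings()) {
  con <- file(path, "wb")  # binary mode: identical bytes on every platform
  on.exit(close(con))
  hdr <- c(
    paste0("# dne_outlier_fraction=", format(settings$dne_outlier_fraction)),
    paste0("# boundary_discard=", settings$boundary_discard),
    paste0("# slope_weighting=", settings$slope_weighting),
    paste0("# along_axis_bins=", paste(settings$along_axis_bins, collapse = ";")),
    paste0("# long_axis_azimuth=", format(settings$long_axis_azimuth)))
  writeLines(hdr, con)
  writeLines("specimen_id,egg_id,zone,section_id,complexity,relief,orientation",
             con)
  writeLines(sprintf("%s,%s,%d,%s,%s,%s,%s",
                     records$specimen_id, records$egg_id,
                     as.integer(records$zone), records$section_id,
                     .num_str(records$complexity), .num_str(records$relief),
                     .num_str(records$orientation)), con)
  invisible(path)
}

.num_str <- function(x) ifelse(is.na(x), "NA", sprintf("%.10g", x))

#' Read a SCORE CSV written by [write_score_csv()]
#'
#' @param path file path.
#' @return data frame of score records (comment lines skipped).
#' @export
read_score_csv <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
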