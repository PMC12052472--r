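#' Parameters for a synthetic ornamented section
#'
#' The generator emulates the standardized inputs of the scoring
#' workflow: a 10 mm diameter surface section carrying node (dome) and
#' ridge ornamentation on an otherwise flat shell patch, as a height
#' field z(x, y) triangulated over a disc.  Nodes are radially symmetric
#' Gaussians; ridges are Gaussian-profile crests extruded along
#' `ridge_azimuth`; a band-limited smooth noise field adds fine texture.
#' Amplitudes control relief, node density and width control complexity,
#' and the balance of ridges versus nodes (and the ridge azimuth)
#' controls directionality.
#'
#' Default amplitudes and widths are in the range of real eggshell
#' ornamentation: node and ridge crests a few tenths of a millimetre
#' high and around half a millimetre wide.
#'
#' @param section_diameter disc diameter in mm (default 10).
#' @param grid_resolution grid vertices per mm (default 12, giving about
#'   22000 faces before decimation -- comfortably above the 5000-face
#'   standard the pipeline decimates to).
#' @param node_count number of Gaussian nodes scattered over the disc
#'   (at most 1024; centres are drawn from a fixed-size seeded pool so
#'   that increasing the count adds nodes to the same arrangement).
#' @param node_amplitude node height in mm.
#' @param node_width node Gaussian sigma in mm.
#' @param ridge_count number of parallel ridges crossing the disc.
#' @param ridge_amplitude ridge crest height in mm.
#' @param ridge_width ridge Gaussian sigma in mm.
#' @param ridge_azimuth direction the ridge crests run, in degrees
#'   counterclockwise from +X (default 90: along the +Y long axis).
#' @param noise_amplitude standard deviation of the smooth noise field,
#'   mm.
#' @param seed integer seed; the generated mesh is a deterministic
#'   function of the full parameter set.
#' @return an object of class `synth_params`.
#' @export
synth_params <- function(section_diameter = 10, grid_resolution = 12,
                         node_count = 30, node_amplitude = 0.2,
                         node_width = 0.4, ridge_count = 5,
                         ridge_amplitude = 0.2, ridge_width = 0.5,
                         ridge_azimuth = 90, noise_amplitude = 0.02,
                         seed = 1L) {
  stopifnot(section_diameter > 0, grid_resolution > 0,
            node_count >= 0, node_count <= 1024, node_amplitude >= 0,
            node_width > 0, ridge_count >= 0, ridge_amplitude >= 0,
            ridge_width > 0, noise_amplitude >= 0)
  structure(as.list(environment()), class = "synth_params")
}

#' Generate a synthetic ornamented surface section
#'
#' Builds the height field described in [synth_params()], triangulates it
#' over a disc (alternating cell diagonals, to avoid a directional bias
#' from the triangulation itself) and returns it as a standardized
#' [surface_section()].  Deterministic given the seed.
#'
#' @param params a [synth_params()].
#' @param specimen_id,egg_id,zone,section_id metadata for the section.
#' @param relative_position optional position along the egg long axis in
#'   \[0, 1\] (0 = acute pole); when given, `zone` is derived via
#'   [zone_of()].
#' @return a [surface_section()] whose `long_axis_azimuth` is 90 (the
#'   generator's frame puts the egg long axis on +Y).
#' @export
make_section <- function(params = synth_params(), specimen_id = "synth",
                         egg_id = "egg1", zone = 1L, section_id = "s1",
                         relative_position = NULL) {
  stopifnot(inherits(params, "synth_params"))
  r <- params$section_diameter / 2
  step <- 1 / params$grid_resolution
  g <- seq(-r, r, by = step)
  nx <- length(g)
  # ~ 2 * pi r^2 * res^2 faces end up inside the disc
  est_faces <- 2 * pi * r^2 * params$grid_resolution^2
  if (est_faces < 5000)
    stop("grid_resolution too low: about ", round(est_faces),
         " faces would be generated; need at least 5000", call. = FALSE)

  xy <- expand.grid(x = g, y = g)
  z <- .with_seed(params$seed, .synth_height(xy$x, xy$y, params))
  V <- cbind(xy$x, xy$y, z)

  F <- .grid_faces(nx, nx)
  cen_x <- (V[F[, 1L], 1L] + V[F[, 2L], 1L] + V[F[, 3L], 1L]) / 3
  cen_y <- (V[F[, 1L], 2L] + V[F[, 2L], 2L] + V[F[, 3L], 2L]) / 3
  keep <- cen_x^2 + cen_y^2 <= r^2
  F <- F[keep, , drop = FALSE]
  used <- sort(unique(as.vector(F)))
  remap <- integer(nrow(V))
  remap[used] <- seq_along(used)
  mesh <- triangle_mesh(V[used, , drop = FALSE], matrix(remap[F], ncol = 3L))

  if (!is.null(relative_position)) zone <- zone_of(relative_position)
  surface_section(mesh, specimen_id = specimen_id, egg_id = egg_id,
                  zone = zone, long_axis_azimuth = 90,
                  section_diameter = params$section_diameter,
                  section_id = section_id)
}

# height field: nodes + ridges + band-limited noise (RNG already seeded)
.synth_height <- function(x, y, p) {
  r <- p$section_diameter / 2
  z <- numeric(length(x))
  # node centres come from a fixed-size seeded pool: raising node_count
  # adds nodes to the same arrangement instead of reshuffling it, so
  # density ladders are nested and complexity grows monotonically
  rho <- r * sqrt(runif(1024L))
  th <- runif(1024L, 0, 2 * pi)
  if (p$node_count > 0 && p$node_amplitude > 0) {
    cx <- (rho * cos(th))[seq_len(p$node_count)]
    cy <- (rho * sin(th))[seq_len(p$node_count)]
    for (i in seq_len(p$node_count)) {
      d2 <- (x - cx[i])^2 + (y - cy[i])^2
      z <- z + p$node_amplitude * exp(-d2 / (2 * p$node_width^2))
    }
  }
  if (p$ridge_count > 0 && p$ridge_amplitude > 0) {
    # signed distance from crest lines running along ridge_azimuth
    az <- p$ridge_azimuth * pi / 180
    tpos <- -sin(az) * x + cos(az) * y       # coordinate across the crests
    spacing <- p$section_diameter / (p$ridge_count + 1)
    offsets <- (seq_len(p$ridge_count) - (p$ridge_count + 1) / 2) * spacing
    offsets <- offsets + runif(p$ridge_count, -0.2, 0.2) * spacing
    for (off in offsets) {
      z <- z + p$ridge_amplitude * exp(-(tpos - off)^2 / (2 * p$ridge_width^2))
    }
  }
  if (p$noise_amplitude > 0) {
    nwave <- 16L
    fr <- matrix(runif(2L * nwave, -1.2, 1.2), ncol = 2L)  # cycles per mm
    ph <- runif(nwave, 0, 2 * pi)
    amp <- rnorm(nwave)
    field <- numeric(length(x))
    for (i in seq_len(nwave)) {
      field <- field + amp[i] * cos(2 * pi * (fr[i, 1L] * x + fr[i, 2L] * y) +
                                    ph[i])
    }
    z <- z + p$noise_amplitude * field / sqrt(sum(amp^2) / 2)
  }
  z
}

# alternating-diagonal triangulation of an nx x ny vertex grid
.grid_faces <- function(nx, ny) {
  i <- rep(seq_len(nx - 1L), times = ny - 1L)
  j <- rep(seq_len(ny - 1L), each = nx - 1L)
  v00 <- (j - 1L) * nx + i
  v10 <- v00 + 1L
  v01 <- v00 + nx
  v11 <- v01 + 1L
  flip <- (i + j) %% 2L == 0L
  t1 <- cbind(v00, v10, ifelse(flip, v11, v01))
  t2 <- cbind(ifelse(flip, v00, v10), v11, v01)
  rbind(t1, t2)
}

#' Map a relative long-axis position to an egg zone
#'
#' The egg is divided into five equal-length zones along its long axis;
#' zone 1 is the acute pole.  Intervals are half-open with the upper
#' endpoint closed into zone 5, so `zone_of(1) == 5`.
#'
#' @param relative_position fraction in \[0, 1\] along the long axis
#'   (0 = acute pole).
#' @return integer zone in 1..5 (vectorised).
#' @export
zone_of <- function(relative_position) {
  p <- as.numeric(relative_position)
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("`relative_position` must lie in [0, 1]", call. = FALSE)
  pmin(as.integer(floor(5 * p)) + 1L, 5L)
}

#' Parameters for a synthetic egg (a clutch of sections)
#'
#' @param egg_length,egg_width egg dimensions in mm (defaults 137 x 92,
#'   the size class of a large theropod egg); recorded as metadata only --
#'   sections are local height fields.
#' @param sections_per_zone sections generated in each of the five zones
#'   (default 6, giving the 30-section minimum an egg needs to enter the
#'   analysis).
#' @param base a [synth_params()] giving the egg's baseline ornamentation.
#' @param zone_overrides named list (`"1"` .. `"5"`) of parameter lists
#'   overriding `base` within a zone, e.g.
#'   `list("5" = list(node_amplitude = 0.05))` for ornamentation fading
#'   towards the blunt pole.
#' @param seed integer master seed; per-section seeds are derived from it.
#' @return an object of class `synth_egg_params`.
#' @export
synth_egg_params <- function(egg_length = 137, egg_width = 92,
                             sections_per_zone = 6, base = synth_params(),
                             zone_overrides = list(), seed = 1L) {
  stopifnot(egg_length > 0, egg_width > 0, sections_per_zone >= 1,
            inherits(base, "synth_params"))
  if (length(zone_overrides) &&
      !all(names(zone_overrides) %in% as.character(1:5)))
    stop("`zone_overrides` must be named by zone (\"1\"..\"5\")",
         call. = FALSE)
  structure(list(egg_length = egg_length, egg_width = egg_width,
                 sections_per_zone = as.integer(sections_per_zone),
                 base = base, zone_overrides = zone_overrides,
                 seed = as.integer(seed)),
            class = "synth_egg_params")
}

#' Generate the sections of a synthetic egg
#'
#' Produces `5 * sections_per_zone` sections (30 by default), each placed
#' at a deterministic relative position along the long axis and labelled
#' with its zone via [zone_of()].  Per-zone overrides allow ornamentation
#' gradients from the acute pole (zone 1) to the blunt pole (zone 5).
#' Per-section seeds are drawn once from the master seed, so the whole
#' clutch is reproducible.
#'
#' @param params a [synth_egg_params()].
#' @param specimen_id,egg_id metadata applied to every section.
#' @return list of [surface_section()] objects.
#' @export
make_egg <- function(params = synth_egg_params(), specimen_id = "synth",
                     egg_id = "egg1") {
  stopifnot(inherits(params, "synth_egg_params"))
  spz <- params$sections_per_zone
  n <- 5L * spz
  seeds <- .with_seed(params$seed, sample.int(.Machine$integer.max, n))
  sections <- vector("list", n)
  idx <- 0L
  for (zone in 1:5) {
    sp <- params$base
    ov <- params$zone_overrides[[as.character(zone)]]
    if (!is.null(ov)) for (nm in names(ov)) sp[[nm]] <- ov[[nm]]
    class(sp) <- "synth_params"
    for (j in seq_len(spz)) {
      idx <- idx + 1L
      pos <- (zone - 1L) / 5 + (j - 0.5) / (5 * spz)
      sp$seed <- seeds[idx]
      sections[[idx]] <- make_section(
        sp, specimen_id = specimen_id, egg_id = egg_id,
        section_id = sprintf("%s_z%d_s%02d", egg_id, zone, j),
        relative_position = pos)
    }
  }
  sections
}

#' Write generated sections to disk with a manifest
#'
#' Each section is written as an ASCII PLY; a `manifest.csv` records the
#' metadata (`path, specimen_id, egg_id, zone, section_id,
#' long_axis_azimuth, section_diameter`) that [run_score()] needs to
#' re-ingest the clutch.
#'
#' @param sections list of [surface_section()] objects.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_sections <- function(sections, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(sections, function(s) {
    fn <- paste0(s$section_id, ".ply")
    write_mesh(s$mesh, file.path(dir, fn), format = "ply")
    data.frame(path = fn, specimen_id = s$specimen_id, egg_id = s$egg_id,
               zone = s$zone, section_id = s$section_id,
               long_axis_azimuth = s$long_axis_azimuth,
               section_diameter = s$section_diameter,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  .write_csv_bytes(manifest, mpath)
  invisible(mpath)
}
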