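test_that("triangle_mesh derives unit normals, areas and validates input", {
  m <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                     rbind(c(1, 2, 3)))
  expect_equal(m$face_areas, 0.5)
  expect_equal(m$face_normals[1, ], c(0, 0, 1))
  expect_equal(sqrt(sum(m$face_normals[1, ]^2)), 1, tolerance = 1e-9)
  expect_equal(mesh_area(m), sum(m$face_areas))
  expect_error(triangle_mesh(matrix(0, 0, 3), rbind(c(1, 2, 3))), "empty")
  expect_error(triangle_mesh(diag(3), rbind(c(1, 2, 4))), "out of range")
})

test_that("vertex normals of a sphere point radially", {
  sp <- icosphere(2)
  dots <- rowSums(sp$vertex_normals * sp$vertices)
  expect_true(all(dots > 0.99))
})

test_that("ASCII PLY reader parses a minimal single-triangle file", {
  f <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0",
               "element vertex 3",
               "property float x", "property float y", "property float z",
               "element face 1",
               "property list uchar int vertex_indices",
               "end_header",
               "0 0 0", "1 0 0", "0 1 0",
               "3 0 1 2"), f)
  m <- read_mesh(f)
  expect_equal(n_vertices(m), 3L)
  expect_equal(n_faces(m), 1L)
})

test_that("PLY write/read round trip is bit-exact", {
  set.seed(11)
  V <- matrix(rnorm(30), 10, 3)
  F <- rbind(c(1, 2, 3), c(2, 3, 4), c(4, 5, 6), c(7, 8, 9), c(8, 9, 10))
  m <- triangle_mesh(V, F)
  f <- withr::local_tempfile(fileext = ".ply")
  write_mesh(m, f, "ply")
  m2 <- read_mesh(f)
  expect_identical(unname(m2$vertices), unname(m$vertices))
  expect_identical(m2$faces, m$faces)
})

test_that("STL cube collapses duplicated corners to 8 vertices, 12 faces", {
  # closed unit cube as 12 facets
  quads <- list(
    list(c(0,0,0), c(0,1,0), c(1,1,0), c(1,0,0)),  # bottom (normal -z)
    list(c(0,0,1), c(1,0,1), c(1,1,1), c(0,1,1)),  # top
    list(c(0,0,0), c(1,0,0), c(1,0,1), c(0,0,1)),  # front
    list(c(1,0,0), c(1,1,0), c(1,1,1), c(1,0,1)),  # right
    list(c(1,1,0), c(0,1,0), c(0,1,1), c(1,1,1)),  # back
    list(c(0,1,0), c(0,0,0), c(0,0,1), c(0,1,1)))  # left
  V <- NULL; F <- NULL
  for (q in quads) {
    base <- if (is.null(V)) 0L else nrow(V)
    V <- rbind(V, q[[1]], q[[2]], q[[3]], q[[4]])
    F <- rbind(F, base + c(1L, 2L, 3L), base + c(1L, 3L, 4L))
  }
  cube <- triangle_mesh(V, F)
  f <- withr::local_tempfile(fileext = ".stl")
  write_mesh(cube, f, "stl")
  m <- read_mesh(f)
  expect_equal(n_vertices(m), 8L)
  expect_equal(n_faces(m), 12L)
  expect_equal(mesh_area(m), 6, tolerance = 1e-12)
})

test_that("corrupt and empty meshes are rejected with informative errors", {
  f <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 0",
               "property float x", "property float y", "property float z",
               "element face 0",
               "property list uchar int vertex_indices", "end_header"), f)
  expect_error(read_mesh(f), "empty")
  writeLines(c("ply", "format ascii 1.0", "garbage here"), f)
  expect_error(read_mesh(f), "unknown keyword")
  expect_error(read_mesh(tempfile()), "not found")
})

test_that("boundary detection: closed surface, disc ring, lone triangle", {
  sp <- icosphere(1)
  bi <- detect_boundary(sp)
  expect_false(any(bi$boundary_face_flags))
  expect_false(any(bi$boundary_vertex_flags))

  pl <- grid_plane(6)
  bi <- detect_boundary(pl, face_rule = "edge")
  cen <- face_centroids(pl)
  # edge-rule boundary faces all touch the outer rim of the square
  on_rim <- cen[, 1] < 1.2 | cen[, 1] > 8.8 | cen[, 2] < 1.2 | cen[, 2] > 8.8
  expect_true(all(on_rim[bi$boundary_face_flags]))
  expect_true(any(bi$boundary_face_flags))

  tr <- triangle_mesh(diag(3), rbind(c(1, 2, 3)))
  bi <- detect_boundary(tr)
  expect_true(all(bi$boundary_vertex_flags))
  expect_true(all(bi$boundary_face_flags))
})

test_that("alignment flattens a tilted plane and maps the hint to +Y", {
  # plane z = x, i.e. tilted 45 degrees; long axis hint (1, 0, 1)
  g <- expand.grid(x = 0:8, y = 0:8)
  m <- triangle_mesh(cbind(g$x, g$y, g$x), eggscore:::.grid_faces(9, 9))
  al <- align_to_xy(m, long_axis_hint = c(1, 0, 1))
  expect_lt(max(abs(al$vertices[, 3])), 1e-9)
  # the hint (1,0,1) lies in the plane: moving along it must move along +Y
  expect_gt(cor(g$x, al$vertices[, 2]), 0.99)
  expect_equal(colMeans(al$vertices), c(x = 0, y = 0, z = 0), tolerance = 1e-9)
})

test_that("alignment is idempotent and inverts a known rotation", {
  p <- synth_params(grid_resolution = 6, seed = 3)
  s <- make_section(p)
  al1 <- align_to_xy(s$mesh)
  al2 <- align_to_xy(al1)
  expect_equal(al2$vertices, al1$vertices, tolerance = 1e-9)

  set.seed(99)
  R <- random_rotation()
  rot <- triangle_mesh(al1$vertices %*% t(R), al1$faces)
  # realign, telling it where the long axis went
  back <- align_to_xy(rot, long_axis_hint = as.vector(R %*% c(0, 1, 0)))
  rms <- sqrt(mean((back$vertices - al1$vertices)^2))
  expect_lt(rms, 1e-6)
})

test_that("alignment rejects degenerate collinear vertex sets", {
  m <- triangle_mesh(cbind(0:3, 0, 0), rbind(c(1, 2, 3), c(2, 3, 4)))
  expect_error(align_to_xy(m), "collinear")
})

test_that("extract_section selects a disc of the right area", {
  pl <- grid_plane(60, 30)  # 30 x 30 mm plane
  sec <- extract_section(pl, center = c(15, 15, 0), diameter = 10)
  expect_s3_class(sec, "surface_section")
  expect_equal(mesh_area(sec$mesh), pi * 25, tolerance = 0.02 * pi * 25)
  expect_warning(extract_section(pl, center = c(15, 15, 0), diameter = 100),
                 "whole mesh")
  expect_error(extract_section(pl, center = c(200, 0, 0), diameter = 10),
               "outside")
  expect_error(extract_section(pl, center = c(15, 15, 0), diameter = -1),
               "diameter")
})

test_that("surface_section validates zone and diameter", {
  m <- grid_plane(2)
  expect_error(surface_section(m, zone = 7), "zone")
  expect_error(surface_section(m, section_diameter = 0), "section_diameter")
  s <- surface_section(m, zone = 3, section_id = "a")
  expect_equal(s$zone, 3L)
})
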