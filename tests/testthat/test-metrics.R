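# Analytic oracles for the three metrics, and their invariants.

closed_settings <- metric_settings(dne_outlier_fraction = 0,
                                   boundary_discard = "none")

test_that("DNE of a flat plane is zero and of a sphere is 8*pi", {
  expect_lt(dne(grid_plane(12), closed_settings)$total, 1e-8)

  sp <- icosphere(4)  # 5120 faces, closed
  d <- dne(sp, closed_settings)
  expect_equal(d$total, 8 * pi, tolerance = 0.02)
  # scale invariance: e scales as s^-2, A as s^2
  sp3 <- triangle_mesh(sp$vertices * 3, sp$faces)
  d3 <- dne(sp3, closed_settings)
  expect_lt(abs(d3$total - d$total) / d$total, 1e-6)
})

test_that("DNE total is exactly the sum of retained face contributions", {
  s <- make_section(synth_params(grid_resolution = 6, seed = 8))
  d <- dne(s$mesh)
  expect_identical(d$total, sum(d$faces$contribution[d$faces$retained]))
  expect_true(all(d$faces$energy_density[d$faces$retained] >= 0))
  # outlier trim drops the top 0.1% of contributions
  n_ret_full <- sum(dne(s$mesh, metric_settings(dne_outlier_fraction = 0))
                    $faces$retained)
  expect_equal(sum(d$faces$retained), n_ret_full - floor(0.001 * n_ret_full))
})

test_that("slope oracles: horizontal zero, tilted plane exact, hemisphere", {
  expect_equal(slope(grid_plane(10))$mean, 0)
  expect_equal(slope(tilted_plane(30))$mean, 30, tolerance = 1e-6)
  hs <- slope(uv_hemisphere(),
              metric_settings(slope_weighting = "area",
                              boundary_discard = "none"))
  expect_equal(hs$mean, 180 / pi, tolerance = 0.01 * 180 / pi)
})

test_that("slope bounds hold on arbitrary surfaces", {
  s <- make_section(synth_params(grid_resolution = 6, seed = 17,
                                 node_amplitude = 0.6))
  sl <- slope(s$mesh)
  th <- sl$face_slopes[!is.na(sl$face_slopes)]
  expect_true(all(th >= 0 & th <= 90))
  expect_lte(sl$mean, max(th))
})

test_that("bin areas partition retained area and respect the azimuth frame", {
  st <- metric_settings()
  # plane whose normal azimuth is 10 degrees: all area in bin 1
  # (the surface dips along azimuth `az`, so its normal leans toward it)
  g <- expand.grid(x = 0:10, y = 0:10)
  tilt_toward <- function(az_deg, slope_deg = 20) {
    az <- az_deg * pi / 180; sl <- tan(slope_deg * pi / 180)
    z <- -sl * (cos(az) * g$x + sin(az) * g$y)
    triangle_mesh(cbind(g$x, g$y, z), eggscore:::.grid_faces(11, 11))
  }
  ba <- bin_areas(tilt_toward(10), st)
  expect_gt(ba$areas[1], 0)
  expect_equal(sum(ba$areas[-1]), 0)
  ba <- bin_areas(tilt_toward(100), st)
  expect_gt(ba$areas[3], 0)
  expect_equal(sum(ba$areas[-3]), 0)
  # horizontal plane: everything excluded as flat-on
  ba <- bin_areas(grid_plane(6), st)
  expect_equal(sum(ba$areas), 0)
  expect_equal(ba$excluded_area, ba$total_area)
  # conservation on a rough surface
  s <- make_section(synth_params(grid_resolution = 6, seed = 5))
  ba <- bin_areas(s$mesh, st)
  expect_equal(sum(ba$areas) + ba$excluded_area, ba$total_area,
               tolerance = 1e-6 * ba$total_area)
})

test_that("orientation oracles: V-grooves +/-100, cone 0, antisymmetry", {
  vg <- make_section(synth_params(node_count = 0, noise_amplitude = 0,
                                  ridge_azimuth = 90, seed = 7))$mesh
  expect_identical(orientation(vg), 100)
  expect_identical(orientation(rotate_mesh_z(vg, 90)), -100)
  expect_equal(orientation(cone_mesh()), 0, tolerance = 1e-9)

  # antisymmetry on a generic rough surface with no flat-on faces
  s <- make_section(synth_params(grid_resolution = 6, seed = 31))$mesh
  om <- orientation(s)
  expect_equal(orientation(rotate_mesh_z(s, 90)), -om, tolerance = 1e-6)
  expect_true(om >= -100 && om <= 100)
})

test_that("orientation respects a non-default long-axis azimuth", {
  vg <- make_section(synth_params(node_count = 0, noise_amplitude = 0,
                                  ridge_azimuth = 0, seed = 7))$mesh
  # crests along +X: against the default +Y long axis...
  expect_identical(orientation(vg), -100)
  # ...but along a long axis declared at azimuth 0
  expect_identical(orientation(vg, metric_settings(long_axis_azimuth = 0)), 100)
})

test_that("orientation is undefined on a flat surface", {
  expect_error(orientation(grid_plane(6)), "undefined")
})

test_that("score assembles the metrics and survives metric failure", {
  s <- make_section(synth_params(grid_resolution = 6, seed = 9,
                                 ridge_azimuth = 90))
  rec <- score(s)
  expect_named(rec, c("specimen_id", "egg_id", "zone", "section_id",
                      "complexity", "relief", "orientation"))
  expect_gt(rec$orientation, 0)  # long-axis ridges by construction
  expect_gt(rec$complexity, 0)

  flat <- make_section(synth_params(node_count = 0, ridge_count = 0,
                                    noise_amplitude = 0))
  expect_warning(fr <- score(flat), flat$section_id)
  expect_equal(fr$complexity, 0, tolerance = 1e-8)
  expect_equal(fr$relief, 0, tolerance = 1e-8)
  expect_true(is.na(fr$orientation))
})

test_that("score CSV round trip preserves records and echoes settings", {
  secs <- list(make_section(synth_params(grid_resolution = 6, seed = 1),
                            egg_id = "e1", section_id = "a"),
               make_section(synth_params(grid_resolution = 6, seed = 2),
                            egg_id = "e1", section_id = "b"))
  recs <- score_batch(secs)
  expect_equal(nrow(recs), 2L)
  f <- withr::local_tempfile(fileext = ".csv")
  write_score_csv(recs, f)
  expect_true(any(grepl("^# boundary_discard", readLines(f))))
  back <- read_score_csv(f)
  expect_equal(back$complexity, recs$complexity, tolerance = 1e-9)
  expect_equal(back$section_id, recs$section_id)
})

test_that("metric monotonicity ladders on synthetic surfaces", {
  # increasing ridge dominance -> |orientation| strictly increasing
  ridge_amp <- c(0.02, 0.1, 0.25, 0.5)
  om <- vapply(ridge_amp, function(a) {
    m <- make_section(synth_params(grid_resolution = 6, seed = 40,
                                   node_amplitude = 0.2, ridge_amplitude = a,
                                   noise_amplitude = 0.01))$mesh
    abs(orientation(m))
  }, 0)
  expect_equal(spearman_rho(seq_along(om), om), 1)

  # increasing amplitude -> mean slope increasing
  scale_amp <- c(0.5, 1, 1.5, 2)
  sl <- vapply(scale_amp, function(s) {
    m <- make_section(synth_params(grid_resolution = 6, seed = 41,
                                   node_amplitude = 0.2 * s,
                                   ridge_amplitude = 0.2 * s))$mesh
    slope(m)$mean
  }, 0)
  expect_equal(spearman_rho(seq_along(sl), sl), 1)

  # increasing node density -> DNE increasing
  dens <- c(5, 20, 50, 100)
  dn <- vapply(dens, function(k) {
    m <- make_section(synth_params(grid_resolution = 6, seed = 42,
                                   node_count = k))$mesh
    dne(m)$total
  }, 0)
  expect_equal(spearman_rho(seq_along(dn), dn), 1)
})
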