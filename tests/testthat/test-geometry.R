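# Source spaces, sensor arrays, the single-sphere forward model and patch
# growth.

test_that("icosphere subdivision gives the standard vertex/face counts", {
  ss0 <- build_sphere_source_space(0, 0.08)
  expect_equal(nrow(ss0$vertices), 12)
  expect_equal(nrow(ss0$triangles), 20)
  ss3 <- build_sphere_source_space(3, 0.08)
  expect_equal(nrow(ss3$vertices), 10 * 4^3 + 2)
})

test_that("icosphere approximates the analytic sphere area within 3%", {
  ss <- build_sphere_source_space(2, 0.08)
  expect_lt(abs(ss$total_area - 4 * pi * 0.08^2) / (4 * pi * 0.08^2), 0.03)
  # vertex areas positive, sum to mesh area, and normals are unit radial
  expect_true(all(ss$vertex_area > 0))
  expect_equal(sum(ss$vertex_area), ss$total_area, tolerance = 1e-9)
  expect_equal(sqrt(rowSums(ss$normals^2)), rep(1, nrow(ss$normals)),
               tolerance = 1e-9)
  outward <- rowSums(ss$normals * ss$vertices)
  expect_true(all(outward > 0))
})

test_that("OBJ meshes round-trip and malformed files are reported", {
  ss <- build_sphere_source_space(1, 0.08)
  f <- tempfile(fileext = ".obj")
  write_mesh_obj(ss, f)
  back <- load_mesh(f)
  expect_equal(back$vertices, ss$vertices, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(nrow(back$triangles), nrow(ss$triangles))

  tet <- tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "v 0 0 1",
               "f 1 2 3", "f 1 2 4", "f 1 3 4", "f 2 3 4"), tet)
  ts <- load_mesh(tet)
  expect_equal(nrow(ts$vertices), 4)
  expect_equal(nrow(ts$triangles), 4)

  quad <- tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 1 1 0", "v 0 1 0", "f 1 2 3 4"),
             quad)
  expect_error(load_mesh(quad), "non-triangular")

  bad <- tempfile(fileext = ".obj")
  writeLines(c("v 0 0", "f 1 2 3"), bad)
  expect_error(load_mesh(bad), "line 1")
})

test_that("FreeSurfer ASCII surfaces parse with 0-based faces", {
  f <- tempfile()
  writeLines(c("#!ascii version of a surface", "4 4",
               "0 0 0 0", "1 0 0 0", "0 1 0 0", "0 0 1 0",
               "0 1 2 0", "0 1 3 0", "0 2 3 0", "1 2 3 0"), f)
  ss <- load_mesh(f, format = "fsascii")
  expect_equal(nrow(ss$vertices), 4)
  expect_equal(sort(unique(as.vector(ss$triangles))), 1:4)
})

test_that("sensor caps have the requested layout", {
  one <- build_sensor_cap(1, 0.12, 1.0)
  expect_equal(nrow(one$positions), 1)
  expect_equal(sqrt(sum(one$positions^2)), 0.12, tolerance = 1e-12)
  expect_equal(one$positions / 0.12, one$orientations, tolerance = 1e-12,
               ignore_attr = TRUE)

  ctf <- build_sensor_cap(275, 0.12, 0.6)
  expect_equal(nrow(ctf$positions), 275)
  expect_gt(min(stats::dist(ctf$positions)), 0)

  half <- build_sensor_cap(100, 0.12, 0.5)
  expect_true(all(half$positions[, 3] >= 0))

  expect_error(build_sensor_cap(10, 0.05, 0.5), "geometry error")
})

test_that("radial dipoles are silent, tangential dipoles are not", {
  sa <- build_sensor_cap(80, 0.12, 0.6)
  set.seed(7)
  max_radial <- 0
  max_tangential <- 0
  for (i in 1:100) {
    pos <- stats::rnorm(3)
    pos <- pos / sqrt(sum(pos^2)) * stats::runif(1, 0.02, 0.085)
    radial <- pos / sqrt(sum(pos^2))
    B_rad <- mnecoh:::sarvas_field(pos, radial, sa$positions)
    tang <- stats::rnorm(3)
    tang <- tang - sum(tang * radial) * radial
    tang <- tang / sqrt(sum(tang^2))
    B_tan <- mnecoh:::sarvas_field(pos, tang, sa$positions)
    max_radial <- max(max_radial, max(abs(B_rad)))
    max_tangential <- max(max_tangential, max(abs(B_tan)))
  }
  expect_lt(max_radial, 1e-10 * max_tangential)
})

test_that("Sarvas field matches the free-space radial-component identity", {
  # volume currents in a spherical conductor contribute nothing to the
  # radial field component, so for radial sensors the gain must equal the
  # primary-current (Biot-Savart) dipole field projected radially --
  # an independent closed form
  sa <- build_sensor_cap(60, 0.13, 0.7)
  rad <- sa$positions / sqrt(rowSums(sa$positions^2))
  set.seed(11)
  for (i in 1:10) {
    r0 <- stats::rnorm(3)
    r0 <- r0 / sqrt(sum(r0^2)) * stats::runif(1, 0.03, 0.08)
    q <- stats::rnorm(3)
    B <- mnecoh:::sarvas_field(r0, q, sa$positions)
    br <- rowSums(B * rad)
    a_vec <- sweep(sa$positions, 2, r0)
    qxa <- cbind(q[2] * a_vec[, 3] - q[3] * a_vec[, 2],
                 q[3] * a_vec[, 1] - q[1] * a_vec[, 3],
                 q[1] * a_vec[, 2] - q[2] * a_vec[, 1])
    br_free <- 1e-7 * rowSums(qxa * rad) / rowSums(a_vec^2)^1.5
    expect_lt(rel_diff(br, br_free), 1e-12)
  }
})

test_that("lead field is linear and scales as k^-2 under geometric scaling", {
  geom <- tiny_geometry()
  pos <- c(0.02, 0.01, 0.05)
  q <- c(0, 1, 0)
  sa <- geom$sa
  expect_equal(mnecoh:::sarvas_field(pos, 2 * q, sa$positions),
               2 * mnecoh:::sarvas_field(pos, q, sa$positions))
  B1 <- mnecoh:::sarvas_field(pos, q, sa$positions)
  B2 <- mnecoh:::sarvas_field(2 * pos, q, 2 * sa$positions)
  expect_equal(B2, B1 / 4, tolerance = 1e-12)
})

test_that("lead-field preconditions are enforced", {
  ss <- build_sphere_source_space(1, 0.08)
  sa <- build_sensor_cap(10, 0.12, 0.5)
  expect_error(compute_lead_field(ss, sa, conductor_radius = 0.05),
               "inside the conductor")
  sa_in <- sa
  sa_in$positions <- sa_in$positions * 0.5
  expect_error(compute_lead_field(ss, sa_in, conductor_radius = 0.089),
               "outside the conductor")
})

test_that("gradiometer gains differ from magnetometer gains", {
  ss <- build_cortical_source_space(1, 0.08)
  mag <- build_sensor_cap(20, 0.12, 0.5)
  grd <- build_sensor_cap(20, 0.12, 0.5, sensor_type = "axial_gradiometer",
                          baseline = 0.05)
  g1 <- compute_lead_field(ss, mag)$gain
  g2 <- compute_lead_field(ss, grd)$gain
  expect_true(all(is.finite(g2)))
  # the far coil removes part of the field, so gains shrink but stay
  # strongly correlated
  expect_gt(stats::cor(as.vector(g1), as.vector(g2)), 0.9)
  expect_lt(max(abs(g2)), max(abs(g1)))
})

test_that("grow_patch accumulates exactly the minimal covering set", {
  # icosahedron: all 12 vertices are equivalent, so per-vertex area is
  # total/12; pick the radius that makes it exactly 0.5 cm^2
  unit <- build_sphere_source_space(0, 1)
  r <- sqrt(12 * 0.5e-4 / unit$total_area)
  ss <- build_sphere_source_space(0, r)
  expect_equal(ss$vertex_area, rep(0.5e-4, 12), tolerance = 1e-12)
  p <- grow_patch(ss, 5, 2)
  expect_equal(length(p$member_vertices), 4)
  expect_equal(p$achieved_area, 2, tolerance = 1e-9)

  expect_equal(grow_patch(ss, 5, 0)$member_vertices, 5)
  all_v <- grow_patch(ss, 5, ss$total_area * 1e4)
  expect_equal(sort(all_v$member_vertices), 1:12)
  expect_error(grow_patch(ss, 5, ss$total_area * 1e4 + 1),
               "insufficient mesh")
})

test_that("grow_patch is monotone in target area and minimally covering", {
  ss <- tiny_geometry()$ss
  seeds <- c(3, 40, 101)
  for (seed in seeds) {
    prev <- integer(0)
    for (area in c(0, 1, 2, 4, 8)) {
      p <- grow_patch(ss, seed, area)
      expect_true(all(prev %in% p$member_vertices))
      expect_true(seed %in% p$member_vertices)
      if (area > 0) {
        expect_gte(p$achieved_area, area)
        last <- utils::tail(p$member_vertices, 1)
        expect_lt(p$achieved_area - ss$vertex_area[last] * 1e4, area)
      }
      prev <- p$member_vertices
    }
  }
})
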