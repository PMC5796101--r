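test_that("nearest_hit finds analytic intersections and handles degeneracies", {
  tri <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                       rbind(c(1, 2, 3)), 1L, "leaf")
  cen <- c(1 / 3, 1 / 3, 0)
  h <- nearest_hit(tri, cen + c(0, 0, 5), c(0, 0, -1))
  expect_identical(h$triangle, 1L)
  expect_equal(h$distance, 5, tolerance = 1e-12)

  # ray parallel to and coplanar with the triangle: no hit
  h <- nearest_hit(tri, c(-1, 0.25, 0), c(1, 0, 0))
  expect_true(is.na(h$triangle))

  # ray pointing away: no hit
  h <- nearest_hit(tri, cen + c(0, 0, 5), c(0, 0, 1))
  expect_true(is.na(h$triangle))
})

test_that("BVH-accelerated intersection is identical to brute force", {
  mesh <- random_mesh(500, seed = 4)
  set.seed(9)
  n <- 1000
  origins <- matrix(runif(3 * n, -2, 2), ncol = 3)
  dirs <- matrix(rnorm(3 * n), ncol = 3)
  a <- nearest_hit(mesh, origins, dirs, method = "bvh")
  b <- nearest_hit(mesh, origins, dirs, method = "brute")
  expect_identical(a$triangle, b$triangle)
  expect_identical(a$distance, b$distance)
  expect_true(any(!is.na(a$triangle)))   # scene actually gets hit
})

test_that("beam interception follows the cosine law with exact ledger closure", {
  mats <- black()
  # horizontal black leaf under a vertical beam: full interception
  m <- trace_scene(square_leaf(), mats, vertical_beam(1000),
                   n_rays = 1e6, seed = 7)
  expect_equal(m$elements$ppfd, 1000, tolerance = 0.005)
  expect_lt(abs(m$elements$ppfd - 1000), 3 * m$elements$se + 1e-9)

  # tilted 60 degrees from horizontal: half the flux density
  m60 <- trace_scene(square_leaf(tilt_deg = 60), mats, vertical_beam(1000),
                     n_rays = 1e6, seed = 7)
  expect_equal(m60$elements$ppfd, 500, tolerance = 0.005)

  for (mm in list(m, m60)) {
    closure <- with(mm$ledger, emitted - absorbed - escaped - truncated)
    expect_lt(abs(closure), 1e-9 * mm$ledger$emitted)
  }
})

test_that("scattering materials conserve energy and black scenes ignore max_impacts", {
  mats <- black()
  mats$leaf <- optical_material(0.3, 0.25)
  scene <- mesh_bind(square_leaf(side = 0.4, center = c(0, 0, 0.5)),
                     square_leaf(side = 1, center = c(0, 0, 0), id = 2L,
                                 kind = "floor"))
  m <- trace_scene(scene, mats, vertical_beam(500), n_rays = 2e5, seed = 3,
                   max_impacts = 10)
  expect_gt(m$ledger$truncated, -1e-12)
  closure <- with(m$ledger, emitted - absorbed - escaped - truncated)
  expect_lt(abs(closure), 1e-9 * m$ledger$emitted)
  # scattered light reaches the floor beyond the beam shadow: the floor
  # absorbs more than the unshaded beam fraction alone
  expect_gt(m$elements$absorbed_flux[m$elements$kind == "floor"], 0)

  # with rho = tau = 0 there are no scattering paths: max_impacts is inert
  m1 <- trace_scene(scene, black(), vertical_beam(500), n_rays = 1e5,
                    seed = 5, max_impacts = 1)
  m10 <- trace_scene(scene, black(), vertical_beam(500), n_rays = 1e5,
                     seed = 5, max_impacts = 10)
  expect_identical(m1$elements$incident_flux, m10$elements$incident_flux)
})

test_that("a random black canopy at LAI 1 transmits the Beer-Lambert gap fraction", {
  cano <- random_black_canopy(lai = 1, seed = 8)
  mats <- black()
  m <- trace_scene(cano$mesh, mats, vertical_beam(1000), n_rays = 1e6,
                   seed = 2)
  floor_ppfd <- m$elements$ppfd[m$elements$kind == "floor"]
  gap <- floor_ppfd / 1000
  expect_equal(gap, exp(-1), tolerance = 0.01 / exp(-1))
  # the finite-leaf closed form agrees with exp(-LAI) at this leaf size
  expect_equal(cano$expected_gap, exp(-1), tolerance = 0.002)
})

test_that("Monte Carlo standard errors scale as 1/sqrt(n_rays)", {
  scene <- square_leaf(side = 0.3)
  mats <- black()
  ns <- c(1e4, 1e5, 1e6)
  ses <- vapply(ns, function(n) {
    trace_scene(scene, mats, vertical_beam(1000), n_rays = n, seed = 11,
                n_batches = 100)$elements$se
  }, 0)
  slope <- coef(lm(log(ses) ~ log(ns)))[2]
  expect_equal(unname(slope), -0.5, tolerance = 0.2)
})

test_that("per-leaf PPFD is invariant under rigid rotation of scene plus beam", {
  p <- build_plant(plant_config(n_leaves = 15, rng_seed = 6))
  mats <- default_materials()
  ill0 <- vertical_beam(800)
  m0 <- trace_scene(p$mesh, mats, ill0, n_rays = 4e5, seed = 13)
  a <- 50 * pi / 180   # rotate about x by 50 degrees
  rot <- matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
  mesh_r <- transform_mesh(p$mesh, rotation = rot)
  ill_r <- scene_illumination(beam = list(
    direction = as.vector(rot %*% c(0, 0, -1)), ppfd_normal = 800))
  m_r <- trace_scene(mesh_r, mats, ill_r, n_rays = 4e5, seed = 13)
  t0 <- dplyr::filter(m0$elements, .data$kind == "leaf")
  tr <- dplyr::filter(m_r$elements, .data$kind == "leaf")
  # agreement within Monte Carlo error (4 joint standard errors)
  tol <- 4 * sqrt(t0$se^2 + tr$se^2) + 1e-9
  expect_true(all(abs(t0$ppfd - tr$ppfd) < pmax(tol, 0.02 * t0$ppfd + 1)))
})

test_that("leaf tables join by id and reject unknown leaves", {
  p <- build_plant(plant_config(n_leaves = 8, rng_seed = 2))
  mats <- default_materials()
  m <- trace_scene(p$mesh, mats, vertical_beam(600), n_rays = 2e5, seed = 1)
  tab <- leaf_ppfd_table(m, p$leaves)
  expect_identical(nrow(tab), 8L)
  expect_identical(tab$leaf_id, p$leaves$leaf_id)
  expect_true(all(tab$ppfd >= 0))

  empty <- leaf_ppfd_table(m, p$leaves[0, ])
  expect_identical(nrow(empty), 0L)
  bogus <- dplyr::mutate(p$leaves, leaf_id = leaf_id + 500L)
  expect_error(leaf_ppfd_table(m, bogus), "not present")
})

test_that("lamp far field approaches the Lambertian point-source law", {
  # small sensor on the lamp axis at distance d: E = flux / (pi d^2)
  sensor <- square_leaf(side = 0.1, kind = "sensor")
  ill <- lamp_illumination(center = c(0, 0, 2), total_flux = 1000,
                           radius = 0.002)
  m <- trace_scene(sensor, black(), ill, n_rays = 4e6, seed = 21)
  analytic <- 1000 / (pi * 2^2)
  expect_equal(m$elements$ppfd, analytic, tolerance = 0.05)
  # zero flux: all-zero map
  ill0 <- lamp_illumination(center = c(0, 0, 2), total_flux = 0)
  m0 <- trace_scene(sensor, black(), ill0, n_rays = 1e4, seed = 1)
  expect_identical(m0$elements$incident_flux, 0)
})

test_that("lamp calibration is linear and errors on dark sensors", {
  p <- build_plant(plant_config(n_leaves = 10, rng_seed = 4))
  sc <- build_scene(p)
  mats <- default_materials()
  zt <- sc$sensor_positions["top", 3]
  ill <- lamp_illumination(center = c(0, 0, zt + 1.5), total_flux = 500)
  cal <- calibrate_lamp(sc$mesh, mats, ill, 833.1, n_rays = 3e5, seed = 2)
  # retracing with the calibrated flux and the same seed reproduces the
  # target exactly (transport linearity)
  m <- trace_scene(sc$mesh, mats, cal$illumination, n_rays = 3e5, seed = 2)
  top <- sensor_readings(m)
  expect_equal(top$ppfd[top$label == "sensor_top"], 833.1,
               tolerance = 1e-9)
  # doubling the flux doubles every tally
  ill2 <- cal$illumination
  ill2$lamp$total_flux <- 2 * cal$total_flux
  m2 <- trace_scene(sc$mesh, mats, ill2, n_rays = 3e5, seed = 2)
  expect_equal(m2$elements$incident_flux, 2 * m$elements$incident_flux,
               tolerance = 1e-12)
  # a target of zero yields zero flux
  cal0 <- calibrate_lamp(sc$mesh, mats, ill, 0, n_rays = 1e4, seed = 2)
  expect_identical(cal0$total_flux, 0)
  # sensor that cannot see the lamp: calibration refuses
  expect_error(
    calibrate_lamp(sc$mesh, mats, ill, 100, sensor_label = "sensor_none",
                   n_rays = 1e4, seed = 2),
    "not found")
})

test_that("traces are bitwise deterministic and fail cleanly without materials", {
  p <- build_plant(plant_config(n_leaves = 6, rng_seed = 9))
  mats <- default_materials()
  m1 <- trace_scene(p$mesh, mats, vertical_beam(300), n_rays = 1e5, seed = 17)
  m2 <- trace_scene(p$mesh, mats, vertical_beam(300), n_rays = 1e5, seed = 17)
  expect_identical(m1$elements$incident_flux, m2$elements$incident_flux)
  expect_identical(m1$ledger, m2$ledger)
  expect_error(trace_scene(p$mesh, list(leaf = optical_material(0, 0)),
                           vertical_beam(300), n_rays = 1e4),
               "no material")
})

test_that("per-leaf detector grids tally at the requested pitch", {
  leaf <- square_leaf(side = 0.2)
  m <- trace_scene(leaf, black(), vertical_beam(1000), n_rays = 2e5,
                   seed = 3, patch_grids = TRUE, detector_pitch = 0.05)
  expect_length(m$patches, 1)
  g <- m$patches[[1]]
  expect_identical(dim(g), c(4L, 4L))   # 0.2 m / 0.05 m
  # grid totals match the whole-leaf tally
  expect_equal(sum(g) * 0.05^2, m$elements$incident_flux, tolerance = 1e-9)
  # interior cells see the uniform beam PPFD
  expect_equal(mean(g), 1000, tolerance = 0.05)
})
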