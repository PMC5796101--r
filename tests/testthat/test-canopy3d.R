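test_that("allometric leaf area matches direct evaluation and rejects out-of-range dims", {
  expect_equal(leaf_area_from_dimensions(20, 5), 71.047)
  expect_equal(leaf_area_from_dimensions(10, 4),
               -14.623 + 32.296 + 8.5 + 7.232)
  # vectorised
  expect_equal(leaf_area_from_dimensions(c(20, 10), c(5, 4)),
               c(71.047, 33.405))
  # tiny dimensions drive the regression negative: domain error, not a clamp
  expect_error(leaf_area_from_dimensions(1, 0.5), "calibration range")
  expect_error(leaf_area_from_dimensions(-1, 5), "positive")
})

test_that("phyllotaxis azimuth chains accumulate divergence angles mod 360", {
  expect_equal(phyllotaxis_azimuths(c(90, 90, 90, 90), 0),
               c(0, 90, 180, 270, 0))
  # reference Irwin divergence measurements average to 137.6 degrees
  expect_equal(round(mean(irwin_divergence_angles()), 1), 137.6)
  # near-golden-angle spirals avoid azimuthal overlap (brute-force pairwise)
  az <- phyllotaxis_azimuths(rep(137.6, 13), 0)
  expect_length(az, 14)
  d <- abs(outer(az, az, "-")) %% 360
  d <- pmin(d, 360 - d)
  expect_true(all(d[upper.tri(d)] > 5))
  expect_error(phyllotaxis_azimuths(numeric(0)))
})

test_that("built plants are deterministic and mesh areas equal allometric areas", {
  cfg <- plant_config(n_leaves = 30, rng_seed = 11)
  p1 <- build_plant(cfg)
  p2 <- build_plant(cfg)
  expect_identical(p1$mesh$vertices, p2$mesh$vertices)
  expect_identical(p1$leaves, p2$leaves)

  # per-leaf triangulated area vs allometric area, several random configs
  for (seed in c(1, 7, 23, 101)) {
    p <- build_plant(plant_config(n_leaves = 20, rng_seed = seed))
    a <- mesh_element_areas(p$mesh)
    leaf_a <- a$area[a$kind == "leaf"][order(a$element_id[a$kind == "leaf"])]
    expect_lt(max(abs(leaf_a * 1e4 - p$leaves$allometric_area) /
                    p$leaves$allometric_area), 0.01)
    # every leaf triangulated with >= 8 triangles
    leaf_tris <- table(p$mesh$element_id[p$mesh$element_id %in%
                                           p$leaves$leaf_id])
    expect_true(all(leaf_tris >= 8))
  }
})

test_that("rescaling to a target total area is exact and fraction-preserving", {
  cfg0 <- plant_config(n_leaves = 40, rng_seed = 5)
  cfg1 <- plant_config(n_leaves = 40, rng_seed = 5,
                       target_total_leaf_area = 4194.84)
  p0 <- build_plant(cfg0)
  p1 <- build_plant(cfg1)
  expect_lt(abs(sum(p1$leaves$allometric_area) - 4194.84) / 4194.84, 0.005)
  # each leaf's share of the total is preserved through the rescale
  f0 <- p0$leaves$allometric_area / sum(p0$leaves$allometric_area)
  f1 <- p1$leaves$allometric_area / sum(p1$leaves$allometric_area)
  expect_lt(max(abs(f1 - f0) / f0), 1e-6)
  # records stay allometrically consistent after the per-leaf re-solve
  expect_equal(leaf_area_from_dimensions(p1$leaves$length, p1$leaves$width),
               p1$leaves$allometric_area, tolerance = 1e-9)
})

test_that("single-leaf configs and chamber footprint behave as specified", {
  p <- build_plant(plant_config(n_leaves = 1, rng_seed = 3))
  expect_identical(sum(p$mesh$elements$kind == "leaf"), 1L)
  expect_true(all(c("stem", "pot") %in% p$mesh$elements$kind))

  # all leaf centroids inside the 1 x 1 m chamber footprint (default config)
  p <- test_plant()
  for (lid in p$leaves$leaf_id) {
    sel <- p$mesh$element_id == lid
    vids <- unique(as.vector(p$mesh$triangles[sel, ]))
    cen <- colMeans(p$mesh$vertices[vids, , drop = FALSE])
    expect_true(all(abs(cen[1:2]) <= 0.5))
  }
})

test_that("leaf records satisfy their invariants", {
  p <- test_plant()
  lv <- p$leaves
  expect_true(all(lv$allometric_area > 0))
  expect_true(all(lv$length > 0 & lv$width > 0))
  expect_true(all(lv$azimuth >= 0 & lv$azimuth < 360))
  expect_true(all(lv$petiole_length > 0))
  # every leaf element id maps to exactly one record
  leaf_ids <- p$mesh$elements$element_id[p$mesh$elements$kind == "leaf"]
  expect_setequal(leaf_ids, lv$leaf_id)
})

test_that("OBJ and PLY round trips preserve geometry and element structure", {
  p <- build_plant(plant_config(n_leaves = 5, rng_seed = 2))
  f <- withr::local_tempfile(fileext = ".obj")
  write_obj(p$mesh, f)
  m2 <- read_obj(f)
  expect_equal(m2$vertices, unname(p$mesh$vertices), tolerance = 1e-7)
  expect_identical(unname(m2$triangles), unname(p$mesh$triangles))
  expect_identical(m2$element_id, p$mesh$element_id)
  expect_identical(m2$elements$kind, p$mesh$elements$kind)

  fply <- withr::local_tempfile(fileext = ".ply")
  write_ply(p$mesh, fply)
  lines <- readLines(fply)
  expect_identical(lines[1], "ply")
  expect_identical(sum(grepl("^3 ", lines)), nrow(p$mesh$triangles))

  fcsv <- withr::local_tempfile(fileext = ".csv")
  write_leaf_csv(p, fcsv)
  back <- readr::read_csv(fcsv, show_col_types = FALSE)
  expect_equal(back$allometric_area, p$leaves$allometric_area)
})

test_that("invalid plant configurations are rejected", {
  expect_error(plant_config(n_leaves = 0))
  expect_error(plant_config(leaf_length_range = c(5, 5)), "non-degenerate")
  expect_error(plant_config(leaf_length_range = c(-1, 5)))
  # dimensions that violate the allometric model abort the build
  expect_error(
    build_plant(plant_config(n_leaves = 5,
                             leaf_length_range = c(0.5, 1),
                             leaf_width_range = c(0.1, 0.3))),
    "calibration range")
})
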