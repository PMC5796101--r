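# small scene builders shared across tests

# horizontal square leaf of side `side`, centred at `center`, optionally
# rotated about the x-axis by `tilt_deg`
square_leaf <- function(side = 0.2, center = c(0, 0, 0), tilt_deg = 0,
                        id = 1L, kind = "leaf") {
  s <- side / 2
  v <- rbind(c(-s, -s, 0), c(s, -s, 0), c(s, s, 0), c(-s, s, 0))
  if (tilt_deg != 0) {
    a <- tilt_deg * pi / 180
    rot <- matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
    v <- v %*% t(rot)
  }
  v <- sweep(v, 2, -center)
  triangle_mesh(v, rbind(c(1, 2, 3), c(1, 3, 4)), c(id, id),
                c(kind, kind))
}

black <- function() list(leaf = optical_material(0, 0),
                         floor = optical_material(0, 0),
                         sensor = optical_material(0, 0),
                         stem = optical_material(0, 0),
                         pot = optical_material(0, 0),
                         wall = optical_material(0, 0))

vertical_beam <- function(ppfd = 1000) {
  scene_illumination(beam = list(direction = c(0, 0, -1),
                                 ppfd_normal = ppfd))
}

# randomized black-leaf canopy over a unit floor: N small horizontal squares
# with centres sampled from a region enlarged by one leaf width so the floor
# sees a spatially stationary leaf field (no edge bias); N set so the
# one-sided leaf area per unit ground area (LAI) is as requested
random_black_canopy <- function(lai = 1, leaf_side = 0.04, seed = 1) {
  set.seed(seed)
  a <- leaf_side^2
  half_enl <- 0.5 + leaf_side
  area_enl <- (2 * half_enl)^2
  n <- round(lai * area_enl / a)
  parts <- list()
  # floor: element 9000, exactly 1 x 1 centred at origin
  parts[[1]] <- square_leaf(side = 1, center = c(0, 0, 0), id = 9000L,
                            kind = "floor")
  for (i in seq_len(n)) {
    cx <- runif(1, -half_enl, half_enl)
    cy <- runif(1, -half_enl, half_enl)
    cz <- runif(1, 0.1, 1.1)
    parts[[i + 1]] <- square_leaf(side = leaf_side, center = c(cx, cy, cz),
                                  id = i)
  }
  list(mesh = do.call(mesh_bind, parts), n_leaves = n,
       # exact gap probability for this finite-leaf stationary field
       expected_gap = (1 - a / area_enl)^n)
}

# random triangle soup for intersection oracle tests
random_mesh <- function(n_tri = 500, seed = 1) {
  set.seed(seed)
  v0 <- matrix(runif(3 * n_tri, -1, 1), ncol = 3)
  v1 <- v0 + matrix(runif(3 * n_tri, -0.2, 0.2), ncol = 3)
  v2 <- v0 + matrix(runif(3 * n_tri, -0.2, 0.2), ncol = 3)
  verts <- do.call(rbind, lapply(seq_len(n_tri), function(i) {
    rbind(v0[i, ], v1[i, ], v2[i, ])
  }))
  tris <- matrix(seq_len(3 * n_tri), ncol = 3, byrow = TRUE)
  triangle_mesh(verts, tris, seq_len(n_tri), rep("leaf", n_tri))
}

# small default plant reused by several tests (cached per session)
test_plant <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- build_plant(plant_config(target_total_leaf_area = 4194.84))
    }
    cache
  }
})
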