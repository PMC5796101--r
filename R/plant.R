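#' Leaf area from length and width (allometric model)
#'
#' Non-destructive leaf-area estimate for Irwin mango from blade length and
#' maximum width:
#' `LA = -14.623 + 8.074 W + 0.085 L^2 + 0.452 W^2` (area in cm^2,
#' dimensions in cm).  The regression is only valid inside its calibration
#' range; dimension pairs for which it returns a non-positive area are
#' rejected rather than clamped, because silently clamping would corrupt
#' area-weighted canopy integration downstream.
#'
#' @param length blade length, cm (vectorised).
#' @param width blade maximum width, cm (vectorised).
#' @return Leaf area in cm^2.
#' @examples
#' leaf_area_from_dimensions(20, 5)   # 71.047
#' @export
leaf_area_from_dimensions <- function(length, width) {
  if (any(length <= 0) || any(width <= 0)) {
    stop("leaf length and width must be positive", call. = FALSE)
  }
  area <- allometry_raw(length, width)
  if (any(area <= 0)) {
    stop("allometric leaf area <= 0: dimensions outside the model's ",
         "calibration range", call. = FALSE)
  }
  area
}

allometry_raw <- function(length, width) {
  -14.623 + 8.074 * width + 0.085 * length^2 + 0.452 * width^2
}

#' Reference divergence angles for a two-year-old Irwin mango
#'
#' Azimuthal angles (degrees) between successive leaves along the stem,
#' measured on a vase-trained two-year-old Irwin mango; their mean is the
#' plant's phyllotactic divergence angle (137.6 degrees, close to the golden
#' angle).
#'
#' @return Numeric vector of 11 angles in degrees.
#' @export
irwin_divergence_angles <- function() {
  c(151.5, 133.2, 141.5, 157.6, 129.9, 122.1,
    138.0, 138.8, 124.4, 150.9, 125.9)
}

#' Leaf azimuths from a divergence-angle sequence
#'
#' Starting from `start_azimuth`, each successive leaf is rotated by the next
#' divergence angle: `azimuth[k] = (azimuth[k-1] + angle[k]) mod 360`.  The
#' output has one more entry than the input (the start plus one azimuth per
#' divergence step).
#'
#' @param divergence_angles numeric vector of divergence angles, degrees.
#' @param start_azimuth azimuth of the first leaf, degrees.
#' @return Numeric vector of azimuths in `[0, 360)`, length
#'   `length(divergence_angles) + 1`.
#' @export
phyllotaxis_azimuths <- function(divergence_angles, start_azimuth = 0) {
  stopifnot(length(divergence_angles) >= 1)
  cumsum(c(start_azimuth, divergence_angles)) %% 360
}

#' Plant construction parameters
#'
#' Describes the procedural canopy: leaf count and dimension ranges, the
#' phyllotactic divergence (a fixed sequence of angles, or a mean/sd pair to
#' sample from), leaf inclination, and the Y-branch skeleton.  Defaults
#' emulate a two-year-old vase-trained Irwin mango: about 0.42 m^2 of
#' one-sided leaf area on a main stem that splits into two then four branches,
#' with leaves clustered in flush-like whorls near branch tips (as mango
#' leaves grow) so the canopy forms a dense crown shell with a strongly shaded
#' interior.
#'
#' @param n_leaves number of leaves (>= 1).
#' @param divergence_angles either a numeric vector of angles (degrees) used
#'   cyclically, or a list `list(mean =, sd =)` sampled per leaf.  Default:
#'   mean 137.6, sd 13.38 (the reference Irwin measurements,
#'   [irwin_divergence_angles()]).
#' @param leaf_length_range,leaf_width_range,petiole_length_range uniform
#'   sampling ranges, cm.
#' @param inclination_range leaf inclination from horizontal, degrees
#'   (negative = drooping).
#' @param branch_levels number of Y-split levels above the main stem.
#' @param branch_lengths metres; length `branch_levels + 1` (stem first).
#' @param branch_diameters metres; same length as `branch_lengths`.
#' @param branch_tilts degrees from vertical per level (length
#'   `branch_levels`).
#' @param leaf_zone fraction of each branch segment (measured from its tip)
#'   that carries leaves; small values cluster leaves into tip whorls.
#' @param target_total_leaf_area optional cm^2; leaf areas are uniformly
#'   rescaled (and dimensions re-solved through the allometric model) so the
#'   summed allometric area matches this target.
#' @param rng_seed integer seed; all stochastic draws for a build flow from
#'   this one seed.
#' @return A validated list of class `plant_config`.
#' @export
plant_config <- function(n_leaves = 80,
                         divergence_angles = list(mean = 137.6, sd = 13.38),
                         leaf_length_range = c(15, 22),
                         leaf_width_range = c(4, 5.5),
                         petiole_length_range = c(2, 4),
                         inclination_range = c(-30, 45),
                         branch_levels = 2,
                         branch_lengths = c(0.5, 0.35, 0.25),
                         branch_diameters = c(0.025, 0.015, 0.010),
                         branch_tilts = c(30, 50),
                         leaf_zone = 0.6,
                         target_total_leaf_area = NULL,
                         rng_seed = 1L) {
  stopifnot(n_leaves >= 1)
  check_range <- function(r, nm) {
    if (length(r) != 2 || any(r[1] >= r[2]) ||
        (nm != "inclination_range" && any(r <= 0))) {
      stop(nm, " must be a positive, non-degenerate (lo, hi) range",
           call. = FALSE)
    }
  }
  check_range(leaf_length_range, "leaf_length_range")
  check_range(leaf_width_range, "leaf_width_range")
  check_range(petiole_length_range, "petiole_length_range")
  check_range(inclination_range, "inclination_range")
  if (is.list(divergence_angles)) {
    stopifnot(all(c("mean", "sd") %in% names(divergence_angles)))
  } else {
    stopifnot(is.numeric(divergence_angles), length(divergence_angles) >= 1)
  }
  stopifnot(branch_levels >= 0,
            length(branch_lengths) == branch_levels + 1,
            length(branch_diameters) == branch_levels + 1,
            length(branch_tilts) == branch_levels,
            all(branch_lengths > 0), all(branch_diameters > 0),
            leaf_zone > 0, leaf_zone <= 1)
  if (!is.null(target_total_leaf_area)) stopifnot(target_total_leaf_area > 0)
  structure(
    list(n_leaves = as.integer(n_leaves),
         divergence_angles = divergence_angles,
         leaf_length_range = leaf_length_range,
         leaf_width_range = leaf_width_range,
         petiole_length_range = petiole_length_range,
         inclination_range = inclination_range,
         branch_levels = as.integer(branch_levels),
         branch_lengths = branch_lengths,
         branch_diameters = branch_diameters,
         branch_tilts = branch_tilts,
         leaf_zone = leaf_zone,
         target_total_leaf_area = target_total_leaf_area,
         rng_seed = as.integer(rng_seed)),
    class = "plant_config")
}

# lanceolate half-width profile: two mirrored quadratic arcs, max at t = peak
lanceolate_profile <- function(t, peak = 0.4) {
  ifelse(t <= peak,
         1 - ((t - peak) / peak)^2,
         1 - ((t - peak) / (1 - peak))^2)
}

# one flat lanceolate blade; returns vertices (local units: metres) and
# triangles; one-sided area is scaled exactly to area_m2 by scaling widths
leaf_blade_geometry <- function(base, dir, side, length_m, width_m, area_m2,
                                n_stations = 7) {
  ts <- seq(0, 1, length.out = n_stations)
  prof <- lanceolate_profile(ts)
  centers <- t(vapply(ts, function(t) base + dir * (length_m * t), numeric(3)))
  half <- 0.5 * width_m * prof
  interior <- 2:(n_stations - 1)
  # nominal polygon area (planar): sum of trapezoids, linear in half-widths
  du <- diff(ts) * length_m
  nominal <- sum((half[-1] + half[-n_stations]) * du)
  half <- half * (area_m2 / nominal)
  verts <- rbind(centers[1, , drop = FALSE])
  for (i in interior) {
    verts <- rbind(verts,
                   centers[i, ] - side * half[i],
                   centers[i, ] + side * half[i])
  }
  verts <- rbind(verts, centers[n_stations, , drop = FALSE])
  nL <- length(interior)
  li <- function(k) 2L * k        # left vertex of k-th interior station
  ri <- function(k) 2L * k + 1L
  tris <- list(c(1L, ri(1), li(1)))
  for (k in seq_len(nL - 1)) {
    tris[[length(tris) + 1L]] <- c(li(k), ri(k), li(k + 1))
    tris[[length(tris) + 1L]] <- c(ri(k), ri(k + 1), li(k + 1))
  }
  tip <- nrow(verts)
  tris[[length(tris) + 1L]] <- c(li(nL), ri(nL), tip)
  list(vertices = verts, triangles = do.call(rbind, tris))
}

# Y-branch skeleton: tibble of segments (branch_id, level, start, end, radius)
branch_skeleton <- function(config) {
  segs <- list()
  add <- function(id, level, start, end, radius, azimuth) {
    segs[[length(segs) + 1L]] <<- list(branch_id = id, level = level,
                                       start = start, end = end,
                                       radius = radius, azimuth = azimuth)
  }
  add(1L, 0L, c(0, 0, 0), c(0, 0, config$branch_lengths[1]),
      config$branch_diameters[1] / 2, 0)
  frontier <- list(list(id = 1L, end = c(0, 0, config$branch_lengths[1]),
                        azimuth = 0))
  next_id <- 2L
  for (lev in seq_len(config$branch_levels)) {
    tilt <- config$branch_tilts[lev] * pi / 180
    len <- config$branch_lengths[lev + 1]
    rad <- config$branch_diameters[lev + 1] / 2
    new_frontier <- list()
    for (k in seq_along(frontier)) {
      parent <- frontier[[k]]
      # branching plane rotates 90 deg per level so the crown fills out
      base_az <- parent$azimuth + (lev - 1) * 90
      for (s in c(-1, 1)) {
        az <- (base_az + ifelse(s < 0, 180, 0)) * pi / 180
        d <- c(sin(az) * sin(tilt), cos(az) * sin(tilt), cos(tilt))
        end <- parent$end + d * len
        add(next_id, lev, parent$end, end, rad, base_az + ifelse(s < 0, 180, 0))
        new_frontier[[length(new_frontier) + 1L]] <-
          list(id = next_id, end = end, azimuth = base_az + ifelse(s < 0, 180, 0))
        next_id <- next_id + 1L
      }
    }
    frontier <- new_frontier
  }
  segs
}

#' Build a procedural 3D plant
#'
#' Generates the triangle mesh (leaf blades, stem and branch prisms, pot) and
#' the per-leaf record table from a [plant_config()].  The build is fully
#' deterministic given `rng_seed`.  Leaves are attached along each branch
#' segment's leaf zone in spiral order with the configured divergence
#' sequence; every blade is triangulated with at least 8 triangles and its
#' one-sided mesh area equals its allometric area exactly (widths are scaled,
#' lengths kept).
#'
#' If `target_total_leaf_area` is set, every leaf's area is multiplied by the
#' common factor `target / sum(areas)` — preserving each leaf's share of the
#' total exactly — and its length and width are re-solved through
#' [leaf_area_from_dimensions()] so records stay allometrically consistent.
#'
#' @param config a [plant_config()].
#' @return A list of class `canopy3d` with:
#'   * `mesh`: the [triangle_mesh()] (element ids of leaves equal `leaf_id`);
#'   * `leaves`: tibble with `leaf_id`, `length`, `width`, `petiole_length`,
#'     `allometric_area` (cm^2), `azimuth`, `inclination` (degrees),
#'     `attachment_height` (m), `branch_id`;
#'   * `config`: the input configuration.
#' @export
build_plant <- function(config) {
  stopifnot(inherits(config, "plant_config"))
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  })
  set.seed(config$rng_seed)

  segs <- branch_skeleton(config)
  seg_len <- vapply(segs, function(s) sqrt(sum((s$end - s$start)^2)), 0)
  # leaves per segment, proportional to length (largest remainder)
  exact <- config$n_leaves * seg_len / sum(seg_len)
  n_seg <- floor(exact)
  rem <- config$n_leaves - sum(n_seg)
  if (rem > 0) {
    ord <- order(exact - n_seg, decreasing = TRUE)
    n_seg[ord[seq_len(rem)]] <- n_seg[ord[seq_len(rem)]] + 1
  }

  n <- config$n_leaves
  L <- runif(n, config$leaf_length_range[1], config$leaf_length_range[2])
  W <- runif(n, config$leaf_width_range[1], config$leaf_width_range[2])
  P <- runif(n, config$petiole_length_range[1], config$petiole_length_range[2])
  incl <- runif(n, config$inclination_range[1], config$inclination_range[2])
  area <- leaf_area_from_dimensions(L, W)

  # per-branch phyllotaxis chains
  leaf_seg <- rep(seq_along(segs), n_seg)
  azimuth <- numeric(n)
  attach_t <- numeric(n)
  for (si in seq_along(segs)) {
    idx <- which(leaf_seg == si)
    if (length(idx) == 0) next
    k <- length(idx)
    if (is.list(config$divergence_angles)) {
      div <- stats::rnorm(k, config$divergence_angles$mean,
                          config$divergence_angles$sd)
    } else {
      div <- rep_len(config$divergence_angles, k)
    }
    start_az <- segs[[si]]$azimuth + runif(1, 0, 360)
    azimuth[idx] <- phyllotaxis_azimuths(div, start_az)[seq_len(k)]
    # leaf zone: upper `leaf_zone` fraction of the segment, evenly spaced
    attach_t[idx] <- 1 - config$leaf_zone * (seq_len(k) - 0.5) / k
  }

  # optional uniform rescale to a target total area
  if (!is.null(config$target_total_leaf_area)) {
    f <- config$target_total_leaf_area / sum(area)
    area_new <- area * f
    for (i in seq_len(n)) {
      target_i <- area_new[i]
      g <- function(s) allometry_raw(s * L[i], s * W[i]) - target_i
      s <- uniroot(g, c(0.2, 5), tol = 1e-12)$root
      L[i] <- s * L[i]; W[i] <- s * W[i]
    }
    area <- area_new
  }

  meshes <- list()
  # stem / branch prisms (element ids from 1000)
  for (si in seq_along(segs)) {
    s <- segs[[si]]
    meshes[[length(meshes) + 1L]] <-
      prism_mesh(s$start, s$end, s$radius, 1000L + si, "stem")
  }
  # pot: cylinder below the plant base
  meshes[[length(meshes) + 1L]] <-
    prism_mesh(c(0, 0, -0.4), c(0, 0, 0), 0.15, 2000L, "pot", n_sides = 12)

  attach_height <- numeric(n)
  for (i in seq_len(n)) {
    s <- segs[[leaf_seg[i]]]
    axis <- s$end - s$start
    attach <- s$start + axis * attach_t[i]
    attach_height[i] <- attach[3]
    az <- azimuth[i] * pi / 180     # clockwise from north (+y); +x east
    be <- incl[i] * pi / 180
    d <- c(sin(az) * cos(be), cos(az) * cos(be), sin(be))
    horiz <- c(sin(az), cos(az), 0)
    side <- c(cos(az), -sin(az), 0)  # horizontal, perpendicular to azimuth
    base <- attach + horiz * s$radius + d * (P[i] / 100)
    blade <- leaf_blade_geometry(base, d, side, L[i] / 100, W[i] / 100,
                                 area[i] / 1e4)
    meshes[[length(meshes) + 1L]] <- triangle_mesh(
      blade$vertices, blade$triangles,
      rep(i, nrow(blade$triangles)),
      tibble::tibble(element_id = i, kind = "leaf", label = NA_character_))
  }

  mesh <- do.call(mesh_bind, meshes)
  leaves <- tibble::tibble(
    leaf_id = seq_len(n),
    length = L, width = W, petiole_length = P,
    allometric_area = area,
    azimuth = azimuth %% 360,
    inclination = incl,
    attachment_height = attach_height,
    branch_id = vapply(segs, function(s) s$branch_id, 0L)[leaf_seg])

  structure(list(mesh = mesh, leaves = leaves, config = config),
            class = "canopy3d")
}

#' @export
print.canopy3d <- function(x, ...) {
  cat("<canopy3d> ", nrow(x$leaves), " leaves, total one-sided leaf area ",
      sprintf("%.1f", sum(x$leaves$allometric_area)), " cm^2\n", sep = "")
  print(x$mesh)
  invisible(x)
}

#' Export the per-leaf record table as CSV
#'
#' @param plant a [build_plant()] result (or its `leaves` tibble).
#' @param path output CSV path (UTF-8, decimal point, header row).
#' @return `path`, invisibly.
#' @export
write_leaf_csv <- function(plant, path) {
  leaves <- if (inherits(plant, "canopy3d")) plant$leaves else plant
  readr::write_csv(leaves, path)
  invisible(path)
}
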