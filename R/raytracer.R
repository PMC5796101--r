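#' Optical material (PAR-band, bi-Lambertian)
#'
#' @param reflectance hemispherical reflectance rho in `[0, 1]`.
#' @param transmittance hemispherical transmittance tau in `[0, 1]`;
#'   `rho + tau <= 1` (the remainder is absorbed).
#' @return An object of class `optical_material`.
#' @export
optical_material <- function(reflectance = 0, transmittance = 0) {
  stopifnot(reflectance >= 0, transmittance >= 0,
            reflectance + transmittance <= 1)
  structure(list(reflectance = reflectance, transmittance = transmittance),
            class = "optical_material")
}

#' Default scene materials
#'
#' Leaves get typical PAR-band optics for thick evergreen leaves
#' (rho = 0.10, tau = 0.05); stems reflect weakly; everything else — floor,
#' walls (black-out cloth), pot, sensors — is black.  Override any entry for
#' other scenes (e.g. reflective greenhouse floors).
#'
#' @param leaf_reflectance,leaf_transmittance leaf optics, overridable.
#' @return Named list of [optical_material()], one per element kind.
#' @export
default_materials <- function(leaf_reflectance = 0.10,
                              leaf_transmittance = 0.05) {
  list(leaf = optical_material(leaf_reflectance, leaf_transmittance),
       stem = optical_material(0.15, 0),
       pot = optical_material(0, 0),
       wall = optical_material(0, 0),
       floor = optical_material(0, 0),
       lamp = optical_material(0, 0),
       sensor = optical_material(0, 0))
}

# bounding sphere of a mesh (centre + radius with small margin)
bounding_sphere <- function(mesh) {
  bb <- mesh_bbox(mesh)
  center <- colMeans(bb)
  radius <- sqrt(sum((bb["hi", ] - center)^2))
  list(center = center, radius = radius * 1.001 + 1e-6)
}

# build C++ source descriptors from a scene_illumination
prepare_sources <- function(illumination, mesh) {
  bs <- bounding_sphere(mesh)
  src <- list()
  disc_area <- pi * bs$radius^2
  if (!is.null(illumination$beam) && illumination$beam$ppfd_normal > 0) {
    src[[length(src) + 1L]] <- list(
      type = 1L, flux = illumination$beam$ppfd_normal * disc_area,
      dir = illumination$beam$direction,
      center = bs$center, radius = bs$radius,
      back = 2 * bs$radius + 1)
  }
  if (!is.null(illumination$sky) && illumination$sky$ppfd_horizontal > 0) {
    pt <- sky_patch_table(illumination$sky$n_patches, 1, 1)
    # emission through direction-perpendicular discs: per-patch flux
    # proportional to radiance x solid angle (uniform radiance dome)
    L <- illumination$sky$ppfd_horizontal / pi
    cos_hi <- cos(pt$zenith_lo * pi / 180)
    cos_lo <- cos(pt$zenith_hi * pi / 180)
    patches <- cbind(flux = L * pt$solid_angle * disc_area,
                     cos0 = cos_hi, cos1 = cos_lo,
                     phi0 = pt$azimuth_lo * pi / 180,
                     phi1 = pt$azimuth_hi * pi / 180)
    src[[length(src) + 1L]] <- list(
      type = 2L, flux = sum(patches[, "flux"]),
      center = bs$center, radius = bs$radius,
      back = 2 * bs$radius + 1, patches = patches)
  }
  if (!is.null(illumination$lamp) && illumination$lamp$total_flux > 0) {
    src[[length(src) + 1L]] <- list(
      type = 3L, flux = illumination$lamp$total_flux,
      center = illumination$lamp$center,
      radius = illumination$lamp$radius)
  }
  src
}

# per-leaf detector frames (planar blades): origin + in-plane axes + grid size
leaf_patch_frames <- function(mesh, leaf_ids, pitch) {
  frames <- list()
  elem_index <- match(mesh$element_id, mesh$elements$element_id)
  for (lid in leaf_ids) {
    tri_sel <- which(mesh$element_id == lid)
    if (length(tri_sel) == 0) next
    vids <- unique(as.vector(mesh$triangles[tri_sel, ]))
    v <- mesh$vertices[vids, , drop = FALSE]
    # plane frame from the first triangle
    tr <- mesh$triangles[tri_sel[1], ]
    a <- mesh$vertices[tr[1], ]; b <- mesh$vertices[tr[2], ]
    cc <- mesh$vertices[tr[3], ]
    e1 <- b - a; e1 <- e1 / sqrt(sum(e1^2))
    nrm <- pracma_cross(b - a, cc - a)
    nrm <- nrm / sqrt(sum(nrm^2))
    e2 <- pracma_cross(nrm, e1)
    u <- as.vector((sweep(v, 2, a)) %*% e1)
    w <- as.vector((sweep(v, 2, a)) %*% e2)
    origin <- a + min(u) * e1 + min(w) * e2
    nu <- max(1L, ceiling((max(u) - min(u)) / pitch))
    nv <- max(1L, ceiling((max(w) - min(w)) / pitch))
    frames[[length(frames) + 1L]] <- list(
      elem = match(lid, mesh$elements$element_id) - 1L,
      origin = origin, e1 = e1, e2 = e2, nu = nu, nv = nv)
  }
  frames
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Monte Carlo ray trace of a scene
#'
#' Traces photon packets from every source in `illumination` through the
#' mesh.  At each surface hit the packet's weight is tallied as *incident*
#' flux on that element (both faces — the convention of a quantum sensor
#' laminated to the leaf), then the packet is diffusely reflected
#' (probability rho), diffusely transmitted (tau) or absorbed; paths
#' terminate after `max_impacts` interactions.  Packet weight is constant
#' (rays are allocated to sources in proportion to flux), so the energy
#' ledger `emitted = absorbed + escaped + truncated` closes exactly.
#'
#' @param mesh a [triangle_mesh()] (typically `build_scene()$mesh`).
#' @param materials named list of [optical_material()] keyed by element kind;
#'   every kind present in the mesh must be covered.
#' @param illumination a [scene_illumination()].
#' @param n_rays number of photon packets (default 1e6; standard errors are
#'   reported so smaller desk-scale budgets stay interpretable).
#' @param max_impacts maximum surface interactions per packet (default 10).
#' @param detector_pitch detector grid spacing on leaves, metres (default
#'   0.005 = 5 mm); used when `patch_grids = TRUE`.
#' @param seed integer; the trace is bitwise reproducible given the seed.
#' @param patch_grids also tally per-leaf detector grids at
#'   `detector_pitch` spacing?
#' @param n_batches batches for Monte Carlo standard errors.
#' @return An object of class `irradiance_map`:
#'   * `elements`: tibble `element_id`, `kind`, `label`, `area` (m^2,
#'     one-sided), `incident_flux` (umol s^-1), `ppfd`, `se`
#'     (umol m^-2 s^-1), `absorbed_flux`;
#'   * `ledger`: tibble `emitted`, `absorbed` (by kind), `escaped`,
#'     `truncated` (umol s^-1);
#'   * `patches`: named list of per-leaf PPFD matrices (if requested);
#'   * `n_rays`, `seed`.
#' @export
trace_scene <- function(mesh, materials, illumination,
                        n_rays = 1e6, max_impacts = 10,
                        detector_pitch = 0.005, seed = 1L,
                        patch_grids = FALSE, n_batches = 10L) {
  stopifnot(inherits(mesh, "triangle_mesh"),
            inherits(illumination, "scene_illumination"),
            n_rays >= 1, max_impacts >= 1, detector_pitch > 0)
  kinds <- unique(mesh$elements$kind)
  missing_kind <- setdiff(kinds, names(materials))
  if (length(missing_kind) > 0) {
    stop("no material for element kind(s): ",
         paste(missing_kind, collapse = ", "), call. = FALSE)
  }
  elems <- mesh$elements
  rho <- vapply(elems$kind, function(k) materials[[k]]$reflectance, 0)
  tau <- vapply(elems$kind, function(k) materials[[k]]$transmittance, 0)
  elem_of_tri <- match(mesh$element_id, elems$element_id) - 1L

  sources <- prepare_sources(illumination, mesh)
  frames <- list()
  if (patch_grids) {
    leaf_ids <- elems$element_id[elems$kind == "leaf"]
    frames <- leaf_patch_frames(mesh, leaf_ids, detector_pitch)
  }

  res <- cpp_trace(mesh$vertices, mesh$triangles - 1L, elem_of_tri,
                   rho, tau, sources, n_rays, as.integer(max_impacts),
                   as.integer(seed), as.integer(n_batches), frames,
                   detector_pitch)

  areas <- mesh_element_areas(mesh)
  ppfd <- res$incident / areas$area
  nb <- ncol(res$incident_batch)
  batch_ppfd <- sweep(res$incident_batch * nb, 1, areas$area, "/")
  se <- apply(batch_ppfd, 1, sd) / sqrt(nb)
  elements <- dplyr::mutate(areas,
                            incident_flux = res$incident,
                            ppfd = ppfd, se = se,
                            absorbed_flux = res$absorbed)
  absorbed_by_kind <- elements |>
    dplyr::summarise(absorbed = sum(.data$absorbed_flux), .by = "kind")
  ledger <- tibble::tibble(
    emitted = res$emitted,
    absorbed = sum(res$absorbed),
    escaped = res$escaped,
    truncated = res$truncated)
  patches <- NULL
  if (patch_grids && length(frames) > 0) {
    cell_area <- detector_pitch^2
    patches <- lapply(res$patch_tallies, function(g) g / cell_area)
    names(patches) <- vapply(frames, function(f) {
      as.character(elems$element_id[f$elem + 1L])
    }, "")
  }
  out <- structure(list(elements = elements, ledger = ledger,
                        absorbed_by_kind = absorbed_by_kind,
                        patches = patches,
                        n_rays = res$n_rays, seed = seed,
                        detector_pitch = detector_pitch),
                   class = "irradiance_map")
  if (isTRUE(getOption("canopyray.verbose"))) {
    message(sprintf(
      "trace: seed %d, %g rays, emitted %.4g = absorbed %.4g + escaped %.4g + truncated %.4g umol/s",
      seed, res$n_rays, ledger$emitted, ledger$absorbed, ledger$escaped,
      ledger$truncated))
  }
  out
}

#' Export an irradiance map as CSV
#'
#' Writes the per-element table to `path`; with `patch_dir` set, each leaf's
#' detector-grid PPFD matrix (if traced with `patch_grids = TRUE`) is written
#' as `leaf_<id>.csv` in that directory.
#'
#' @param map an `irradiance_map`.
#' @param path output CSV for the per-element table.
#' @param patch_dir optional directory for per-leaf patch-grid matrices.
#' @return `path`, invisibly.
#' @export
write_irradiance_csv <- function(map, path, patch_dir = NULL) {
  stopifnot(inherits(map, "irradiance_map"))
  readr::write_csv(map$elements, path)
  if (!is.null(patch_dir) && !is.null(map$patches)) {
    dir.create(patch_dir, showWarnings = FALSE, recursive = TRUE)
    for (id in names(map$patches)) {
      utils::write.table(map$patches[[id]],
                         file.path(patch_dir, paste0("leaf_", id, ".csv")),
                         sep = ",", row.names = FALSE, col.names = FALSE)
    }
  }
  invisible(path)
}

#' @export
print.irradiance_map <- function(x, ...) {
  cat("<irradiance_map> ", x$n_rays, " rays; ledger: emitted ",
      sprintf("%.4g", x$ledger$emitted), ", absorbed ",
      sprintf("%.4g", x$ledger$absorbed), ", escaped ",
      sprintf("%.4g", x$ledger$escaped), ", truncated ",
      sprintf("%.4g", x$ledger$truncated), " umol/s\n", sep = "")
  print(x$elements)
  invisible(x)
}

#' Nearest ray-mesh intersection
#'
#' Returns the closest triangle hit by each ray (distance > 1e-9 m), or `NA`
#' if none.  `method = "brute"` tests every triangle and is the in-package
#' oracle for the BVH-accelerated path — both must agree exactly.
#'
#' @param mesh a [triangle_mesh()].
#' @param origins numeric 3-vector or n x 3 matrix of ray origins (m).
#' @param directions matching 3-vector or n x 3 matrix (need not be unit).
#' @param method `"bvh"` (accelerated) or `"brute"` (exhaustive).
#' @return A tibble with `triangle` (1-based index into mesh triangles),
#'   `distance` (m), `bary_u`, `bary_v`; `NA` rows for misses.
#' @export
nearest_hit <- function(mesh, origins, directions,
                        method = c("bvh", "brute")) {
  method <- match.arg(method)
  if (is.null(dim(origins))) origins <- matrix(origins, nrow = 1)
  if (is.null(dim(directions))) directions <- matrix(directions, nrow = 1)
  out <- cpp_nearest_hit(mesh$vertices, mesh$triangles - 1L,
                         origins, directions, method == "bvh")
  tibble::tibble(triangle = as.integer(out[, 1]), distance = out[, 2],
                 bary_u = out[, 3], bary_v = out[, 4])
}

#' Per-leaf intercepted PPFD table
#'
#' Joins an [trace_scene()] result with the per-leaf record table by leaf id.
#'
#' @param map an `irradiance_map`.
#' @param leaves per-leaf tibble with a `leaf_id` column ([build_plant()]'s
#'   `leaves`).
#' @return A tibble with `leaf_id`, `ppfd`, `se` (umol m^-2 s^-1).
#' @export
leaf_ppfd_table <- function(map, leaves) {
  stopifnot(inherits(map, "irradiance_map"))
  if (nrow(leaves) == 0) {
    return(tibble::tibble(leaf_id = integer(0), ppfd = numeric(0),
                          se = numeric(0)))
  }
  leaf_elems <- dplyr::filter(map$elements, .data$kind == "leaf")
  unknown <- setdiff(leaves$leaf_id, leaf_elems$element_id)
  if (length(unknown) > 0) {
    stop("leaf id(s) not present in the irradiance map: ",
         paste(head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  dplyr::left_join(
    dplyr::select(leaves, "leaf_id"),
    dplyr::select(leaf_elems, leaf_id = "element_id", "ppfd", "se"),
    by = "leaf_id")
}

#' Virtual sensor readings
#'
#' @param map an `irradiance_map` from a scene containing sensor elements.
#' @return A tibble with `label`, `ppfd`, `se`.
#' @export
sensor_readings <- function(map) {
  stopifnot(inherits(map, "irradiance_map"))
  map$elements |>
    dplyr::filter(.data$kind == "sensor") |>
    dplyr::select("label", "ppfd", "se")
}

#' Calibrate lamp flux to a target sensor PPFD
#'
#' Light transport is linear in source flux, so one trace at a probe flux
#' fixes the scale: the returned flux is the probe flux times
#' `target / probe reading`.
#'
#' @param mesh scene mesh containing the reference sensor.
#' @param materials as in [trace_scene()].
#' @param illumination a [scene_illumination()] whose `lamp` is to be
#'   calibrated.
#' @param target_ppfd desired reading at the reference sensor.
#' @param sensor_label reference sensor label (default `"sensor_top"`).
#' @param ... further arguments to [trace_scene()] (`n_rays`, `seed`, ...).
#' @return A list: `illumination` (with calibrated flux), `total_flux`,
#'   `probe_ppfd` (reading at the probe flux).
#' @export
calibrate_lamp <- function(mesh, materials, illumination, target_ppfd,
                           sensor_label = "sensor_top", ...) {
  stopifnot(!is.null(illumination$lamp), target_ppfd >= 0)
  if (target_ppfd == 0) {
    illumination$lamp$total_flux <- 0
    return(list(illumination = illumination, total_flux = 0,
                probe_ppfd = NA_real_))
  }
  probe_flux <- illumination$lamp$total_flux
  if (probe_flux <= 0) probe_flux <- 1000
  probe <- illumination
  probe$lamp$total_flux <- probe_flux
  map <- trace_scene(mesh, materials, probe, ...)
  reading <- sensor_readings(map)
  row <- dplyr::filter(reading, .data$label == sensor_label)
  if (nrow(row) != 1) {
    stop("sensor '", sensor_label, "' not found in scene", call. = FALSE)
  }
  if (row$ppfd <= 0) {
    stop("reference sensor receives no flux; cannot calibrate",
         call. = FALSE)
  }
  flux <- probe_flux * target_ppfd / row$ppfd
  illumination$lamp$total_flux <- flux
  list(illumination = illumination, total_flux = flux,
       probe_ppfd = row$ppfd)
}
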