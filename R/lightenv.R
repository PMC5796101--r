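#' Site and time for solar geometry
#'
#' @param latitude degrees north (|latitude| <= 90).
#' @param longitude degrees east.
#' @param datetime a `POSIXct` (interpreted as local civil time) or an
#'   ISO-8601 string.
#' @param utc_offset hours east of UTC of the local clock (e.g. 9 for Korea
#'   Standard Time).
#' @return An object of class `site_time`.
#' @export
site_time <- function(latitude, longitude, datetime, utc_offset) {
  stopifnot(abs(latitude) <= 90)
  if (is.character(datetime)) {
    datetime <- as.POSIXct(datetime, tz = "UTC")
  }
  structure(list(latitude = latitude, longitude = longitude,
                 datetime = datetime, utc_offset = utc_offset),
            class = "site_time")
}

#' Solar position (zenith and azimuth)
#'
#' Computed from the standard low-precision solar-geometry formulas
#' (Fourier-series declination and equation of time, hour angle from true
#' solar time); accuracy is a few hundredths of a degree over recent decades,
#' well inside the 0.5 degree envelope needed for canopy work.
#'
#' @param site a [site_time()].
#' @return A tibble with `zenith` (degrees, 0 = overhead; > 90 means the sun
#'   is below the horizon) and `azimuth` (degrees clockwise from north).
#' @export
solar_position <- function(site) {
  stopifnot(inherits(site, "site_time"))
  lt <- as.POSIXlt(site$datetime)
  doy <- lt$yday + 1
  hour <- lt$hour + lt$min / 60 + lt$sec / 3600
  g <- 2 * pi / 365 * (doy - 1 + (hour - 12) / 24)   # fractional year, rad
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                      0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  time_offset <- eqtime + 4 * site$longitude - 60 * site$utc_offset
  tst <- hour * 60 + time_offset                     # true solar time, min
  ha <- (tst / 4 - 180) * pi / 180                   # hour angle, rad
  lat <- site$latitude * pi / 180
  cos_zen <- sin(lat) * sin(decl) + cos(lat) * cos(decl) * cos(ha)
  cos_zen <- pmin(1, pmax(-1, cos_zen))
  zen <- acos(cos_zen)
  # azimuth clockwise from north
  saz <- atan2(sin(ha) * cos(decl),
               cos(ha) * cos(decl) * sin(lat) - sin(decl) * cos(lat))
  az <- (saz * 180 / pi + 180) %% 360
  tibble::tibble(zenith = zen * 180 / pi, azimuth = az)
}

#' Scene illumination container
#'
#' Bundles up to three light sources: a collimated beam (sun), a uniform
#' diffuse sky dome, and a Lambertian disc lamp.  At least one source must be
#' present; all fluxes are PPFD-based (umol photons m^-2 s^-1, PAR band).
#'
#' @param beam `NULL` or `list(direction = unit 3-vector (propagation),
#'   ppfd_normal = PPFD on a plane normal to the beam)`.
#' @param sky `NULL` or `list(ppfd_horizontal =, n_patches =)`.
#' @param lamp `NULL` or `list(center = 3-vector (m), radius = m,
#'   total_flux = umol s^-1)` (Lambertian, emitting downward).
#' @return An object of class `scene_illumination`.
#' @export
scene_illumination <- function(beam = NULL, sky = NULL, lamp = NULL) {
  if (is.null(beam) && is.null(sky) && is.null(lamp)) {
    stop("at least one light source is required", call. = FALSE)
  }
  if (!is.null(beam)) {
    stopifnot(beam$ppfd_normal >= 0, length(beam$direction) == 3)
    beam$direction <- beam$direction / sqrt(sum(beam$direction^2))
  }
  if (!is.null(sky)) {
    stopifnot(sky$ppfd_horizontal >= 0)
    if (is.null(sky$n_patches)) sky$n_patches <- 145
  }
  if (!is.null(lamp)) {
    stopifnot(lamp$total_flux >= 0, lamp$radius > 0, length(lamp$center) == 3)
  }
  structure(list(beam = beam, sky = sky, lamp = lamp),
            class = "scene_illumination")
}

#' Natural illumination from a global PPFD and a diffuse fraction
#'
#' Splits global horizontal PPFD into a collimated solar beam and a uniform
#' diffuse sky dome.  The horizontal components close exactly:
#' direct-horizontal `(1 - f) * ghi` plus diffuse-horizontal `f * ghi` equals
#' the input.  The beam-normal PPFD is `(1 - f) * ghi / cos(zenith)`.
#' When the sun is at or below the horizon the diffuse fraction is forced to
#' 1 (with a warning if a smaller value was requested), since a direct
#' component is undefined there.
#'
#' An optional enclosure transmittance (greenhouse glazing or chamber film)
#' scales both components before they enter the scene.
#'
#' @param ghi_ppfd global horizontal PPFD, umol m^-2 s^-1.
#' @param diffuse_fraction fraction of `ghi_ppfd` that is diffuse, in
#'   `[0, 1]`.
#' @param site optional [site_time()]; its [solar_position()] supplies
#'   `zenith` / `azimuth` unless these are given directly.
#' @param zenith,azimuth solar position in degrees (azimuth clockwise from
#'   north) if `site` is not given.
#' @param sky_patches dome discretisation (equal-solid-angle patches).
#' @param enclosure_transmittance scalar in `[0, 1]` applied to both
#'   components (default 1 = open sky).
#' @return A [scene_illumination()] with `beam` (unless fully diffuse) and
#'   `sky`.
#' @export
natural_illumination <- function(ghi_ppfd, diffuse_fraction = 0.3,
                                 site = NULL, zenith = NULL, azimuth = NULL,
                                 sky_patches = 145,
                                 enclosure_transmittance = 1) {
  stopifnot(ghi_ppfd >= 0, diffuse_fraction >= 0, diffuse_fraction <= 1,
            enclosure_transmittance >= 0, enclosure_transmittance <= 1)
  if (!is.null(site)) {
    sp <- solar_position(site)
    zenith <- sp$zenith
    azimuth <- sp$azimuth
  }
  stopifnot(!is.null(zenith), !is.null(azimuth))
  f <- diffuse_fraction
  if (zenith >= 90 && f < 1) {
    warning("sun at or below the horizon: forcing diffuse_fraction to 1",
            call. = FALSE)
    f <- 1
  }
  ghi <- ghi_ppfd * enclosure_transmittance
  beam <- NULL
  if (f < 1 && ghi > 0) {
    zr <- zenith * pi / 180
    ar <- azimuth * pi / 180
    sun <- c(sin(zr) * sin(ar), sin(zr) * cos(ar), cos(zr))  # toward sun
    beam <- list(direction = -sun,
                 ppfd_normal = (1 - f) * ghi / cos(zr))
  }
  sky <- if (ghi > 0 && f > 0) {
    list(ppfd_horizontal = f * ghi, n_patches = sky_patches)
  } else if (is.null(beam)) {
    list(ppfd_horizontal = 0, n_patches = sky_patches)
  } else NULL
  scene_illumination(beam = beam, sky = sky)
}

#' Lamp illumination
#'
#' A horizontal Lambertian disc emitting downward, e.g. a plasma growth lamp
#' mounted above the canopy.  In the far field a disc of vanishing radius
#' behaves as a Lambertian point source with irradiance
#' `E = flux * cos(theta) / (pi * r^2)`.
#'
#' @param center disc centre, metres (z is the mounting height).
#' @param total_flux total emitted photon flux, umol s^-1.  Usually set by
#'   [calibrate_lamp()] so a reference sensor reads a target PPFD.
#' @param radius disc radius, metres.
#' @return A [scene_illumination()] with only a `lamp` source.
#' @export
lamp_illumination <- function(center, total_flux, radius = 0.15) {
  stopifnot(radius > 0, total_flux >= 0)
  scene_illumination(lamp = list(center = center, radius = radius,
                                 total_flux = total_flux))
}

#' Discretised sky-dome patch table
#'
#' Partitions the hemisphere into equal-solid-angle patches (rings of equal
#' delta-cos(zenith), equal azimuth count per ring) and reports each patch's
#' share of the diffuse flux through a horizontal reference area.  The flux
#' column is normalised so it sums exactly to
#' `ppfd_horizontal * reference_area`.
#'
#' @param n_patches requested number of patches (rounded to a rings x
#'   sectors grid).
#' @param ppfd_horizontal diffuse horizontal PPFD.
#' @param reference_area horizontal reference area, m^2.
#' @return A tibble with `patch`, `zenith_lo`, `zenith_hi`, `azimuth_lo`,
#'   `azimuth_hi` (degrees), `solid_angle` (sr) and `flux` (umol s^-1).
#' @export
sky_patch_table <- function(n_patches = 145, ppfd_horizontal = 1,
                            reference_area = 1) {
  stopifnot(n_patches >= 1, ppfd_horizontal >= 0, reference_area > 0)
  n_rings <- max(1L, round(sqrt(n_patches / 4)))
  n_per <- max(1L, round(n_patches / n_rings))
  cosb <- seq(1, 0, length.out = n_rings + 1)   # equal delta-cos bands
  rows <- list()
  for (i in seq_len(n_rings)) {
    phis <- seq(0, 2 * pi, length.out = n_per + 1)
    for (j in seq_len(n_per)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        cos_hi = cosb[i], cos_lo = cosb[i + 1],
        phi_lo = phis[j], phi_hi = phis[j + 1])
    }
  }
  tab <- dplyr::bind_rows(rows)
  # integral of cos(theta) over the patch solid angle
  w <- (tab$cos_hi^2 - tab$cos_lo^2) / 2 * (tab$phi_hi - tab$phi_lo)
  flux <- w / sum(w) * ppfd_horizontal * reference_area
  tibble::tibble(
    patch = seq_len(nrow(tab)),
    zenith_lo = acos(tab$cos_hi) * 180 / pi,
    zenith_hi = acos(tab$cos_lo) * 180 / pi,
    azimuth_lo = tab$phi_lo * 180 / pi,
    azimuth_hi = tab$phi_hi * 180 / pi,
    solid_angle = (tab$cos_hi - tab$cos_lo) * (tab$phi_hi - tab$phi_lo),
    flux = flux)
}

# ----------------------------------------------------------------- scenes

#' Assemble a plant into a chamber scene
#'
#' Adds the enclosure floor, optional black-out walls (no ceiling, so an
#' overhead lamp is never self-occluded), and three virtual quantum sensors
#' — small horizontal squares labelled `sensor_top`, `sensor_middle`,
#' `sensor_bottom` — mounted at the top, mid-height and base of the canopy,
#' mirroring in-canopy sensor placement in closed-chamber gas-exchange work.
#'
#' @param plant a [build_plant()] result.
#' @param chamber_size `c(x, y, height)` of the enclosure in metres (the
#'   floor sits at the bottom of the pot).
#' @param walls include the enclosure walls as mesh elements?
#' @param sensor_positions optional 3 x 3 numeric matrix (rows `top`,
#'   `middle`, `bottom`; columns x, y, z in metres).  The default emulates
#'   in-canopy quantum-sensor mounting: the top sensor just above the apex,
#'   the middle sensor inside the upper crown, the bottom sensor at the
#'   crown base — staggered in azimuth so the (opaque) sensors never shade
#'   one another.
#' @param sensor_size sensor square side, metres.
#' @return A list of class `canopy_scene`: `mesh` (plant + enclosure +
#'   sensors), `leaves`, `sensor_positions`, `sensor_heights`,
#'   `chamber_size`.
#' @export
build_scene <- function(plant, chamber_size = c(1, 1, 2), walls = TRUE,
                        sensor_positions = NULL, sensor_size = 0.06) {
  stopifnot(inherits(plant, "canopy3d"))
  z_floor <- -0.4
  z_top_wall <- z_floor + chamber_size[3]
  hx <- chamber_size[1] / 2
  hy <- chamber_size[2] / 2
  parts <- list(plant$mesh)
  parts[[length(parts) + 1L]] <- quad_mesh(
    c(-hx, -hy, z_floor), c(hx, -hy, z_floor),
    c(hx, hy, z_floor), c(-hx, hy, z_floor),
    3000L, "floor", "floor")
  if (walls) {
    wall_id <- 3001L
    corners <- list(
      list(c(-hx, -hy), c(hx, -hy)), list(c(hx, -hy), c(hx, hy)),
      list(c(hx, hy), c(-hx, hy)), list(c(-hx, hy), c(-hx, -hy)))
    for (w in corners) {
      a <- w[[1]]; b <- w[[2]]
      parts[[length(parts) + 1L]] <- quad_mesh(
        c(a, z_floor), c(b, z_floor), c(b, z_top_wall), c(a, z_top_wall),
        wall_id, "wall", "wall")
      wall_id <- wall_id + 1L
    }
  }
  if (is.null(sensor_positions)) {
    z_lo <- min(plant$leaves$attachment_height)
    # top of the leaf canopy from leaf triangle vertices
    leaf_tris <- plant$mesh$element_id %in% plant$leaves$leaf_id
    leaf_verts <- unique(as.vector(plant$mesh$triangles[leaf_tris, ]))
    z_hi <- max(plant$mesh$vertices[leaf_verts, 3])
    span <- z_hi - z_lo
    r <- 0.12
    az <- c(0, 2 * pi / 3, 4 * pi / 3)
    sensor_positions <- rbind(
      top = c(0.05, 0, z_hi + 0.03),
      middle = c(r * cos(az[2]), r * sin(az[2]), z_lo + 0.8 * span),
      bottom = c(r * cos(az[3]), r * sin(az[3]), z_lo + 0.05 * span))
  } else {
    sensor_positions <- as.matrix(sensor_positions)
    rownames(sensor_positions) <- c("top", "middle", "bottom")
  }
  s <- sensor_size / 2
  sid <- 4000L
  for (nm in rownames(sensor_positions)) {
    p <- sensor_positions[nm, ]
    parts[[length(parts) + 1L]] <- quad_mesh(
      c(p[1] - s, p[2] - s, p[3]), c(p[1] + s, p[2] - s, p[3]),
      c(p[1] + s, p[2] + s, p[3]), c(p[1] - s, p[2] + s, p[3]),
      sid, "sensor", paste0("sensor_", nm))
    sid <- sid + 1L
  }
  structure(list(mesh = do.call(mesh_bind, parts),
                 leaves = plant$leaves,
                 sensor_positions = sensor_positions,
                 sensor_heights = sensor_positions[, 3],
                 chamber_size = chamber_size),
            class = "canopy_scene")
}

#' @export
print.canopy_scene <- function(x, ...) {
  cat("<canopy_scene> chamber ", paste(x$chamber_size, collapse = " x "),
      " m; sensors at z = ",
      paste(sprintf("%.2f", x$sensor_heights), collapse = ", "), " m\n",
      sep = "")
  print(x$mesh)
  invisible(x)
}
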