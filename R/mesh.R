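#' Triangle mesh scenes
#'
#' A `triangle_mesh` is the shared geometric currency of the package: vertices
#' in metres (right-handed, z-up, +y = geographic north), triangles as
#' vertex-index triples, and per-triangle element membership.  An *element* is
#' a physically meaningful unit (one leaf blade, one stem segment, the floor,
#' a virtual quantum sensor, ...) identified by an integer id and a kind.
#'
#' @param vertices numeric matrix, n x 3, coordinates in metres.
#' @param triangles integer matrix, m x 3, 1-based vertex indices.
#' @param element_id integer vector, length m, element membership per triangle.
#' @param element_kind character: either length m (per triangle, constant
#'   within an element) or a tibble with columns `element_id`, `kind` and
#'   optionally `label`.
#'
#' @return An object of class `triangle_mesh`: a list with `vertices`,
#'   `triangles`, `element_id` and an `elements` tibble
#'   (`element_id`, `kind`, `label`).
#' @export
triangle_mesh <- function(vertices, triangles, element_id, element_kind) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  stopifnot(ncol(vertices) == 3, ncol(triangles) == 3)
  if (nrow(triangles) > 0 &&
      (min(triangles) < 1 || max(triangles) > nrow(vertices))) {
    stop("triangle vertex indices out of range", call. = FALSE)
  }
  element_id <- as.integer(element_id)
  if (length(element_id) != nrow(triangles)) {
    stop("element_id must have one entry per triangle", call. = FALSE)
  }
  if (is.data.frame(element_kind)) {
    elements <- tibble::as_tibble(element_kind)
    if (!"label" %in% names(elements)) elements$label <- NA_character_
  } else {
    stopifnot(length(element_kind) == nrow(triangles))
    elements <- tibble::tibble(element_id = element_id, kind = element_kind) |>
      dplyr::distinct() |>
      dplyr::mutate(label = NA_character_)
  }
  if (anyDuplicated(elements$element_id)) {
    stop("an element_id maps to more than one kind", call. = FALSE)
  }
  if (!all(element_id %in% elements$element_id)) {
    stop("triangles reference unknown element ids", call. = FALSE)
  }
  bad <- setdiff(elements$kind, mesh_kinds())
  if (length(bad) > 0) {
    stop("unknown element kind(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(vertices = vertices, triangles = triangles,
         element_id = element_id,
         elements = dplyr::arrange(elements, .data$element_id)),
    class = "triangle_mesh"
  )
}

mesh_kinds <- function() {
  c("leaf", "stem", "pot", "wall", "floor", "lamp", "sensor")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat("<triangle_mesh> ", nrow(x$vertices), " vertices, ",
      nrow(x$triangles), " triangles, ",
      nrow(x$elements), " elements (",
      paste(sprintf("%s: %d", names(table(x$elements$kind)),
                    as.integer(table(x$elements$kind))), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

triangle_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$triangles
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Per-element one-sided surface areas
#'
#' @param mesh a [triangle_mesh()].
#' @return A tibble with `element_id`, `kind`, `label`, `area` (m^2, one-sided).
#' @export
mesh_element_areas <- function(mesh) {
  areas <- triangle_areas(mesh)
  tibble::tibble(element_id = mesh$element_id, area = areas) |>
    dplyr::summarise(area = sum(.data$area), .by = "element_id") |>
    dplyr::left_join(mesh$elements, by = "element_id") |>
    dplyr::select("element_id", "kind", "label", "area") |>
    dplyr::arrange(.data$element_id)
}

#' Combine meshes into one scene
#'
#' Vertex indices are offset automatically; element ids must not collide.
#'
#' @param ... `triangle_mesh` objects.
#' @return A single [triangle_mesh()].
#' @export
mesh_bind <- function(...) {
  parts <- Filter(Negate(is.null), list(...))
  stopifnot(length(parts) >= 1)
  ids <- unlist(lapply(parts, function(m) m$elements$element_id))
  if (anyDuplicated(ids)) {
    stop("element ids collide across meshes", call. = FALSE)
  }
  offset <- 0L
  vs <- list(); fs <- list(); es <- list(); el <- list()
  for (m in parts) {
    vs[[length(vs) + 1L]] <- m$vertices
    fs[[length(fs) + 1L]] <- m$triangles + offset
    es[[length(es) + 1L]] <- m$element_id
    el[[length(el) + 1L]] <- m$elements
    offset <- offset + nrow(m$vertices)
  }
  triangle_mesh(do.call(rbind, vs), do.call(rbind, fs),
                unlist(es), dplyr::bind_rows(el))
}

#' Rigid transform of a mesh
#'
#' @param mesh a [triangle_mesh()].
#' @param rotation 3 x 3 rotation matrix (applied first).
#' @param translation length-3 numeric offset in metres.
#' @return The transformed [triangle_mesh()].
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  mesh$vertices <- sweep(mesh$vertices %*% t(rotation), 2, -translation)
  mesh
}

mesh_bbox <- function(mesh) {
  rbind(lo = apply(mesh$vertices, 2, min), hi = apply(mesh$vertices, 2, max))
}

# quad as two triangles; p1..p4 in CCW order (normal by right-hand rule)
quad_mesh <- function(p1, p2, p3, p4, element_id, kind, label = NA_character_) {
  triangle_mesh(
    rbind(p1, p2, p3, p4),
    rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)),
    rep(as.integer(element_id), 2),
    tibble::tibble(element_id = as.integer(element_id), kind = kind,
                   label = label)
  )
}

# open prism (cylinder approximation) along axis from base to top
prism_mesh <- function(base, top, radius, element_id, kind, n_sides = 6,
                       label = NA_character_) {
  axis <- top - base
  len <- sqrt(sum(axis^2))
  d <- axis / len
  # orthonormal frame
  up <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- up - sum(up * d) * d
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d[2] * e1[3] - d[3] * e1[2],
          d[3] * e1[1] - d[1] * e1[3],
          d[1] * e1[2] - d[2] * e1[1])
  ang <- 2 * pi * (seq_len(n_sides) - 1) / n_sides
  ring <- t(vapply(ang, function(a) radius * (cos(a) * e1 + sin(a) * e2),
                   numeric(3)))
  verts <- rbind(sweep(ring, 2, -base), sweep(ring, 2, -top))
  tris <- do.call(rbind, lapply(seq_len(n_sides), function(i) {
    j <- if (i == n_sides) 1L else i + 1L
    rbind(c(i, j, i + n_sides), c(j, j + n_sides, i + n_sides))
  }))
  triangle_mesh(verts, tris, rep(as.integer(element_id), nrow(tris)),
                tibble::tibble(element_id = as.integer(element_id),
                               kind = kind, label = label))
}

# ----------------------------------------------------------------- mesh I/O

#' Write a mesh as Wavefront OBJ
#'
#' One named object (`o`) per element; the element kind is encoded in the
#' material name (`usemtl <kind>`).
#'
#' @param mesh a [triangle_mesh()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# canopyray triangle mesh", con)
  v <- mesh$vertices
  writeLines(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  kind_of <- setNames(mesh$elements$kind, mesh$elements$element_id)
  for (eid in unique(mesh$element_id)) {   # original triangle order
    sel <- mesh$element_id == eid
    writeLines(sprintf("o element_%d", eid), con)
    writeLines(sprintf("usemtl %s", kind_of[[as.character(eid)]]), con)
    f <- mesh$triangles[sel, , drop = FALSE]
    writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  }
  invisible(path)
}

#' Read a Wavefront OBJ written by [write_obj()]
#'
#' @param path OBJ file path.
#' @return A [triangle_mesh()].
#' @export
read_obj <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  tok1 <- sub(" .*", "", lines)
  vs <- lines[tok1 == "v"]
  verts <- do.call(rbind, lapply(strsplit(vs, "\\s+"), function(p) {
    as.numeric(p[2:4])
  }))
  cur_id <- NA_integer_
  cur_kind <- NA_character_
  tris <- list(); eids <- integer(0); kinds <- character(0)
  for (ln in lines) {
    if (startsWith(ln, "o ")) {
      cur_id <- as.integer(sub("^o element_", "", ln))
    } else if (startsWith(ln, "usemtl ")) {
      cur_kind <- sub("^usemtl ", "", ln)
    } else if (startsWith(ln, "f ")) {
      p <- strsplit(ln, "\\s+")[[1]]
      idx <- as.integer(sub("/.*", "", p[2:4]))
      tris[[length(tris) + 1L]] <- idx
      eids <- c(eids, cur_id)
      kinds <- c(kinds, cur_kind)
    }
  }
  triangle_mesh(verts, do.call(rbind, tris), eids, kinds)
}

#' Write a mesh as ASCII PLY
#'
#' Per-face integer properties `element_id` and `kind_code` (index into the
#' comment-listed kind table) are included.
#'
#' @inheritParams write_obj
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  kinds <- mesh_kinds()
  kind_of <- setNames(mesh$elements$kind, mesh$elements$element_id)
  kind_code <- match(kind_of[as.character(mesh$element_id)], kinds) - 1L
  writeLines(c(
    "ply", "format ascii 1.0",
    paste("comment kinds:", paste(kinds, collapse = " ")),
    sprintf("element vertex %d", nrow(mesh$vertices)),
    "property double x", "property double y", "property double z",
    sprintf("element face %d", nrow(mesh$triangles)),
    "property list uchar int vertex_indices",
    "property int element_id", "property int kind_code",
    "end_header"), con)
  v <- mesh$vertices
  writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  f <- mesh$triangles - 1L
  writeLines(sprintf("3 %d %d %d %d %d", f[, 1], f[, 2], f[, 3],
                     mesh$element_id, kind_code), con)
  invisible(path)
}
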