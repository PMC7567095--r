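#' Triangle surface mesh
#'
#' The basic container for all conductor geometry: a triangle surface mesh
#' with vertex coordinates in millimetres in a right-handed world frame.
#' Conductivity boundaries must be closed 2-manifolds with outward-oriented
#' face winding; evaluation surfaces may be open.
#'
#' @param vertices numeric matrix (n x 3) of vertex positions in mm.
#' @param faces integer matrix (m x 3) of 1-based vertex indices.
#' @param label optional surface role, one of `"body"`, `"skull"`, `"eyes"`,
#'   `"evaluation"` or `NULL`.
#' @param weld if `TRUE`, vertices closer than `weld_tol` are merged and
#'   degenerate (zero-area) faces dropped.
#' @param weld_tol welding tolerance in mm.
#' @return an object of class `trimesh` with elements `vertices`, `faces`
#'   and `label`.
#' @export
trimesh <- function(vertices, faces, label = NULL, weld = FALSE,
                    weld_tol = 1e-9) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L)
    stop("vertices must be an n x 3 matrix")
  faces <- as.matrix(faces)
  if (nrow(faces) > 0 && ncol(faces) != 3L)
    stop("faces must be an m x 3 matrix (triangles only)")
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  if (nrow(faces) > 0 &&
      (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  if (!is.null(label))
    label <- match.arg(label, c("body", "skull", "eyes", "evaluation"))
  m <- structure(list(vertices = vertices, faces = faces, label = label),
                 class = "trimesh")
  if (weld) m <- weld_vertices(m, tol = weld_tol)
  m
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("trimesh: %d vertices, %d faces%s\n",
              nrow(x$vertices), nrow(x$faces),
              if (is.null(x$label)) "" else paste0(" [", x$label, "]")))
  invisible(x)
}

is_trimesh <- function(x) inherits(x, "trimesh")

#' Merge duplicate vertices and drop degenerate faces
#'
#' @param mesh a `trimesh`.
#' @param tol vertices closer than this (mm) are merged.
#' @return a `trimesh` with unique vertices.
#' @export
weld_vertices <- function(mesh, tol = 1e-9) {
  v <- mesh$vertices
  key <- apply(round(v / max(tol, 1e-12)), 1L, paste, collapse = ",")
  first <- !duplicated(key)
  map <- match(key, key[first])
  newv <- v[first, , drop = FALSE]
  newf <- matrix(map[mesh$faces], ncol = 3L)
  deg <- newf[, 1L] == newf[, 2L] | newf[, 2L] == newf[, 3L] |
    newf[, 1L] == newf[, 3L]
  newf <- newf[!deg, , drop = FALSE]
  trimesh(newv, newf, label = mesh$label)
}

# -- low-level geometry helpers ------------------------------------------

face_corners <- function(mesh) {
  list(a = mesh$vertices[mesh$faces[, 1L], , drop = FALSE],
       b = mesh$vertices[mesh$faces[, 2L], , drop = FALSE],
       c = mesh$vertices[mesh$faces[, 3L], , drop = FALSE])
}

cross3 <- function(u, v) {
  cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
        u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
        u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
}

#' Face normals and areas
#'
#' @param mesh a `trimesh`.
#' @return list with `normals` (m x 3 unit, winding-ordered), `areas`
#'   (mm^2) and `centroids` (mm).
#' @export
face_geometry <- function(mesh) {
  fc <- face_corners(mesh)
  cr <- cross3(fc$b - fc$a, fc$c - fc$a)
  a2 <- sqrt(rowSums(cr^2))
  n <- cr / ifelse(a2 > 0, a2, 1)
  list(normals = n, areas = a2 / 2,
       centroids = (fc$a + fc$b + fc$c) / 3)
}

#' Signed enclosed volume of a closed mesh
#'
#' Positive when face winding is outward (right-handed).
#' @param mesh a `trimesh`.
#' @return signed volume in mm^3.
#' @export
signed_volume <- function(mesh) {
  fc <- face_corners(mesh)
  sum(rowSums(fc$a * cross3(fc$b, fc$c))) / 6
}

# unique undirected edges; returns matrix (e x 2, sorted rows) and the
# count of faces adjacent to each edge
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  es <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  key <- paste(es[, 1L], es[, 2L])
  tab <- table(key)
  first <- !duplicated(key)
  uniq <- es[first, , drop = FALSE]
  deg <- as.integer(tab[paste(uniq[, 1L], uniq[, 2L])])
  list(edges = uniq, degree = deg)
}

#' Mesh summary statistics
#'
#' Vertex and face counts, unique-edge length statistics, total area and the
#' Euler characteristic V - E + F (2 for a closed genus-0 surface, additive
#' over connected components).
#'
#' @param mesh a non-empty `trimesh`.
#' @return list of class `mesh_stats` with `n_vertices`, `n_faces`,
#'   `n_edges`, `mean_edge`, `sd_edge`, `area`, `euler`.
#' @export
mesh_statistics <- function(mesh) {
  stopifnot(is_trimesh(mesh))
  if (nrow(mesh$vertices) == 0L || nrow(mesh$faces) == 0L)
    stop("mesh_statistics: empty mesh")
  ed <- mesh_edges(mesh)
  dv <- mesh$vertices[ed$edges[, 1L], , drop = FALSE] -
    mesh$vertices[ed$edges[, 2L], , drop = FALSE]
  len <- sqrt(rowSums(dv^2))
  fg <- face_geometry(mesh)
  structure(list(
    n_vertices = nrow(mesh$vertices),
    n_faces = nrow(mesh$faces),
    n_edges = nrow(ed$edges),
    mean_edge = mean(len),
    sd_edge = stats::sd(len),
    area = sum(fg$areas),
    euler = nrow(mesh$vertices) - nrow(ed$edges) + nrow(mesh$faces)
  ), class = "mesh_stats")
}

#' @export
print.mesh_stats <- function(x, ...) {
  cat(sprintf(
    "mesh: V=%d E=%d F=%d  edge %.3f +/- %.3f mm  area %.1f mm^2  chi=%d\n",
    x$n_vertices, x$n_edges, x$n_faces, x$mean_edge,
    if (is.na(x$sd_edge)) 0 else x$sd_edge, x$area, x$euler))
  invisible(x)
}

#' Validate a surface mesh
#'
#' Report-only check of the invariants expected of a conductivity boundary:
#' every edge shared by exactly two faces (closed 2-manifold), consistent
#' outward winding (positive signed volume), no zero-area faces, no
#' duplicate vertices.
#'
#' @param mesh a `trimesh`.
#' @param require_closed if `TRUE`, openness is recorded as a defect.
#' @return list of class `mesh_validation` with logical `closed`,
#'   `oriented`, integer `n_boundary_edges`, and character vector `defects`
#'   (empty when the mesh is a valid conductor boundary).
#' @export
validate_mesh <- function(mesh, require_closed = TRUE) {
  stopifnot(is_trimesh(mesh))
  defects <- character()
  ed <- mesh_edges(mesh)
  n_boundary <- sum(ed$degree == 1L)
  n_nonman <- sum(ed$degree > 2L)
  closed <- n_boundary == 0L && n_nonman == 0L
  if (n_nonman > 0L)
    defects <- c(defects, sprintf("%d non-manifold edges", n_nonman))
  if (require_closed && n_boundary > 0L)
    defects <- c(defects, sprintf("%d boundary edges", n_boundary))
  fg <- face_geometry(mesh)
  nz <- sum(fg$areas <= 1e-12)
  if (nz > 0L) defects <- c(defects, sprintf("%d zero-area faces", nz))
  key <- apply(round(mesh$vertices * 1e9), 1L, paste, collapse = ",")
  nd <- sum(duplicated(key))
  if (nd > 0L) defects <- c(defects, sprintf("%d duplicate vertices", nd))
  oriented <- NA
  if (closed) {
    sv <- signed_volume(mesh)
    oriented <- sv > 0
    if (!oriented)
      defects <- c(defects, sprintf("inward orientation (signed volume %.3g)", sv))
    # consistency of winding between neighbours: each directed edge must
    # appear exactly once
    f <- mesh$faces
    de <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
    dk <- paste(de[, 1L], de[, 2L])
    if (anyDuplicated(dk)) {
      oriented <- FALSE
      defects <- c(defects, "inconsistent face winding")
    }
  }
  structure(list(closed = closed, oriented = oriented,
                 n_boundary_edges = n_boundary, defects = defects),
            class = "mesh_validation")
}

#' @export
print.mesh_validation <- function(x, ...) {
  cat(sprintf("mesh validation: closed=%s oriented=%s, %d defect(s)\n",
              x$closed, x$oriented, length(x$defects)))
  for (d in x$defects) cat(" -", d, "\n")
  invisible(x)
}

#' Flip face orientation
#' @param mesh a `trimesh`.
#' @return the mesh with reversed winding.
#' @export
flip_faces <- function(mesh) {
  mesh$faces <- mesh$faces[, c(1L, 3L, 2L), drop = FALSE]
  mesh
}

#' Ensure outward orientation of a closed mesh
#' @param mesh a closed `trimesh`.
#' @return the mesh, flipped if its signed volume was negative.
#' @export
orient_outward <- function(mesh) {
  if (signed_volume(mesh) < 0) flip_faces(mesh) else mesh
}

#' Area-weighted vertex normals
#' @param mesh a `trimesh`.
#' @return n x 3 matrix of unit vertex normals.
#' @export
vertex_normals <- function(mesh) {
  fg <- face_geometry(mesh)
  wn <- fg$normals * fg$areas
  n <- matrix(0, nrow(mesh$vertices), 3L)
  for (k in 1:3) {
    idx <- mesh$faces[, k]
    for (j in 1:3)
      n[, j] <- n[, j] + tabulate2(idx, wn[, j], nrow(n))
  }
  len <- sqrt(rowSums(n^2))
  n / ifelse(len > 0, len, 1)
}

# sum `w` into bins `idx` of length n (base-R rowsum wrapper)
tabulate2 <- function(idx, w, n) {
  out <- numeric(n)
  s <- rowsum(w, idx)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}

#' Rigidly transform a mesh
#' @param mesh a `trimesh`.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 vector (mm).
#' @return transformed `trimesh`.
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  mesh$vertices <- sweep(mesh$vertices %*% t(rotation), 2L, -translation)
  mesh
}
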