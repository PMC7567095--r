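#' CT volume container
#'
#' A voxel grid of Hounsfield-unit values with isotropic spacing and a
#' voxel-to-world affine of the form `world = origin + spacing * index0`
#' (index0 zero-based, x fastest).
#'
#' @param data 3-d numeric array of HU values.
#' @param spacing isotropic voxel spacing in mm, > 0.
#' @param origin world position (mm) of voxel (0, 0, 0).
#' @return an object of class `ct_volume`.
#' @export
ct_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  stopifnot(length(dim(data)) == 3L, spacing > 0, length(origin) == 3L)
  if (!all(is.finite(data))) stop("ct_volume: non-finite HU values")
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("ct_volume: %s voxels, %.3g mm spacing, HU range [%.0f, %.0f]\n",
              paste(dim(x$data), collapse = " x "), x$spacing,
              min(x$data), max(x$data)))
  invisible(x)
}

#' Voxel-to-world affine (4 x 4) of a volume
#' @param vol a `ct_volume` (or a mask carrying the same metadata).
#' @return 4 x 4 matrix mapping zero-based voxel indices to mm.
#' @export
volume_affine <- function(vol) {
  A <- diag(c(rep(vol$spacing, 3L), 1))
  A[1:3, 4L] <- vol$origin
  A
}

#' Write a volume to NIfTI
#' @param vol a `ct_volume` or binary mask volume.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(vol, path) {
  img <- RNifti::asNifti(vol$data * 1.0)
  RNifti::pixdim(img) <- rep(vol$spacing, 3L)
  img <- RNifti::`sform<-`(img, structure(volume_affine(vol), code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume
#' @param path NIfTI file path.
#' @return a `ct_volume` (origin/spacing from the sform when present).
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  A <- tryCatch(structure(RNifti::xform(img), code = NULL),
                error = function(e) NULL)
  sp <- RNifti::pixdim(img)[1L]
  orig <- c(0, 0, 0)
  if (!is.null(A)) {
    # accept only axis-aligned, isotropic transforms (all this tool writes)
    S <- A[1:3, 1:3]
    if (max(abs(S - diag(diag(S)))) < 1e-6 &&
        max(abs(diag(S) - diag(S)[1L])) < 1e-6) {
      sp <- abs(diag(S)[1L])
      orig <- A[1:3, 4L]
    }
  }
  ct_volume(array(as.numeric(img), dim = dim(img)), spacing = sp,
            origin = orig)
}

# mask helper: same metadata as a ct_volume but logical data
as_mask <- function(data, like) {
  structure(list(data = data, spacing = like$spacing, origin = like$origin),
            class = "ct_volume")
}

#' Morphological closure with a spherical kernel
#'
#' Dilation followed by erosion with a spherical structuring element of the
#' given physical radius. The voxel radius is `round(radius / spacing)`
#' (round half up) so results are reproducible across spacings; distances
#' are exact (Euclidean distance transform), making the operation exactly
#' idempotent. Channels narrower than twice the radius are filled.
#'
#' @param mask a logical-valued volume (as from [segment_volume()]).
#' @param radius kernel radius in mm, >= 0.
#' @return closed mask volume.
#' @export
morph_close <- function(mask, radius) {
  stopifnot(radius >= 0)
  r <- floor(radius / mask$spacing + 0.5)   # round half up
  if (r < 1) return(mask)
  as_mask(morph_erode_vox(morph_dilate_vox(mask$data, r), r), mask)
}

morph_dilate_vox <- function(m, r_vox) {
  d2 <- .edt_squared_cpp(as.logical(m), dim(m))
  array(d2 <= r_vox^2 + 1e-9, dim = dim(m))
}

morph_erode_vox <- function(m, r_vox) {
  d2 <- .edt_squared_cpp(!as.logical(m), dim(m))
  array(d2 > r_vox^2 + 1e-9, dim = dim(m)) & m
}

#' Dilate a mask by a physical radius
#' @param mask logical-valued volume.
#' @param radius dilation radius in mm.
#' @return dilated mask volume.
#' @export
morph_dilate <- function(mask, radius) {
  r <- floor(radius / mask$spacing + 0.5)
  if (r < 1) return(mask)
  as_mask(morph_dilate_vox(mask$data, r), mask)
}

#' Connected components of a binary volume (26-connectivity)
#' @param mask logical-valued volume.
#' @return volume of integer labels (0 = background) with attribute
#'   `n_components`.
#' @export
label_components <- function(mask) {
  lab <- .label_components_cpp(as.logical(mask$data), dim(mask$data))
  out <- as_mask(array(lab, dim = dim(mask$data)), mask)
  attr(out, "n_components") <- attr(lab, "n_components")
  out
}

largest_component <- function(mask) {
  lab <- label_components(mask)
  n <- attr(lab, "n_components")
  if (n == 0L) stop("largest_component: empty mask")
  counts <- tabulate(lab$data[lab$data > 0L], n)
  as_mask(lab$data == which.max(counts), mask)
}

#' Iso-surface of a scalar or binary volume
#'
#' Marching-tetrahedra extraction at the given level, mapped to world
#' coordinates through the volume affine. Binary masks are extracted
#' directly (interface vertices at voxel-edge midpoints), which keeps
#' features at the few-voxel scale — thin bone sheets, hole rims — within
#' one voxel of the generating surface; an optional 3^3 box pre-filter
#' trades a smoother surface for erosion of such features.
#'
#' @param vol a volume (`ct_volume` or mask).
#' @param level iso level (0.5 for binary masks).
#' @param smooth_mask box-smooth binary input before extraction.
#' @return a closed `trimesh` in mm.
#' @export
iso_surface <- function(vol, level = 0.5, smooth_mask = FALSE) {
  d <- vol$data * 1.0
  if (smooth_mask && is.logical(vol$data)) d <- box_smooth3(d)
  if (any(d[1, , ] > level) || any(d[dim(d)[1L], , ] > level) ||
      any(d[, 1, ] > level) || any(d[, , 1] > level) ||
      any(d[, dim(d)[2L], ] > level) || any(d[, , dim(d)[3L]] > level))
    stop("iso_surface: mask touches the volume border; pad the volume first")
  res <- .marching_tetrahedra_cpp(as.numeric(d), dim(d), level)
  if (nrow(res$vertices) == 0L) stop("iso_surface: empty surface")
  v <- sweep(res$vertices * vol$spacing, 2L, -vol$origin)
  m <- trimesh(v, res$faces, weld = TRUE, weld_tol = 1e-9)
  orient_outward(m)
}

# 3^3 box filter with edge replication; keeps binary interfaces within the
# original voxel band while giving the iso-surface sub-voxel placement
box_smooth3 <- function(d) {
  dm <- dim(d)
  out <- array(0, dm)
  cnt <- array(0, dm)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    xs <- pmin(pmax(seq_len(dm[1L]) + dx, 1L), dm[1L])
    ys <- pmin(pmax(seq_len(dm[2L]) + dy, 1L), dm[2L])
    zs <- pmin(pmax(seq_len(dm[3L]) + dz, 1L), dm[3L])
    out <- out + d[xs, ys, zs]
    cnt <- cnt + 1
  }
  out / cnt
}

#' Distance from points to a triangle mesh
#' @param points n x 3 matrix (mm).
#' @param mesh a `trimesh`.
#' @return numeric vector of unsigned distances (mm).
#' @export
point_mesh_distance <- function(points, mesh) {
  points <- matrix(as.numeric(points), ncol = 3L)
  if (nrow(mesh$faces) < 2000L)
    return(.point_mesh_distance_cpp(points, mesh$vertices, mesh$faces))
  ed <- mesh_edges(mesh)
  dv <- mesh$vertices[ed$edges[, 1L], , drop = FALSE] -
    mesh$vertices[ed$edges[, 2L], , drop = FALSE]
  cell <- max(2 * mean(sqrt(rowSums(dv^2))), 0.5)
  .point_mesh_distance_grid_cpp(points, mesh$vertices, mesh$faces, cell)
}

#' Symmetric (vertex-sampled) Hausdorff distance between two meshes
#' @param mesh_a,mesh_b `trimesh` objects.
#' @return max over both directions of vertex-to-surface distance (mm).
#' @export
hausdorff_distance <- function(mesh_a, mesh_b) {
  max(max(point_mesh_distance(mesh_a$vertices, mesh_b)),
      max(point_mesh_distance(mesh_b$vertices, mesh_a)))
}

#' Voxelise a closed mesh on a volume grid
#' @param mesh closed `trimesh` (mm).
#' @param like a volume providing grid, spacing and origin.
#' @return logical mask volume (`TRUE` inside the mesh).
#' @export
voxelize_mesh <- function(mesh, like) {
  m <- .voxelize_mesh_cpp(mesh$vertices, mesh$faces, like$origin,
                          like$spacing, dim(like$data))
  as_mask(array(m, dim = dim(like$data)), like)
}

#' Create an empty voxel grid covering a bounding box
#' @param lower,upper bounding box corners (mm).
#' @param spacing voxel spacing (mm).
#' @param padding extra margin (mm) added on all sides.
#' @return zero-filled `ct_volume`.
#' @export
empty_grid <- function(lower, upper, spacing, padding = 2) {
  lower <- lower - padding
  upper <- upper + padding
  n <- pmax(2L, as.integer(ceiling((upper - lower) / spacing)) + 1L)
  ct_volume(array(0, n), spacing = spacing, origin = lower)
}
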