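#' Segmentation parameters
#'
#' Parameters of the CT-to-surfaces recipe: HU thresholds (automatic from
#' the histogram by default), morphological closure radii, per-surface
#' target edge lengths and the evaluation-surface margin.
#'
#' @param t_air_soft air/soft-tissue threshold (HU) or `NA` for automatic
#'   (midpoint of the two dominant histogram modes, approximately -500 HU).
#' @param t_soft_bone soft-tissue/bone threshold (HU) or `NA` for automatic
#'   (first bin after the soft-tissue mode falls below `peak_fraction` of
#'   its height).
#' @param peak_fraction soft-peak decay fraction for the automatic bone
#'   threshold.
#' @param body_closure_radius,skull_closure_radius spherical closure radii
#'   (mm).
#' @param body_edge,skull_edge,eval_edge target mean edge lengths (mm).
#' @param eval_margin evaluation-surface margin below the skull (mm).
#' @return an object of class `segmentation_params`.
#' @export
segmentation_params <- function(t_air_soft = NA, t_soft_bone = NA,
                                peak_fraction = 0.01,
                                body_closure_radius = 2,
                                skull_closure_radius = 1,
                                body_edge = 1.4, skull_edge = 0.67,
                                eval_edge = 1, eval_margin = 1) {
  if (!is.na(t_air_soft) && !is.na(t_soft_bone) &&
      t_air_soft >= t_soft_bone)
    stop("segmentation_params: thresholds must be ordered")
  stopifnot(body_closure_radius >= 0, skull_closure_radius >= 0,
            eval_margin >= 0, peak_fraction > 0, peak_fraction < 1)
  structure(list(t_air_soft = t_air_soft, t_soft_bone = t_soft_bone,
                 peak_fraction = peak_fraction,
                 body_closure_radius = body_closure_radius,
                 skull_closure_radius = skull_closure_radius,
                 body_edge = body_edge, skull_edge = skull_edge,
                 eval_edge = eval_edge, eval_margin = eval_margin),
            class = "segmentation_params")
}

#' Automatic segmentation thresholds from the CT histogram
#'
#' The air/soft threshold is placed halfway between the two dominant modes
#' of the intensity histogram (air and pooled soft tissue). The soft/bone
#' threshold is placed at the first histogram bin after the soft-tissue
#' mode whose (smoothed) count falls below `peak_fraction` of the mode
#' height — an operational version of "after the end of the soft-tissue
#' peak".
#'
#' @param ct a `ct_volume`.
#' @param peak_fraction decay fraction defining the end of the soft peak.
#' @param min_separation minimum HU separation between the two modes.
#' @return list with `t_air_soft`, `t_soft_bone` and the detected `modes`.
#' @export
find_thresholds <- function(ct, peak_fraction = 0.01, min_separation = 100) {
  stopifnot(inherits(ct, "ct_volume"))
  v <- round(as.numeric(ct$data))
  lo <- min(v); hi <- max(v)
  if (hi - lo < min_separation)
    stop("find_thresholds: histogram is unimodal; supply fixed thresholds")
  hi <- hi + 300L   # head-room so the decay criterion can fire
  counts <- tabulate(v - lo + 1L, hi - lo + 1L)
  sm <- smooth_counts(counts, width = 31L)
  # local maxima with a +/- 50 HU dominance window
  win <- 50L
  n <- length(sm)
  is_peak <- vapply(seq_len(n), function(i) {
    a <- max(1L, i - win); b <- min(n, i + win)
    sm[i] > 0 && sm[i] == max(sm[a:b]) && i == (a:b)[which.max(sm[a:b])]
  }, logical(1L))
  peaks <- which(is_peak)
  # refine each smoothed peak to the raw-count argmax nearby (exact for
  # noise-free spike histograms) and rank modes by the raw count mass in
  # their window (robust near the filter edges)
  refined <- vapply(peaks, function(i) {
    a <- max(1L, i - win); b <- min(n, i + win)
    (a:b)[which.max(counts[a:b])]
  }, integer(1L))
  strength <- vapply(peaks, function(i) {
    a <- max(1L, i - win); b <- min(n, i + win)
    sum(counts[a:b])
  }, 0)
  keep <- !duplicated(refined)
  refined <- refined[keep]; strength <- strength[keep]
  if (length(refined) < 2L)
    stop("find_thresholds: fewer than two histogram modes; ",
         "supply fixed thresholds")
  ord <- refined[order(-strength)]
  # two dominant modes, required to be well separated
  m1 <- ord[1L]
  m2 <- ord[which(abs(ord - m1) >= min_separation)[1L]]
  if (is.na(m2))
    stop("find_thresholds: dominant modes closer than ", min_separation,
         " HU; supply fixed thresholds")
  modes <- sort(c(m1, m2)) + lo - 1L
  t_air_soft <- mean(modes)
  # soft mode is the higher-HU of the two dominant modes
  soft <- max(m1, m2)
  hpeak <- sm[soft]
  after <- which(sm[soft:n] < peak_fraction * hpeak)[1L]
  if (is.na(after))
    stop("find_thresholds: soft-tissue peak does not decay; ",
         "supply a fixed bone threshold")
  t_soft_bone <- (soft + after - 1L) + lo - 1L
  list(t_air_soft = t_air_soft, t_soft_bone = t_soft_bone, modes = modes)
}

smooth_counts <- function(counts, width = 31L) {
  k <- rep(1 / width, width)
  as.numeric(stats::filter(counts, k, sides = 2L, circular = FALSE)) ->
    sm
  sm[is.na(sm)] <- 0
  sm
}

#' Label volume
#'
#' Voxel labels partitioning a CT volume: 0 = air, 1 = body (soft tissue),
#' 2 = bone; optionally 3 = brain when a brain mask is supplied.
#'
#' @param labels integer array.
#' @param like volume carrying spacing/origin.
#' @param thresholds thresholds used.
#' @return object of class `label_volume`.
#' @export
label_volume <- function(labels, like, thresholds = NULL) {
  structure(list(data = labels, spacing = like$spacing, origin = like$origin,
                 thresholds = thresholds),
            class = c("label_volume", "ct_volume"))
}

#' Mask of one label
#' @param lv a `label_volume`.
#' @param label one of `"body"`, `"bone"`, `"air"`, `"brain"`.
#' @return logical mask volume. Body includes bone (bone is inside the
#'   body); air is everything else.
#' @export
label_mask <- function(lv, label = c("body", "bone", "air", "brain")) {
  label <- match.arg(label)
  m <- switch(label,
              body = lv$data >= 1L,
              bone = lv$data == 2L,
              air = lv$data == 0L,
              brain = lv$data == 3L)
  as_mask(m, lv)
}

#' Threshold segmentation of a CT volume
#'
#' Air/body/bone segmentation: the body is the largest 26-connected
#' component above the air/soft threshold, smoothed by spherical
#' morphological closure; bone is the above-bone-threshold part of the
#' body, smoothed by its own closure.
#'
#' @param ct a `ct_volume`.
#' @param params a [segmentation_params()].
#' @return a [label_volume()].
#' @export
segment_volume <- function(ct, params = segmentation_params()) {
  stopifnot(inherits(ct, "ct_volume"))
  th <- list(t_air_soft = params$t_air_soft,
             t_soft_bone = params$t_soft_bone)
  if (is.na(th$t_air_soft) || is.na(th$t_soft_bone)) {
    auto <- find_thresholds(ct, peak_fraction = params$peak_fraction)
    if (is.na(th$t_air_soft)) th$t_air_soft <- auto$t_air_soft
    if (is.na(th$t_soft_bone)) th$t_soft_bone <- auto$t_soft_bone
  }
  if (th$t_air_soft >= th$t_soft_bone)
    stop("segment_volume: thresholds must be ordered")
  raw_body <- as_mask(ct$data > th$t_air_soft, ct)
  if (!any(raw_body$data)) stop("segment_volume: empty body mask")
  body <- largest_component(raw_body)
  body <- morph_close(body, params$body_closure_radius)
  bone <- as_mask(ct$data > th$t_soft_bone & body$data, ct)
  if (any(bone$data))
    bone <- morph_close(bone, params$skull_closure_radius)
  labels <- array(0L, dim = dim(ct$data))
  labels[body$data] <- 1L
  labels[bone$data & body$data] <- 2L
  label_volume(labels, ct, thresholds = th)
}

#' Extract a boundary surface from a binary mask
#'
#' Sub-voxel iso-surface (marching tetrahedra on the mask at level 0.5) in
#' world coordinates, then isotropic remeshing to the target edge length.
#' The result is a closed outward-oriented mesh.
#'
#' @param mask logical mask volume (must not touch the volume border).
#' @param target_edge target mean edge length (mm); `NULL` to skip
#'   remeshing.
#' @param label optional surface label.
#' @return a `trimesh`.
#' @export
extract_boundary_surface <- function(mask, target_edge = NULL,
                                     label = NULL) {
  if (!any(mask$data)) stop("extract_boundary_surface: empty mask")
  m <- iso_surface(mask, level = 0.5)
  if (!is.null(target_edge))
    m <- remesh_to_target_edge(m, target_edge)
  m$label <- label
  m
}

#' Cortical evaluation surface from brain and skull masks
#'
#' Boundary of the brain mask minus the `margin`-dilated skull mask: the
#' surface on which cortical E-fields are evaluated, kept a fixed distance
#' below the skull for numerical stability of the BEM.
#'
#' @param brain_mask,skull_mask aligned logical mask volumes.
#' @param margin clearance to the skull (mm).
#' @param target_edge optional remeshing target (mm).
#' @return a `trimesh` labelled `"evaluation"`.
#' @export
make_evaluation_surface <- function(brain_mask, skull_mask, margin = 1,
                                    target_edge = NULL) {
  stopifnot(margin >= 0,
            identical(dim(brain_mask$data), dim(skull_mask$data)))
  dil <- morph_dilate(skull_mask, margin)
  keep <- brain_mask$data & !dil$data
  if (!any(keep))
    stop("make_evaluation_surface: empty evaluation region ",
         "(margin too large)")
  extract_boundary_surface(as_mask(keep, brain_mask),
                           target_edge = target_edge, label = "evaluation")
}

#' Dice coefficient of two binary masks
#' @param a,b logical mask volumes on the same grid.
#' @return scalar in [0, 1].
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a$data), dim(b$data)))
  2 * sum(a$data & b$data) / (sum(a$data) + sum(b$data))
}
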