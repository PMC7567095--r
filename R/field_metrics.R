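#' E-field sample set
#'
#' E-field 3-vectors at a shared, ordered set of evaluation points for one
#' coil placement.
#'
#' @param points n x 3 matrix of evaluation points (mm).
#' @param E n x 3 matrix of field vectors (V/m), finite.
#' @param placement_id optional identifier of the coil placement.
#' @return an object of class `field_set`.
#' @export
field_set <- function(points, E, placement_id = NULL) {
  points <- matrix(as.numeric(points), ncol = 3L)
  E <- matrix(as.numeric(E), ncol = 3L)
  if (nrow(points) != nrow(E))
    stop("field_set: one field vector per point required")
  if (!all(is.finite(E))) stop("field_set: non-finite field values")
  structure(list(points = points, E = E, placement_id = placement_id),
            class = "field_set")
}

#' @export
print.field_set <- function(x, ...) {
  mag <- sqrt(rowSums(x$E^2))
  cat(sprintf("field_set: %d points, |E| max %.3g V/m (mean %.3g)\n",
              nrow(x$E), max(mag), mean(mag)))
  invisible(x)
}

#' Field magnitudes
#' @param fs a `field_set`.
#' @return numeric vector |E| (V/m).
#' @export
field_magnitude <- function(fs) sqrt(rowSums(fs$E^2))

check_same_points <- function(E, E_ref) {
  stopifnot(inherits(E, "field_set"), inherits(E_ref, "field_set"))
  if (nrow(E$E) != nrow(E_ref$E))
    stop("field metric: point sets differ in size")
  if (max(abs(E$points - E_ref$points)) > 1e-6)
    stop("field metric: fields are sampled on different points")
}

#' Relative error between two field sets
#'
#' `RE = ||E - E_ref|| / ||E_ref||` with the Cartesian components of all
#' points pooled into 3N-vectors. Sensitive to both magnitude and direction
#' errors.
#'
#' @param E,E_ref `field_set` objects on the same points.
#' @param subset optional point indices (e.g. from [hotspot_restrict()]);
#'   the pooled norms are then taken over the subset only.
#' @return scalar RE (dimensionless, >= 0).
#' @export
relative_error <- function(E, E_ref, subset = NULL) {
  check_same_points(E, E_ref)
  a <- E$E; b <- E_ref$E
  if (!is.null(subset)) { a <- a[subset, , drop = FALSE]
                          b <- b[subset, , drop = FALSE] }
  nb <- sqrt(sum(b^2))
  if (nb == 0) stop("relative_error: reference field is zero")
  sqrt(sum((a - b)^2)) / nb
}

#' Correlation error between two field sets
#'
#' `CCE = 1 - cos(E~, E_ref~)` where both fields are first de-meaned
#' component-wise across points and then pooled into 3N-vectors. Invariant
#' to positive rescaling of either field; 0 for perfectly correlated
#' patterns, 2 for anti-correlated ones.
#'
#' @inheritParams relative_error
#' @return scalar CCE in [0, 2].
#' @export
correlation_error <- function(E, E_ref, subset = NULL) {
  check_same_points(E, E_ref)
  a <- E$E; b <- E_ref$E
  if (!is.null(subset)) { a <- a[subset, , drop = FALSE]
                          b <- b[subset, , drop = FALSE] }
  a <- sweep(a, 2L, colMeans(a))
  b <- sweep(b, 2L, colMeans(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop("correlation_error: constant field (zero variance after de-meaning)")
  1 - sum(a * b) / (na * nb)
}

#' Mean angular error between two field sets
#'
#' Arithmetic mean over points of the angle between the two field vectors,
#' in degrees. Points where either field vanishes are excluded (their count
#' is reported as an attribute).
#'
#' @inheritParams relative_error
#' @return mean angle in degrees in [0, 180], with attribute `n_excluded`.
#' @export
mean_angular_error <- function(E, E_ref, subset = NULL) {
  check_same_points(E, E_ref)
  a <- E$E; b <- E_ref$E
  if (!is.null(subset)) { a <- a[subset, , drop = FALSE]
                          b <- b[subset, , drop = FALSE] }
  na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
  ok <- na > 0 & nb > 0
  if (!any(ok)) stop("mean_angular_error: no points with nonzero fields")
  cosang <- rowSums(a[ok, , drop = FALSE] * b[ok, , drop = FALSE]) /
    (na[ok] * nb[ok])
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  structure(mean(ang), n_excluded = sum(!ok))
}

#' Hotspot restriction of a field set
#'
#' Indices of the points where the E-field energy density exceeds 50
#' percent of its maximum, i.e. where `|E| > sqrt(0.5) * max |E|` (strict
#' inequality). The mask is always computed from the reference field; the
#' peak point itself is always included.
#'
#' @param E_ref reference `field_set`.
#' @return integer vector of point indices.
#' @export
hotspot_restrict <- function(E_ref) {
  stopifnot(inherits(E_ref, "field_set"))
  mag <- field_magnitude(E_ref)
  peak <- which.max(mag)
  sort(union(peak, which(mag > sqrt(0.5) * mag[peak])))
}

#' Distance between field maxima
#'
#' Euclidean distance between the points of maximum field magnitude of two
#' field sets on a shared point set. Ties are broken deterministically by
#' the lowest point index.
#'
#' @param E_a,E_b `field_set` objects on the same points.
#' @return distance in mm.
#' @export
peak_distance <- function(E_a, E_b) {
  check_same_points(E_a, E_b)
  ia <- which.max(field_magnitude(E_a))  # which.max takes the lowest index
  ib <- which.max(field_magnitude(E_b))
  sqrt(sum((E_a$points[ia, ] - E_b$points[ib, ])^2))
}

#' Signed projected orientation angle of the field at the peak
#'
#' The angle between the coil pointing direction and the E-field at the
#' reference peak, after projecting the field onto the coil plane; used to
#' summarise orientation-dependent direction errors.
#'
#' @param E a `field_set`.
#' @param coil a placed `coil_model`.
#' @return signed angle in degrees in (-180, 180].
#' @export
projected_orientation_angle <- function(E, coil) {
  stopifnot(inherits(E, "field_set"), inherits(coil, "coil_model"))
  R <- coil$transform$rotation
  ey <- R[, 2L]; ex <- R[, 1L]
  v <- E$E[which.max(field_magnitude(E)), ]
  vy <- sum(v * ey); vx <- sum(v * ex)
  atan2(vx, vy) * 180 / pi
}

#' Per-placement comparison of a field against a reference
#'
#' All four error metrics, whole-surface and restricted to the hotspot of
#' the reference field.
#'
#' @param E,E_ref `field_set` objects on the same points.
#' @return one-row data frame with columns `re`, `cce`, `ang`, `peak_mm`
#'   and their hotspot-restricted counterparts (`*_hot`).
#' @export
compare_fields <- function(E, E_ref) {
  hs <- hotspot_restrict(E_ref)
  data.frame(
    re = relative_error(E, E_ref),
    cce = correlation_error(E, E_ref),
    ang = as.numeric(mean_angular_error(E, E_ref)),
    peak_mm = peak_distance(E, E_ref),
    re_hot = relative_error(E, E_ref, subset = hs),
    cce_hot = if (length(hs) >= 2L)
      tryCatch(correlation_error(E, E_ref, subset = hs),
               error = function(e) NA_real_) else NA_real_,
    ang_hot = as.numeric(mean_angular_error(E, E_ref, subset = hs)),
    n_hotspot = length(hs))
}

#' Grid summary of per-placement metrics
#'
#' Mean, standard deviation, median and the 2.3/16/84/97.7 percentiles of a
#' metric over a placement grid (the percentile pairs correspond to +/- 1
#' and +/- 2 standard deviations for normal data).
#'
#' @param x numeric vector of per-placement metric values.
#' @return one-row data frame of summary statistics.
#' @export
summarize_metric <- function(x) {
  q <- stats::quantile(x, c(0.023, 0.16, 0.5, 0.84, 0.977), names = FALSE,
                       na.rm = TRUE)
  data.frame(mean = mean(x, na.rm = TRUE), sd = stats::sd(x),
             p2.3 = q[1L], p16 = q[2L], median = q[3L], p84 = q[4L],
             p97.7 = q[5L])
}
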