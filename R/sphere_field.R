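#' Spherically symmetric head model
#'
#' A sphere fitted to (part of) the inner-skull surface. The closed-form
#' TMS field in a spherically symmetric conductor does not depend on the
#' radial conductivity profile, but it is only valid for evaluation points
#' at radii smaller than the smallest distance from the sphere origin to
#' the coil windings; that validity radius is computed per placement.
#'
#' @param origin sphere centre (mm).
#' @param radius fitted radius (mm), > 0.
#' @param rms_residual RMS fit residual (mm), informational.
#' @return an object of class `sphere_model`.
#' @export
sphere_model <- function(origin, radius, rms_residual = NA_real_) {
  stopifnot(length(origin) == 3L, radius > 0)
  structure(list(origin = as.numeric(origin), radius = as.numeric(radius),
                 rms_residual = rms_residual),
            class = "sphere_model")
}

#' @export
print.sphere_model <- function(x, ...) {
  cat(sprintf("sphere_model: origin (%.2f, %.2f, %.2f) mm, radius %.2f mm\n",
              x$origin[1L], x$origin[2L], x$origin[3L], x$radius))
  invisible(x)
}

#' Fit a sphere to a local surface region
#'
#' Least-squares sphere through the surface vertices within `region_radius`
#' of `region_center`: an algebraic (Pratt-style linear) fit followed by
#' Gauss-Newton refinement of the geometric distance.
#'
#' @param surface a `trimesh` (typically the inner-skull surface).
#' @param region_center centre of the fitting region (mm).
#' @param region_radius radius of the fitting region (mm).
#' @return a [sphere_model()] with the RMS residual of the geometric fit.
#' @export
fit_local_sphere <- function(surface, region_center, region_radius) {
  stopifnot(is_trimesh(surface), region_radius > 0)
  v <- surface$vertices
  d <- sqrt(colSums((t(v) - region_center)^2))
  pts <- v[d <= region_radius, , drop = FALSE]
  if (nrow(pts) < 10L)
    stop("fit_local_sphere: fewer than 10 vertices in the region")
  # algebraic fit: |x|^2 = 2 c.x + k
  A <- cbind(2 * pts, 1)
  b <- rowSums(pts^2)
  beta <- tryCatch(qr.solve(A, b),
                   error = function(e)
                     stop("fit_local_sphere: degenerate (coplanar) patch"))
  ctr <- beta[1:3]
  r2 <- beta[4L] + sum(ctr^2)
  if (!is.finite(r2) || r2 <= 0)
    stop("fit_local_sphere: degenerate (coplanar) patch")
  r <- sqrt(r2)
  if (r > 1e3 * region_radius)
    stop("fit_local_sphere: degenerate (coplanar) patch")
  # Gauss-Newton refinement of sum (|x - c| - r)^2
  for (it in 1:20) {
    dv <- sweep(pts, 2L, ctr)
    dist <- sqrt(rowSums(dv^2))
    resid <- dist - r
    J <- cbind(-dv / dist, -1)
    step <- tryCatch(qr.solve(J, -resid), error = function(e) rep(0, 4))
    ctr <- ctr + step[1:3]
    r <- r + step[4L]
    if (max(abs(step)) < 1e-10) break
  }
  dist <- sqrt(rowSums(sweep(pts, 2L, ctr)^2))
  sphere_model(ctr, r, rms_residual = sqrt(mean((dist - r)^2)))
}

#' Magnetic field of a current dipole in a spherically symmetric conductor
#'
#' Closed-form external magnetic field of a current dipole inside a
#' spherically symmetric conductor (the classical sphere-model solution of
#' the MEG forward problem). The field is independent of the radial
#' conductivity profile, and radial dipoles are magnetically silent.
#'
#' @param moment dipole moment (A m), length-3.
#' @param position dipole position (mm), strictly inside the sphere of the
#'   field point.
#' @param origin sphere origin (mm).
#' @param points field points (n x 3, mm), strictly farther from the origin
#'   than the dipole.
#' @return n x 3 matrix of B vectors (T).
#' @export
sphere_magnetic_forward <- function(moment, position, origin, points) {
  points <- matrix(as.numeric(points), ncol = 3L)
  q <- as.numeric(moment)                 # A m
  rq <- (as.numeric(position) - as.numeric(origin)) * 1e-3   # m
  R <- sweep(points, 2L, as.numeric(origin)) * 1e-3          # m
  rq_n <- sqrt(sum(rq^2))
  r_n <- sqrt(rowSums(R^2))
  if (any(r_n <= rq_n + 1e-12))
    stop("sphere_magnetic_forward: field point not outside the source radius")
  if (rq_n < 1e-15) return(matrix(0, nrow(points), 3L))  # dipole at origin
  a_v <- R - matrix(rq, nrow(R), 3L, byrow = TRUE)
  a_n <- sqrt(rowSums(a_v^2))
  rq_dot_r <- as.numeric(R %*% rq)
  f <- a_n * (r_n * a_n + r_n^2 - rq_dot_r)
  if (any(abs(f) < 1e-30))
    stop("sphere_magnetic_forward: field point on the singular set")
  a_dot_r <- rowSums(a_v * R)
  cf1 <- a_n^2 / r_n + a_dot_r / a_n + 2 * a_n + 2 * r_n
  cf2 <- a_n + 2 * r_n + a_dot_r / a_n
  gradf <- R * cf1 - matrix(rq, nrow(R), 3L, byrow = TRUE) * cf2
  qxrq <- c(q[2L] * rq[3L] - q[3L] * rq[2L],
            q[3L] * rq[1L] - q[1L] * rq[3L],
            q[1L] * rq[2L] - q[2L] * rq[1L])
  qxrq_dot_r <- as.numeric(R %*% qxrq)
  1e-7 * (matrix(qxrq, nrow(R), 3L, byrow = TRUE) * f - gradf * qxrq_dot_r) /
    f^2
}

#' Validity radius of a sphere model for a placed coil
#' @param model a `sphere_model`.
#' @param coil a placed `coil_model`.
#' @return smallest origin-to-coil-dipole distance (mm).
#' @export
sphere_validity_radius <- function(model, coil) {
  wd <- coil_world_dipoles(coil)
  min(sqrt(colSums((t(wd$positions) - model$origin)^2)))
}

#' TMS-induced E-field in the spherically symmetric model
#'
#' Reciprocity with the sphere-model magnetic forward solution: the
#' component of E along a unit dipole at an evaluation point equals
#' `-dIdt` times the flux of that dipole's closed-form magnetic field
#' through the coil quadrature. The resulting E is exactly tangential
#' (zero radial component) and independent of the conductivity profile.
#'
#' @param model a `sphere_model`.
#' @param coil a placed `coil_model`.
#' @param dIdt coil current rate of change (A/s).
#' @param points evaluation points (n x 3, mm); all must lie strictly
#'   inside the validity radius.
#' @return a [field_set()] with E in V/m.
#' @export
sphere_efield <- function(model, coil, dIdt, points) {
  stopifnot(inherits(model, "sphere_model"), inherits(coil, "coil_model"))
  points <- matrix(as.numeric(points), ncol = 3L)
  vr <- sphere_validity_radius(model, coil)
  pr <- sqrt(colSums((t(points) - model$origin)^2))
  bad <- which(pr >= vr)
  if (length(bad) > 0L)
    stop("sphere_efield: point(s) ", paste(utils::head(bad, 5L),
                                           collapse = ", "),
         " outside the validity radius (", signif(vr, 4), " mm)")
  wd <- coil_world_dipoles(coil)
  cp <- sweep(wd$positions, 2L, model$origin) * 1e-3   # m, origin frame
  wm <- wd$normals * wd$weights * 1e-6                 # m^2, signed
  P <- sweep(points, 2L, model$origin) * 1e-3
  E <- matrix(0, nrow(P), 3L)
  r_n <- sqrt(rowSums(cp^2))
  for (i in seq_len(nrow(P))) {
    p <- P[i, ]
    rq_n <- sqrt(sum(p^2))
    a_v <- sweep(cp, 2L, p)
    a_n <- sqrt(rowSums(a_v^2))
    rq_dot_r <- as.numeric(cp %*% p)
    f <- a_n * (r_n * a_n + r_n^2 - rq_dot_r)
    a_dot_r <- rowSums(a_v * cp)
    cf1 <- a_n^2 / r_n + a_dot_r / a_n + 2 * a_n + 2 * r_n
    cf2 <- a_n + 2 * r_n + a_dot_r / a_n
    # flux of unit-dipole fields through the coil reduces to p x V with
    # V = sum_k w_k [ m_k / F_k - r_k (gradF_k . m_k) / F_k^2 ]
    gf_dot_m <- rowSums(cp * wm) * cf1 - as.numeric(wm %*% p) * cf2
    V <- colSums(wm / f) - colSums(cp * (gf_dot_m / f^2))
    flux <- c(p[2L] * V[3L] - p[3L] * V[2L],
              p[3L] * V[1L] - p[1L] * V[3L],
              p[1L] * V[2L] - p[2L] * V[1L])
    E[i, ] <- -dIdt * 1e-7 * flux
  }
  field_set(points, E)
}
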