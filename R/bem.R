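#' Assemble the linear-collocation BEM system
#'
#' Discretises the surface-potential boundary integral equation of a
#' piecewise-homogeneous conductor with linear (hat) basis functions
#' collocated at the surface vertices. Element integrals of the
#' double-layer (solid-angle) kernel are evaluated analytically for planar
#' triangles, which keeps near-singular sheet-to-sheet interactions (thin
#' skull) accurate. The diagonal is then fixed by the solid-angle closure
#' condition: the total solid angle of the collocation point's own surface
#' is forced to exactly 2 pi, which makes a constant potential an exact
#' discrete null vector (the gauge freedom removed later by deflation).
#'
#' All geometry enters in mm and is converted to metres here — the single
#' unit-conversion point of the solver.
#'
#' @param model a [compartment_model()].
#' @return an object of class `bem_system` (unsolved): the collocation
#'   matrix, stacked vertex coordinates, per-surface index offsets,
#'   conductivity vectors and bookkeeping. The matrix is used in place by
#'   [build_deflated_system()].
#' @export
assemble_double_layer <- function(model) {
  stopifnot(inherits(model, "compartment_model"))
  ns <- length(model$surfaces)
  nvs <- vapply(model$surfaces, function(s) nrow(s$vertices), 0L)
  offsets <- c(0L, cumsum(nvs))
  N <- offsets[ns + 1L]
  X <- do.call(rbind, lapply(model$surfaces, `[[`, "vertices")) * 1e-3
  jump <- model$sigma_in - model$sigma_out
  sigma_bar <- rep((model$sigma_in + model$sigma_out) / 2, nvs)
  A <- matrix(0, N, N)
  for (l in seq_len(ns)) {
    Vl <- model$surfaces[[l]]$vertices * 1e-3
    Fl <- model$surfaces[[l]]$faces
    scale <- -jump[l] / (4 * pi)
    rs <- .assemble_double_layer_into_cpp(A, offsets[l], scale, X, Vl, Fl)
    rows <- (offsets[l] + 1L):offsets[l + 1L]
    idx <- cbind(rows, rows)
    A[idx] <- A[idx] + scale * (2 * pi - rs[rows])
  }
  diag(A) <- diag(A) + sigma_bar
  me <- vapply(model$surfaces,
               function(s) mesh_statistics(s)$mean_edge, 0)
  structure(list(matrix = A, model = model, offsets = offsets,
                 vertices_m = X, sigma_bar = sigma_bar, jump = jump,
                 mean_edge_mm = me, deflated = FALSE, ipiv = NULL),
            class = "bem_system")
}

#' @export
print.bem_system <- function(x, ...) {
  cat(sprintf("bem_system: %d vertices on %d surface(s), %s\n",
              nrow(x$matrix), length(x$model$surfaces),
              if (x$deflated) "deflated + factorised" else "unsolved"))
  invisible(x)
}

#' Deflate and factorise a BEM system
#'
#' The collocation operator of an insulated conductor has a constant
#' potential in its null space (the reference-potential gauge). A rank-one
#' deflation `A + c 11^T / N` (c of the order of the mean conductivity)
#' removes it, after which the matrix is LU-factorised. The factorisation
#' happens in place: the system's matrix storage is reused, and repeated
#' solves reuse the cached factors.
#'
#' @param system a `bem_system` from [assemble_double_layer()].
#' @return the system with `deflated = TRUE` and factors cached.
#' @export
build_deflated_system <- function(system) {
  stopifnot(inherits(system, "bem_system"))
  if (system$deflated) return(system)
  N <- nrow(system$matrix)
  .add_constant_inplace_cpp(system$matrix, mean(system$sigma_bar) / N)
  system$ipiv <- .lu_factor_inplace_cpp(system$matrix)
  system$deflated <- TRUE
  system
}

# internal: distance-based numerical stability margin (mm)
check_source_margin <- function(system, points_mm, what = "dipole") {
  for (l in seq_along(system$model$surfaces)) {
    d <- point_mesh_distance(points_mm, system$model$surfaces[[l]])
    lim <- 0.5 * system$mean_edge_mm[l]
    if (any(d < lim))
      stop(what, " too close to surface ", l, ": distance ",
           signif(min(d), 3), " mm < stability margin ",
           signif(lim, 3), " mm")
  }
  invisible(TRUE)
}

inside_surface <- function(surface, points_mm) {
  om <- .surface_solid_angle_cpp(points_mm * 1e-3,
                                 surface$vertices * 1e-3, surface$faces)
  om > 2 * pi
}

#' Solve the surface potentials for a current dipole
#'
#' @param system a deflated `bem_system`.
#' @param moment dipole moment (A m), length 3.
#' @param position dipole position (mm), strictly inside the conductor and
#'   at least half a mean edge length away from every surface.
#' @param check verify the position preconditions (disable only in inner
#'   loops that have already checked).
#' @return object of class `potential_solution` with `phi` (V, one value
#'   per collocation vertex; defined up to the deflated constant), and the
#'   source description.
#' @export
solve_surface_potentials <- function(system, moment, position, check = TRUE) {
  stopifnot(inherits(system, "bem_system"))
  if (!system$deflated)
    stop("solve_surface_potentials: call build_deflated_system() first")
  position <- as.numeric(position)
  if (check) {
    if (!inside_surface(system$model$surfaces[[1L]], matrix(position, 1L)))
      stop("solve_surface_potentials: dipole outside the conductor")
    check_source_margin(system, matrix(position, 1L))
  }
  p <- as.numeric(moment)
  if (all(p == 0))
    return(structure(list(phi = numeric(nrow(system$matrix)),
                          moment = p, position = position),
                     class = "potential_solution"))
  d <- sweep(system$vertices_m, 2L, position * 1e-3)
  r3 <- rowSums(d^2)^1.5
  s <- as.numeric(d %*% p) / (4 * pi * r3)
  phi <- .lu_solve_cpp(system$matrix, system$ipiv,
                       matrix(s, ncol = 1L), 0L)[, 1L]
  structure(list(phi = phi, moment = p, position = position),
            class = "potential_solution")
}

# Geselowitz magnetic field sign convention:
#   B(r) = B_inf(r) - (mu0/4pi) sum_l (sigma_in - sigma_out)_l
#            int_{S_l} phi n x (r - y)/|r - y|^3 dS
GESELOWITZ_SIGN <- -1

#' Magnetic field outside a conductor via the Geselowitz formula
#'
#' `B = B_inf + (mu0/4pi) sum_l (sigma_l^- - sigma_l^+) int phi n x
#' (r-y)/|r-y|^3 dS`, evaluated with linear-basis surface quadrature.
#' The per-surface potentials are de-meaned before integration; a constant
#' potential contributes nothing to B on a closed surface, so this makes
#' the discrete result exactly gauge invariant.
#'
#' @param model the `compartment_model` the solution belongs to.
#' @param solution a `potential_solution`.
#' @param points field points (n x 3, mm), outside the conductor.
#' @param system the `bem_system` (provides surface offsets).
#' @param quad_points surface quadrature rule: 1 (centroid) or 3 (edge
#'   midpoints).
#' @param check verify that the points are outside the conductor.
#' @return n x 3 matrix of B vectors (T).
#' @export
geselowitz_bfield <- function(model, solution, points, system,
                              quad_points = 1L, check = TRUE) {
  stopifnot(inherits(model, "compartment_model"),
            inherits(solution, "potential_solution"))
  points <- matrix(as.numeric(points), ncol = 3L)
  if (check && any(inside_surface(model$surfaces[[1L]], points)))
    stop("geselowitz_bfield: field point inside the conductor")
  P <- points * 1e-3
  p <- solution$moment
  rp <- solution$position * 1e-3
  d <- sweep(P, 2L, rp)
  r3 <- rowSums(d^2)^1.5
  B <- 1e-7 * cross3(matrix(p, nrow(P), 3L, byrow = TRUE), d) / r3
  for (l in seq_along(model$surfaces)) {
    rows <- (system$offsets[l] + 1L):system$offsets[l + 1L]
    phi <- solution$phi[rows]
    phi <- phi - mean(phi)
    B <- B + GESELOWITZ_SIGN * 1e-7 * system$jump[l] *
      .geselowitz_surface_B_cpp(model$surfaces[[l]]$vertices * 1e-3,
                                model$surfaces[[l]]$faces, phi, P,
                                as.integer(quad_points))
  }
  B
}

#' TMS-induced E-field via reciprocity with the BEM forward solution
#'
#' The E-field component along a unit dipole at an evaluation point equals
#' `-dIdt` times the magnetic flux of that dipole through the coil. The
#' flux of the secondary (volume-current) field is a linear functional of
#' the surface potentials, so one transfer solve per coil placement
#' (`A^T t = g`) turns every evaluation point into a cheap inner product —
#' the standard reciprocal speed-up; results are identical to solving the
#' three unit-dipole problems per point.
#'
#' @param model the `compartment_model`.
#' @param system the deflated `bem_system` for `model`.
#' @param coil a placed `coil_model`.
#' @param dIdt coil current rate of change (A/s).
#' @param points evaluation points (n x 3, mm) inside the conductor, at
#'   least half a mean edge from every surface.
#' @param quad_points flux quadrature rule (1 or 3 points per triangle).
#' @param check verify point preconditions.
#' @return a [field_set()] with E in V/m.
#' @export
bem_efield <- function(model, system, coil, dIdt, points,
                       quad_points = 1L, check = TRUE) {
  stopifnot(inherits(model, "compartment_model"),
            inherits(system, "bem_system"), inherits(coil, "coil_model"))
  if (!system$deflated)
    stop("bem_efield: call build_deflated_system() first")
  points <- matrix(as.numeric(points), ncol = 3L)
  if (check) {
    inside <- inside_surface(model$surfaces[[1L]], points)
    if (!all(inside))
      stop("bem_efield: point(s) ",
           paste(utils::head(which(!inside), 5L), collapse = ", "),
           " outside the conductor")
    check_source_margin(system, points, what = "evaluation point")
  }
  wd <- coil_world_dipoles(coil)
  C <- wd$positions * 1e-3
  WM <- wd$normals * wd$weights * 1e-6
  g <- numeric(nrow(system$vertices_m))
  for (l in seq_along(model$surfaces)) {
    rows <- (system$offsets[l] + 1L):system$offsets[l + 1L]
    gl <- GESELOWITZ_SIGN * 1e-7 * system$jump[l] *
      .geselowitz_flux_vector_cpp(model$surfaces[[l]]$vertices * 1e-3,
                                  model$surfaces[[l]]$faces, C, WM,
                                  as.integer(quad_points))
    g[rows] <- gl - mean(gl)   # per-surface gauge projection
  }
  t_vec <- .lu_solve_cpp(system$matrix, system$ipiv,
                         matrix(g, ncol = 1L), 1L)[, 1L]
  flux_sec <- .transfer_contract_cpp(system$vertices_m, t_vec,
                                     points * 1e-3)
  E_inf <- primary_efield(coil, dIdt, points)$E
  field_set(points, E_inf - dIdt * flux_sec)
}

#' Raw double-layer element integrals of one surface
#'
#' The matrix of analytically integrated hat-function solid-angle kernels
#' `D_ij = int psi_j (y - x_i).n/|y - x_i|^3 dS`, exposed for closure and
#' convergence diagnostics.
#'
#' @param points collocation points (n x 3, mm).
#' @param surface a `trimesh`.
#' @return n x nv matrix (dimensionless steradian weights).
#' @export
double_layer_matrix <- function(points, surface) {
  .assemble_double_layer_cpp(matrix(as.numeric(points), ncol = 3L) * 1e-3,
                             surface$vertices * 1e-3, surface$faces)
}
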