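#' Figure-of-eight coil winding specification
#'
#' Geometry of a small figure-of-eight TMS coil described by its winding
#' envelope: two wings wound in opposite senses, each with several layers
#' of circular turns stacked over the wire height. Defaults correspond to a
#' commercial 24/47 mm butterfly coil with two wings of three layers of
#' four turns, 9-mm wire stack and 2-mm bottom insulation.
#'
#' @param inner_diameter inner winding diameter (mm).
#' @param outer_diameter outer winding diameter (mm).
#' @param wire_height wire stack height (mm).
#' @param bottom_insulation casing thickness between the lowermost wire
#'   surface and the coil face (mm).
#' @param layers_per_wing number of winding layers per wing.
#' @param turns_per_layer circular turns per layer.
#' @param dipole_layers heights of the dipole layers above the lowermost
#'   wire surface (mm); the default three layers sample the stack at 1.5,
#'   4.5 and 7.5 mm, and a single mid-height layer `4.5` gives the thin-coil
#'   simplification.
#' @param samples_per_turn azimuthal dipole samples per turn (>= 8).
#' @return an object of class `coil_spec`.
#' @export
coil_spec <- function(inner_diameter = 24, outer_diameter = 47,
                      wire_height = 9, bottom_insulation = 2,
                      layers_per_wing = 3L, turns_per_layer = 4L,
                      dipole_layers = c(1.5, 4.5, 7.5),
                      samples_per_turn = 32L) {
  if (inner_diameter >= outer_diameter)
    stop("coil_spec: inner diameter must be smaller than outer diameter")
  if (any(dipole_layers < 0 | dipole_layers > wire_height))
    stop("coil_spec: dipole layers must lie within the wire stack")
  if (samples_per_turn < 8L) stop("coil_spec: need >= 8 samples per turn")
  structure(list(inner_diameter = inner_diameter,
                 outer_diameter = outer_diameter,
                 wire_height = wire_height,
                 bottom_insulation = bottom_insulation,
                 layers_per_wing = as.integer(layers_per_wing),
                 turns_per_layer = as.integer(turns_per_layer),
                 dipole_layers = dipole_layers,
                 samples_per_turn = as.integer(samples_per_turn)),
            class = "coil_spec")
}

#' Magnetic-dipole quadrature of a figure-of-eight coil
#'
#' Each turn is approximated as a planar circular loop at its layer height,
#' with turn radii evenly spaced between the inner and outer winding radius.
#' A loop of area `pi r^2` is partitioned into `samples_per_turn` magnetic
#' dipoles of equal area weight placed on the loop. The two wings are
#' centred at +/- the outer winding radius along the coil long axis (x) and
#' carry opposite winding sense, expressed as opposite weight signs; loop
#' normals are +z in the coil frame (away from the head when placed).
#'
#' The coil frame has its origin at the coil-face centre; dipole layers sit
#' at `bottom_insulation + dipole_layers` above the face. Sign convention:
#' with positive weights on the -x wing, a positive current-rate `dIdt`
#' drives the primary E-field under the coil centre along the coil-frame
#' +y axis (the "pointing" direction used for placement angles).
#'
#' @param spec a [coil_spec()].
#' @return an object of class `coil_model`: `positions` (K x 3 mm, coil
#'   frame), `normals` (K x 3, unit), `weights` (K, signed mm^2), and
#'   `transform` (rigid coil-to-world map, identity until placed).
#' @export
build_figure8_quadrature <- function(spec = coil_spec()) {
  stopifnot(inherits(spec, "coil_spec"))
  r_in <- spec$inner_diameter / 2
  r_out <- spec$outer_diameter / 2
  radii <- seq(r_in, r_out, length.out = spec$turns_per_layer)
  n_layers <- length(spec$dipole_layers)
  # each dipole layer represents layers_per_wing / n_layers physical layers
  layer_mult <- spec$layers_per_wing / n_layers
  ang <- (seq_len(spec$samples_per_turn) - 0.5) * 2 * pi /
    spec$samples_per_turn
  pos <- list(); wgt <- numeric(0)
  for (wing in c(-1, 1)) {
    cx <- wing * r_out
    sgn <- wing   # +x wing positive: +y primary E under the centre
    for (z in spec$bottom_insulation + spec$dipole_layers) {
      for (r in radii) {
        w <- layer_mult * pi * r^2 / spec$samples_per_turn
        pos[[length(pos) + 1L]] <-
          cbind(cx + r * cos(ang), r * sin(ang), z)
        wgt <- c(wgt, rep(sgn * w, spec$samples_per_turn))
      }
    }
  }
  positions <- do.call(rbind, pos)
  structure(list(positions = positions,
                 normals = matrix(rep(c(0, 0, 1), each = nrow(positions)),
                                  ncol = 3L),
                 weights = wgt,
                 spec = spec,
                 transform = list(rotation = diag(3),
                                  translation = c(0, 0, 0))),
            class = "coil_model")
}

#' @export
print.coil_model <- function(x, ...) {
  cat(sprintf("coil_model: %d dipoles, |weight| per wing %.1f mm^2\n",
              length(x$weights), sum(abs(x$weights)) / 2))
  invisible(x)
}

#' Coil placement on the scalp
#'
#' @param position scalp position (mm).
#' @param angle orientation angle in degrees, measured in the tangent plane
#'   from the posterior-anterior reference direction (`0` = PA); stored
#'   modulo 360.
#' @param normal outward scalp unit normal at `position`.
#' @param reference world direction whose tangential projection defines the
#'   0-degree (PA) orientation; default +x (anterior).
#' @return an object of class `coil_placement`.
#' @export
coil_placement <- function(position, angle = 0, normal,
                           reference = c(1, 0, 0)) {
  nn <- sqrt(sum(normal^2))
  if (!is.finite(nn) || nn < 1e-9)
    stop("coil_placement: degenerate normal")
  structure(list(position = as.numeric(position),
                 angle = as.numeric(angle) %% 360,
                 normal = as.numeric(normal) / nn,
                 reference = as.numeric(reference)),
            class = "coil_placement")
}

#' Place a coil tangentially on the scalp
#'
#' Positions the coil face orthogonally to the scalp normal at
#' `position + standoff * normal`, with the coil pointing direction (coil
#' frame +y, the primary-E direction under the centre) rotated by the
#' placement angle from the tangential projection of the PA reference.
#'
#' @param coil a `coil_model`.
#' @param placement a [coil_placement()].
#' @param standoff extra coil-to-scalp distance along the normal (mm).
#' @return the coil with its rigid transform set (positions/normals remain
#'   stored in the coil frame; use [coil_world_dipoles()] to materialise).
#' @export
place_coil_tangential <- function(coil, placement, standoff = 0) {
  stopifnot(inherits(coil, "coil_model"), inherits(placement, "coil_placement"))
  n <- placement$normal
  ref <- placement$reference
  e0 <- ref - sum(ref * n) * n
  if (sqrt(sum(e0^2)) < 1e-9)
    stop("place_coil_tangential: reference direction parallel to normal")
  e0 <- e0 / sqrt(sum(e0^2))
  th <- placement$angle * pi / 180
  ey <- cos(th) * e0 + sin(th) * c(n[2] * e0[3] - n[3] * e0[2],
                                   n[3] * e0[1] - n[1] * e0[3],
                                   n[1] * e0[2] - n[2] * e0[1])
  ez <- n
  ex <- c(ey[2] * ez[3] - ey[3] * ez[2],
          ey[3] * ez[1] - ey[1] * ez[3],
          ey[1] * ez[2] - ey[2] * ez[1])
  R <- cbind(ex, ey, ez)
  coil$transform <- list(rotation = R,
                         translation = placement$position + standoff * n)
  coil$placement <- placement
  coil
}

#' Coil dipoles in world coordinates
#' @param coil a `coil_model` (placed or not).
#' @return list with `positions` (mm), `normals` (unit) and `weights`
#'   (signed mm^2) in world coordinates.
#' @export
coil_world_dipoles <- function(coil) {
  R <- coil$transform$rotation
  t <- coil$transform$translation
  list(positions = sweep(coil$positions %*% t(R), 2L, -t),
       normals = coil$normals %*% t(R),
       weights = coil$weights)
}

#' Primary (infinite-medium) electric field of a coil
#'
#' The induced E-field of the coil quadrature in an unbounded homogeneous
#' medium:
#' `E(r) = -(mu0 / 4 pi) dIdt sum_k w_k n_k x (r - r_k) / |r - r_k|^3`.
#' This is the field used by line-navigation-style dosing and by the
#' overestimation-factor comparison; it ignores all conductivity boundaries.
#'
#' @param coil a (placed) `coil_model`.
#' @param dIdt coil current rate of change (A/s).
#' @param points evaluation points (n x 3, mm, world frame).
#' @return a [field_set()] with E in V/m.
#' @export
primary_efield <- function(coil, dIdt, points) {
  points <- matrix(as.numeric(points), ncol = 3L)
  wd <- coil_world_dipoles(coil)
  cp <- wd$positions * 1e-3          # m
  wm <- wd$normals * wd$weights * 1e-6  # m^2, signed
  P <- points * 1e-3
  mu0_4pi <- 1e-7
  E <- matrix(0, nrow(P), 3L)
  for (k in seq_len(nrow(cp))) {
    d <- sweep(P, 2L, cp[k, ])
    r2 <- rowSums(d^2)
    if (any(r2 < (1e-9)^2))
      stop("primary_efield: evaluation point coincides with a coil dipole")
    # w_k n_k x (r - r_k) / |r - r_k|^3
    E <- E + cross3(matrix(wm[k, ], nrow(P), 3L, byrow = TRUE), d) /
      (r2 * sqrt(r2))
  }
  field_set(points, -mu0_4pi * dIdt * E)
}

#' Export a coil quadrature as a point table
#' @param coil a `coil_model`.
#' @param path optional CSV path; when given the table is written there.
#' @return data frame with columns x, y, z, nx, ny, nz, w (world frame).
#' @export
coil_as_pointset <- function(coil, path = NULL) {
  wd <- coil_world_dipoles(coil)
  df <- data.frame(x = wd$positions[, 1L], y = wd$positions[, 2L],
                   z = wd$positions[, 3L], nx = wd$normals[, 1L],
                   ny = wd$normals[, 2L], nz = wd$normals[, 3L],
                   w = wd$weights)
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
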