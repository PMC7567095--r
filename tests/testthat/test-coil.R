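test_that("quadrature weights close the winding areas", {
  # single circular loop: weights sum to pi a^2
  one <- coil_spec(inner_diameter = 20, outer_diameter = 20.000001,
                   layers_per_wing = 1, turns_per_layer = 1,
                   dipole_layers = 4.5)
  # degenerate inner==outer is rejected; use a 1-turn spec instead
  expect_error(coil_spec(inner_diameter = 20, outer_diameter = 20))
  m1 <- build_figure8_quadrature(one)
  wing <- m1$weights[m1$positions[, 1L] > 0]
  expect_equal(sum(abs(wing)), pi * 10^2, tolerance = 1e-7)

  # default coil: 2 wings x 3 layers x 4 turns x 32 samples
  cd <- build_figure8_quadrature(coil_spec())
  expect_equal(length(cd$weights), 768L)
  expect_equal(sum(cd$weights), 0)   # figure-of-eight antisymmetry
  # |weight| per wing = 3 layers x sum of the 4 turn areas, radii 12..23.5
  radii <- seq(12, 23.5, length.out = 4)
  expect_equal(sum(abs(cd$weights)) / 2, 3 * sum(pi * radii^2),
               tolerance = 1e-9)
  # flux of a uniform axial 1-T field through one wing
  wing_w <- cd$weights[cd$positions[, 1L] > 0]
  expect_equal(sum(abs(wing_w)) * 1, 3 * sum(pi * radii^2) * 1,
               tolerance = 1e-9)
  # single-layer simplification keeps the total winding weight
  c1 <- build_figure8_quadrature(coil_spec(dipole_layers = 4.5))
  expect_equal(sum(abs(c1$weights)), sum(abs(cd$weights)), tolerance = 1e-9)
})

test_that("tangential placement geometry and symmetries", {
  coil <- build_figure8_quadrature(coil_spec())
  pl0 <- coil_placement(c(0, 0, 15), angle = 0, normal = c(0, 0, 1))
  pl180 <- coil_placement(c(0, 0, 15), angle = 180, normal = c(0, 0, 1))
  c0 <- coil_world_dipoles(place_coil_tangential(coil, pl0))
  c180 <- coil_world_dipoles(place_coil_tangential(coil, pl180))
  # 180-degree rotation maps the dipole set onto itself with flipped signs
  key <- function(p) paste(round(p[, 1L], 6), round(p[, 2L], 6),
                           round(p[, 3L], 6))
  i <- match(key(c0$positions), key(c180$positions))
  expect_false(anyNA(i))
  expect_equal(c180$weights[i], -c0$weights, tolerance = 1e-9)

  # 360 degrees is the identity
  pl360 <- coil_placement(c(0, 0, 15), angle = 360, normal = c(0, 0, 1))
  c360 <- place_coil_tangential(coil, pl360)
  expect_equal(c360$transform$rotation,
               place_coil_tangential(coil, pl0)$transform$rotation,
               tolerance = 1e-12)

  # all dipoles stay at least the bottom insulation above the scalp plane
  placed <- place_coil_tangential(coil, pl0, standoff = 0)
  wd <- coil_world_dipoles(placed)
  heights <- wd$positions[, 3L] - 15
  expect_gte(min(heights), coil_spec()$bottom_insulation - 1e-9)

  expect_error(coil_placement(c(0, 0, 15), normal = c(0, 0, 0)),
               "degenerate")
})

test_that("primary E-field is linear, zero at dIdt 0, and matches a
           line-current loop for one dipole", {
  coil <- placed_default_coil()
  pts <- rbind(c(0, 0, 10), c(3, -2, 8), c(-5, 1, 0))
  expect_equal(primary_efield(coil, 0, pts)$E, matrix(0, 3, 3))
  E1 <- primary_efield(coil, 50e6, pts)$E
  E2 <- primary_efield(coil, 100e6, pts)$E
  expect_equal(E2, 2 * E1, tolerance = 1e-12)

  # single magnetic dipole vs brute-force loop integration at distance
  # much larger than the loop radius
  a <- 1.5   # mm loop radius
  dip <- structure(list(
    positions = matrix(c(0, 0, 0), 1),
    normals = matrix(c(0, 0, 1), 1),
    weights = pi * a^2,
    transform = list(rotation = diag(3), translation = c(0, 0, 0))),
    class = "coil_model")
  far <- rbind(c(25, 5, 10), c(-18, 22, 4), c(0, 8, -30))
  Ed <- primary_efield(dip, 50e6, far)$E
  El <- loop_primary_efield(c(0, 0, 0), c(0, 0, 1), a, 50e6, far)
  expect_lt(max(sqrt(rowSums((Ed - El)^2)) / sqrt(rowSums(El^2))), 0.01)
})

test_that("PA sign convention: positive dIdt drives E along the pointing
           direction under the centre", {
  coil <- placed_default_coil()   # PA on top of the sphere, ref +x
  E <- primary_efield(coil, 50e6, matrix(c(0, 0, 13), 1))$E
  expect_gt(E[1L], 0)
  expect_lt(abs(E[2L]), 1e-9 * abs(E[1L]))
})

test_that("azimuthal quadrature is converged at the default sampling", {
  sph <- sphere_model(c(0, 0, 0), 15)
  pts <- make_icosphere(12, 1)$vertices
  pl <- coil_placement(c(0, 0, 15), angle = 0, normal = c(0, 0, 1))
  peak <- function(nsamp) {
    cs <- coil_spec(samples_per_turn = nsamp)
    cp <- place_coil_tangential(build_figure8_quadrature(cs), pl,
                                standoff = 2)
    max(field_magnitude(sphere_efield(sph, cp, 50e6, pts)))
  }
  p32 <- peak(32); p64 <- peak(64)
  expect_lt(abs(p64 - p32) / p32, 0.005)
})

test_that("coil point-set export round-trips", {
  coil <- placed_default_coil()
  path <- tempfile(fileext = ".csv")
  df <- coil_as_pointset(coil, path)
  df2 <- utils::read.csv(path)
  expect_equal(nrow(df2), length(coil$weights))
  expect_equal(df2$w, df$w, tolerance = 1e-9)
})
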