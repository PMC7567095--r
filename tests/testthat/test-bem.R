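test_that("double-layer element integrals match numerical quadrature", {
  set.seed(11)
  for (k in 1:4) {
    tri <- matrix(rnorm(9), 3, 3)
    x <- rnorm(3) * 2
    D <- double_layer_matrix(matrix(x, 1), trimesh(tri, matrix(1:3, 1)))
    for (l in 1:3)
      expect_equal(D[1, l], quad_element_integral(tri, x, l),
                   tolerance = 1e-3)
  }
})

test_that("solid-angle closure: 4 pi inside, 0 outside, 2 pi on-surface", {
  s <- make_icosphere(10, 3)
  Vm <- s$vertices * 1e-3
  om_in <- tmsfield:::.surface_solid_angle_cpp(matrix(c(0, 1e-3, 0), 1),
                                               Vm, s$faces)
  expect_equal(om_in / (4 * pi), 1, tolerance = 1e-6)
  om_out <- tmsfield:::.surface_solid_angle_cpp(matrix(c(0.03, 0, 0), 1),
                                                Vm, s$faces)
  expect_lt(abs(om_out), 1e-6)
  # assembled system enforces 2 pi row sums through the diagonal closure
  mod <- compartment_model(list(s), sigma_in = 1, sigma_out = 0)
  sys <- assemble_double_layer(mod)
  # A = diag(sigma_bar) - jump/(4pi) * D with closure-corrected diagonal;
  # a constant potential is an exact null vector
  expect_lt(max(abs(sys$matrix %*% rep(1, nrow(sys$matrix)))), 1e-12)
})

test_that("deflation removes the constant null space and caches factors", {
  s <- make_icosphere(10, 2)   # 162 vertices: svd is cheap
  mod <- compartment_model(list(s), sigma_in = 0.33, sigma_out = 0)
  sys <- assemble_double_layer(mod)
  sv <- svd(sys$matrix)$d
  expect_lt(min(sv), 1e-12)          # singular before deflation
  sysd <- build_deflated_system(sys)
  # solve the same problem twice: bit-identical results (cached factors)
  p1 <- solve_surface_potentials(sysd, c(0, 1e-8, 0), c(0, 0, 5))
  p2 <- solve_surface_potentials(sysd, c(0, 1e-8, 0), c(0, 0, 5))
  expect_identical(p1$phi, p2$phi)
  # zero moment gives zero potential
  p0 <- solve_surface_potentials(sysd, c(0, 0, 0), c(0, 0, 5))
  expect_equal(max(abs(p0$phi)), 0)
})

test_that("deflated matrix is nonsingular and RHS constants shift phi only", {
  s <- make_icosphere(10, 2)
  mod <- compartment_model(list(s), sigma_in = 0.33, sigma_out = 0)
  A <- assemble_double_layer(mod)$matrix   # keep an unfactorised copy
  N <- nrow(A)
  Ad <- A + mean(0.33 / 2) / N
  expect_gt(min(svd(Ad)$d), 1e-6)
  set.seed(3)
  s0 <- rnorm(N)
  x1 <- solve(Ad, s0)
  x2 <- solve(Ad, s0 + 0.01)
  dd <- x2 - x1
  expect_lt(diff(range(dd)), 1e-9 * max(abs(x1)))  # a pure constant shift
})

test_that("surface potentials match the homogeneous-sphere oracle", {
  fx <- sphere15_system()
  pos <- c(3, 2, 9)
  mom <- c(2e-8, -1e-8, 1.5e-8)
  sol <- solve_surface_potentials(fx$system, mom, pos)
  orc <- oracle_sphere_potential(mom, pos, 0.33, 15, fx$mesh$vertices)
  phi <- sol$phi - mean(sol$phi)
  orc <- orc - mean(orc)
  expect_lt(sqrt(mean((phi - orc)^2)) / sqrt(mean(orc^2)), 0.01)
})

test_that("dipole preconditions are enforced", {
  fx <- sphere15_system()
  expect_error(solve_surface_potentials(fx$system, c(0, 0, 1e-8),
                                        c(0, 0, 20)), "outside")
  expect_error(solve_surface_potentials(fx$system, c(0, 0, 1e-8),
                                        c(0, 0, 14.9)), "margin")
})

test_that("equal conductivities across an inner surface change nothing", {
  outer <- make_icosphere(15, 3)
  inner <- make_icosphere(10, 3)
  mod2 <- compartment_model(list(outer, inner), sigma_in = c(0.33, 0.33),
                            sigma_out = c(0, 0.33))
  sys2 <- build_deflated_system(assemble_double_layer(mod2))
  mod1 <- compartment_model(list(outer), 0.33, 0)
  sys1 <- build_deflated_system(assemble_double_layer(mod1))
  mom <- c(1e-8, 0, 1e-8); pos <- c(0, 3, 5)
  phi2 <- solve_surface_potentials(sys2, mom, pos)$phi[1:nrow(outer$vertices)]
  phi1 <- solve_surface_potentials(sys1, mom, pos)$phi
  phi2 <- phi2 - mean(phi2); phi1 <- phi1 - mean(phi1)
  expect_lt(sqrt(mean((phi2 - phi1)^2)) / sqrt(mean(phi1^2)), 1e-6)
})

test_that("Geselowitz B matches the sphere closed form and is gauge
           invariant", {
  fx <- sphere15_system()
  pos <- c(3, 2, 9); mom <- c(2e-8, -1e-8, 1.5e-8)
  sol <- solve_surface_potentials(fx$system, mom, pos)
  fp <- rbind(c(30, 5, 8), c(0, -25, 14), c(10, 20, 18), c(0, 0, 30))
  Bs <- sphere_magnetic_forward(mom, pos, c(0, 0, 0), fp)
  Bg <- geselowitz_bfield(fx$model, sol, fp, fx$system)
  expect_lt(sqrt(sum((Bs - Bg)^2)) / sqrt(sum(Bs^2)), 0.02)
  # gauge invariance: adding a constant to phi leaves B unchanged
  sol_shift <- sol
  sol_shift$phi <- sol$phi + 5
  Bg2 <- geselowitz_bfield(fx$model, sol_shift, fp, fx$system)
  expect_lt(max(abs(Bg2 - Bg)), 1e-10 * max(abs(Bg)))
  # sigma jumps of zero reduce B to the infinite-medium term
  mod0 <- fx$model
  mod0$sigma_in <- 0.33; mod0$sigma_out <- 0.33
  sys0 <- fx$system; sys0$jump <- 0
  B0 <- geselowitz_bfield(mod0, sol, fp, sys0, check = FALSE)
  d <- sweep(fp, 2, pos) * 1e-3
  Binf <- 1e-7 * tmsfield:::cross3(matrix(mom, nrow(fp), 3, byrow = TRUE),
                                   d) / rowSums(d^2)^1.5
  expect_equal(B0, Binf, tolerance = 1e-12)
  # field point inside the conductor is a domain error
  expect_error(geselowitz_bfield(fx$model, sol, matrix(c(0, 0, 5), 1),
                                 fx$system), "inside")
})

test_that("BEM E-field scales exactly with dIdt and respects margins", {
  fx <- sphere15_system()
  coil <- placed_default_coil()
  pts <- make_icosphere(12, 1)$vertices
  E1 <- bem_efield(fx$model, fx$system, coil, 50e6, pts)
  E2 <- bem_efield(fx$model, fx$system, coil, 100e6, pts)
  expect_equal(E2$E, 2 * E1$E, tolerance = 1e-12)
  expect_error(bem_efield(fx$model, fx$system, coil, 50e6,
                          matrix(c(0, 0, 16), 1)), "outside")
  expect_error(bem_efield(fx$model, fx$system, coil, 50e6,
                          matrix(c(0, 0, 14.9), 1)), "margin")
})

test_that("BEM converges to the closed-form sphere field with mesh
           refinement", {
  coil <- placed_default_coil()
  sph <- sphere_model(c(0, 0, 0), 15)
  pts <- make_icosphere(12, 1)$vertices
  E_ref <- sphere_efield(sph, coil, 50e6, pts)
  res <- vapply(2:4, function(sub) {
    s <- make_icosphere(15, sub)
    mod <- compartment_model(list(s), 0.33, 0)
    sys <- build_deflated_system(assemble_double_layer(mod))
    relative_error(bem_efield(mod, sys, coil, 50e6, pts, check = FALSE),
                   E_ref)
  }, 0)
  expect_true(all(diff(res) < 0))   # monotone decrease
  expect_lt(res[3L], 0.02)
})

test_that("floating two-sheet skull equals the nested-surfaces model", {
  # zero-hole skull: two disjoint sheets as ONE floating surface
  shell <- tmsfield:::make_skull_shell(c(15, 15, 15), c(14.3, 14.3, 14.3),
                                       holes = list(), target_edge = 2)
  outer <- make_icosphere(17, 3)
  float_mod <- compartment_model(list(outer, shell),
                                 sigma_in = c(0.33, 0.0066),
                                 sigma_out = c(0, 0.33))
  nest_mod <- make_concentric_spheres_model(c(17, 15, 14.3),
                                            c(0.33, 0.0066, 0.33),
                                            subdivisions = 3)
  sys_f <- build_deflated_system(assemble_double_layer(float_mod))
  sys_n <- build_deflated_system(assemble_double_layer(nest_mod))
  coil <- build_figure8_quadrature(coil_spec())
  coil <- place_coil_tangential(coil, coil_placement(c(0, 0, 17), 0,
                                                     c(0, 0, 1)),
                                standoff = 2)
  pts <- make_icosphere(12, 1)$vertices
  Ef <- bem_efield(float_mod, sys_f, coil, 50e6, pts, check = FALSE)
  En <- bem_efield(nest_mod, sys_n, coil, 50e6, pts, check = FALSE)
  expect_lt(relative_error(Ef, En), 0.02)
})
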