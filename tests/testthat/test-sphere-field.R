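test_that("sphere fit recovers exact and noisy spheres", {
  s <- make_icosphere(14.4, 3, center = c(2, -1, 3))
  fit <- fit_local_sphere(s, region_center = c(2, -1, 17.4),
                          region_radius = 10)
  expect_lt(max(abs(fit$origin - c(2, -1, 3))), 1e-6)
  expect_lt(abs(fit$radius - 14.4), 1e-6)

  # hemisphere patch with 0.05-mm radial noise
  set.seed(7)
  v <- make_icosphere(15, 3)$vertices
  v <- v[v[, 3L] > 0, ]
  v <- v * (1 + rnorm(nrow(v), sd = 0.05 / 15))
  patch <- trimesh(v, matrix(c(1L, 2L, 3L), 1))  # faces unused by the fit
  fitn <- fit_local_sphere(patch, c(0, 0, 15), region_radius = 25)
  expect_lt(abs(fitn$radius - 15), 0.1)

  # flat patch is degenerate
  g <- as.matrix(expand.grid(x = 1:6, y = 1:6))
  flat <- trimesh(cbind(g, 0), matrix(c(1L, 2L, 3L), 1))
  expect_error(fit_local_sphere(flat, c(3, 3, 0), 10), "degenerate")
  expect_error(fit_local_sphere(make_icosphere(10, 0), c(0, 0, 10), 0.1),
               "fewer than 10")
})

test_that("sphere magnetic forward has the silent-source properties", {
  org <- c(1, 2, 0)
  pts <- rbind(c(30, 5, 8), c(1, -25, 14), c(12, 20, 18)) + org
  # radial dipole: B = 0 exactly
  pos <- org + c(3, 2, 9)
  Br <- sphere_magnetic_forward(c(3, 2, 9) * 1e-9, pos, org, pts)
  expect_equal(max(abs(Br)), 0, tolerance = 1e-25)
  # dipole at the origin: B = 0
  B0 <- sphere_magnetic_forward(c(1, 0, 0) * 1e-9, org, org, pts)
  expect_equal(max(abs(B0)), 0)
  # field point inside the source radius is a domain error
  expect_error(sphere_magnetic_forward(c(1, 0, 0), org + c(0, 0, 9), org,
                                       matrix(org + c(0, 0, 5), 1)),
               "outside")
})

test_that("sphere E-field is tangential and linear", {
  sph <- sphere_model(c(0, 0, 0), 15)
  coil <- placed_default_coil()
  pts <- make_icosphere(12, 2)$vertices
  E <- sphere_efield(sph, coil, 50e6, pts)
  rad <- abs(rowSums(E$E * pts)) /
    (field_magnitude(E) * sqrt(rowSums(pts^2)))
  expect_lt(max(rad), 1e-10)
  # linear in dIdt
  E2 <- sphere_efield(sph, coil, 100e6, pts)
  expect_equal(E2$E, 2 * E$E, tolerance = 1e-12)
  # linear in coil weights
  coil2 <- coil
  coil2$weights <- 2 * coil2$weights
  E3 <- sphere_efield(sph, coil2, 50e6, pts)
  expect_equal(E3$E, 2 * E$E, tolerance = 1e-12)
})

test_that("sphere E-field is equivariant under rigid rotation", {
  sph <- sphere_model(c(0, 0, 0), 15)
  coil <- placed_default_coil()
  pts <- make_icosphere(11, 1)$vertices
  E <- sphere_efield(sph, coil, 50e6, pts)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  coil_r <- coil
  coil_r$transform$rotation <- R %*% coil$transform$rotation
  coil_r$transform$translation <- as.numeric(R %*% coil$transform$translation)
  E_r <- sphere_efield(sph, coil_r, 50e6, pts %*% t(R))
  expect_equal(E_r$E %*% R, E$E, tolerance = 1e-9)
})

test_that("points outside the validity radius are rejected by name", {
  sph <- sphere_model(c(0, 0, 0), 15)
  coil <- placed_default_coil()
  vr <- sphere_validity_radius(sph, coil)
  expect_gt(vr, 15)
  bad <- matrix(c(0, 0, vr + 1), 1)
  expect_error(sphere_efield(sph, coil, 50e6, bad), "point\\(s\\) 1")
})
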