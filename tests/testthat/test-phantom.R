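test_that("icosphere has the expected combinatorics and radius", {
  m0 <- make_icosphere(10, 0)
  expect_equal(nrow(m0$vertices), 12L)
  expect_equal(nrow(m0$faces), 20L)
  m3 <- make_icosphere(10, 3)
  expect_equal(nrow(m3$vertices), 642L)
  expect_lt(max(abs(sqrt(rowSums(m3$vertices^2)) - 10)), 1e-9)
  # polyhedral volume converges to the ball volume (inscribed: deficit
  # ~3.4% at subdivision 2, ~0.9% at 3)
  v2 <- signed_volume(make_icosphere(10, 2))
  expect_lt(abs(v2 - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000), 0.04)
  v3 <- signed_volume(m3)
  expect_lt(abs(v3 - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000), 0.02)
})

test_that("concentric spheres model construction and validation", {
  m <- make_concentric_spheres_model(c(17, 15), c(0.33, 0.0066),
                                     subdivisions = 1)
  expect_length(m$surfaces, 2L)
  expect_equal(m$sigma_out, c(0, 0.33))
  m1 <- make_concentric_spheres_model(15, 0.33, subdivisions = 1)
  expect_length(m1$surfaces, 1L)
  expect_error(make_concentric_spheres_model(c(15, 17), c(0.33, 0.0066)),
               "decreasing")
  expect_error(make_concentric_spheres_model(c(17, 15), 0.33),
               "one conductivity per region")
})

test_that("rat phantom surfaces are valid and correctly nested", {
  ph <- coarse_phantom()
  for (nm in c("scalp", "skull", "brain", "evaluation")) {
    rep <- validate_mesh(ph[[nm]])
    expect_true(rep$closed, info = nm)
    expect_true(rep$oriented, info = nm)
  }
  # one closed skull surface with 3 holes: genus 2, Euler characteristic -2
  expect_equal(mesh_statistics(ph$skull)$euler, -2L)
  # evaluation surface honours the margin to the inner skull sheet
  d <- point_mesh_distance(ph$evaluation$vertices, ph$skull)
  expect_gte(min(d), ph$spec$eval_margin)
  # skull floats strictly inside the body
  expect_true(all(tmsfield:::inside_surface(ph$scalp, ph$skull$vertices)))
})

test_that("zero-hole phantom gives two disjoint closed skull sheets", {
  ph0 <- make_rat_phantom(phantom_spec(holes = list(), brainstem_length = 0,
                                       body_edge = 2.2, skull_edge = 1.4,
                                       eval_edge = 1.8))
  expect_equal(mesh_statistics(ph0$skull)$euler, 4L)
  expect_true(validate_mesh(ph0$skull)$closed)
})

test_that("overlapping holes are rejected", {
  expect_error(phantom_spec(holes = list(
    list(direction = c(1, 0, 0), angle = 20),
    list(direction = c(1, 0.2, 0), angle = 20))), "overlap")
})

test_that("CT synthesis assigns exact HU levels without noise", {
  mesh <- make_icosphere(8, 2)
  sphere <- compartment_model(list(mesh), 0.33, 0)
  ct <- synthesize_ct(sphere, spacing = 0.6, noise_sd = 0)
  expect_setequal(unique(as.numeric(ct$data)), c(-1000, 40))
  # voxel-wise agreement with exact point-in-polyhedron containment on a
  # deterministic subsample
  dm <- dim(ct$data)
  set.seed(1)
  sub <- sample.int(prod(dm), 4000L)
  idx <- arrayInd(sub, dm) - 1L
  P <- sweep(idx * ct$spacing, 2L, -ct$origin)
  truth <- tmsfield:::inside_surface(mesh, P)
  expect_equal(as.numeric(ct$data)[sub] > 0, truth)
})

test_that("CT synthesis is seeded and has the three HU modes", {
  ph <- coarse_phantom()
  ct1 <- synthesize_ct(ph$model, spacing = 0.5, noise_sd = 50, seed = 1)
  ct2 <- synthesize_ct(ph$model, spacing = 0.5, noise_sd = 50, seed = 1)
  expect_identical(ct1$data, ct2$data)
  ct3 <- synthesize_ct(ph$model, spacing = 0.5, noise_sd = 50, seed = 2)
  expect_false(identical(ct1$data, ct3$data))
  th <- find_thresholds(ct1)
  expect_lt(abs(th$modes[1L] - (-1000)), 30)
  expect_lt(abs(th$modes[2L] - 40), 30)
  # bone mode present
  expect_gt(sum(ct1$data > 1200), 1000)
})

test_that("phantom bone shell thickness survives voxelisation", {
  ph <- coarse_phantom()
  ct <- synthesize_ct(ph$model, spacing = 0.34, noise_sd = 0)
  bone <- ct$data > 500
  # thickness via the distance transform: max inscribed radius ~ t/2
  d2 <- tmsfield:::.edt_squared_cpp(!as.logical(bone), dim(bone))
  thick <- 2 * sqrt(max(d2[bone])) * ct$spacing
  expect_lt(abs(thick - ph$spec$skull_thickness), 2 * ct$spacing)
})

test_that("CT volumes round-trip through NIfTI", {
  sphere <- compartment_model(list(make_icosphere(6, 1)), 0.33, 0)
  ct <- synthesize_ct(sphere, spacing = 1, noise_sd = 10, seed = 3)
  path <- tempfile(fileext = ".nii.gz")
  write_volume_nifti(ct, path)
  ct2 <- read_volume_nifti(path)
  expect_equal(dim(ct2$data), dim(ct$data))
  expect_equal(ct2$spacing, ct$spacing, tolerance = 1e-6)
  expect_equal(ct2$origin, ct$origin, tolerance = 1e-4)
  expect_equal(as.numeric(ct2$data), as.numeric(ct$data),
               tolerance = 1e-6)
})
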