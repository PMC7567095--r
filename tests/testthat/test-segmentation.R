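test_that("thresholds are exact on noise-free two-level volumes", {
  sphere <- compartment_model(list(make_icosphere(8, 2)), 0.33, 0)
  ct <- synthesize_ct(sphere, spacing = 0.6, noise_sd = 0)
  th <- find_thresholds(ct)
  expect_equal(th$t_air_soft, -480)   # midpoint of -1000 and 40
  expect_equal(th$modes, c(-1000, 40))
  # constant volume: no modes
  flat <- ct_volume(array(0, c(8, 8, 8)), spacing = 1)
  expect_error(find_thresholds(flat), "unimodal|fixed thresholds")
})

test_that("thresholds are stable under CT noise", {
  ph <- coarse_phantom()
  ct <- synthesize_ct(ph$model, spacing = 0.4, noise_sd = 50, seed = 1)
  th <- find_thresholds(ct)
  expect_lt(abs(th$t_air_soft - (-480)), 30)
  expect_gt(th$t_soft_bone, 100)
  expect_lt(th$t_soft_bone, 1200)
})

test_that("segmentation recovers ground-truth masks", {
  ph <- coarse_phantom()
  ct <- synthesize_ct(ph$model, spacing = 0.4, noise_sd = 0)
  # noise-free, no closure: body mask equals the voxelised truth exactly
  lv0 <- segment_volume(ct, segmentation_params(body_closure_radius = 0,
                                                skull_closure_radius = 0))
  gt_body <- voxelize_mesh(ph$scalp, ct)
  expect_identical(label_mask(lv0, "body")$data, gt_body$data)
  gt_bone <- voxelize_mesh(ph$skull, ct)
  expect_identical(label_mask(lv0, "bone")$data, gt_bone$data)
  # default closure changes little on this smooth phantom
  lv <- segment_volume(ct)
  expect_gt(dice_coefficient(label_mask(lv, "body"), gt_body), 0.999)

  # with noise the body mask is still nearly perfect
  ctn <- synthesize_ct(ph$model, spacing = 0.4, noise_sd = 50, seed = 1)
  lvn <- segment_volume(ctn)
  expect_gt(dice_coefficient(label_mask(lvn, "body"), gt_body), 0.99)
})

test_that("only the largest connected component is kept as body", {
  sphere <- compartment_model(list(make_icosphere(8, 2)), 0.33, 0)
  ct <- synthesize_ct(sphere, spacing = 0.8, noise_sd = 0)
  # add a small disconnected blob of soft tissue
  ct$data[2:4, 2:4, 2:4] <- 40
  lv <- segment_volume(ct, segmentation_params(body_closure_radius = 0,
                                               skull_closure_radius = 0))
  expect_false(any(label_mask(lv, "body")$data[2:4, 2:4, 2:4]))
  expect_gt(sum(label_mask(lv, "body")$data), 1000)
})

test_that("bone mask is monotone in the bone threshold", {
  ph <- coarse_phantom()
  ct <- synthesize_ct(ph$model, spacing = 0.5, noise_sd = 30, seed = 2)
  p1 <- segmentation_params(t_air_soft = -480, t_soft_bone = 500,
                            skull_closure_radius = 0)
  p2 <- segmentation_params(t_air_soft = -480, t_soft_bone = 900,
                            skull_closure_radius = 0)
  b1 <- label_mask(segment_volume(ct, p1), "bone")$data
  b2 <- label_mask(segment_volume(ct, p2), "bone")$data
  expect_true(all(b1 | !b2))   # b2 subset of b1
})

test_that("morphological closure fills narrow channels and is idempotent", {
  dm <- c(40, 40, 40)
  cube <- array(FALSE, dm)
  cube[8:32, 8:32, 8:32] <- TRUE
  cube[19:21, , 19:21] <- FALSE   # 1.5-mm tunnel at 0.5-mm voxels
  vol <- ct_volume(array(0, dm), spacing = 0.5)
  mask <- tmsfield:::as_mask(cube, vol)
  closed <- morph_close(mask, 2)
  expect_true(all(closed$data[19:21, 10:30, 19:21]))
  expect_gte(sum(closed$data), sum(mask$data))
  # identity at radius 0; idempotent otherwise
  expect_identical(morph_close(mask, 0)$data, mask$data)
  expect_identical(morph_close(closed, 2)$data, closed$data)
})

test_that("boundary surface extraction is sub-voxel accurate", {
  sphere <- compartment_model(list(make_icosphere(10, 3)), 0.33, 0)
  ct <- synthesize_ct(sphere, spacing = 0.5, noise_sd = 0)
  mask <- tmsfield:::as_mask(ct$data > 0, ct)
  surf <- extract_boundary_surface(mask)
  r <- sqrt(rowSums(surf$vertices^2))
  expect_lt(max(abs(r - 10)), 0.5)
  expect_true(validate_mesh(surf)$closed)
  # remeshed variant stays accurate and hits the target edge
  surf2 <- extract_boundary_surface(mask, target_edge = 1.5)
  expect_lt(abs(mesh_statistics(surf2)$mean_edge - 1.5), 0.3)
  expect_lt(max(abs(sqrt(rowSums(surf2$vertices^2)) - 10)), 0.5)
})

test_that("single-voxel mask gives a tiny closed surface", {
  vol <- ct_volume(array(0, c(7, 7, 7)), spacing = 1)
  m <- array(FALSE, c(7, 7, 7)); m[4, 4, 4] <- TRUE
  s <- iso_surface(tmsfield:::as_mask(m, vol))
  expect_true(validate_mesh(s)$closed)
  expect_equal(mesh_statistics(s)$euler, 2L)
})

test_that("mask touching the volume border is rejected", {
  vol <- ct_volume(array(0, c(7, 7, 7)), spacing = 1)
  m <- array(TRUE, c(7, 7, 7))
  expect_error(iso_surface(tmsfield:::as_mask(m, vol)), "border")
})

test_that("evaluation surface keeps its margin below the skull", {
  ph <- coarse_phantom()
  ct <- synthesize_ct(ph$model, spacing = 0.4, noise_sd = 0)
  skull_mask <- voxelize_mesh(ph$skull, ct)
  brain_mask <- voxelize_mesh(ph$brain, ct)
  ev <- make_evaluation_surface(brain_mask, skull_mask, margin = 1)
  skull_surf <- extract_boundary_surface(skull_mask)
  d <- point_mesh_distance(ev$vertices, skull_surf)
  expect_gte(min(d), 1 - ct$spacing)
  # margin 0: boundary of the brain mask itself
  ev0 <- make_evaluation_surface(brain_mask, skull_mask, margin = 0)
  brain_surf <- iso_surface(brain_mask)
  expect_lt(hausdorff_distance(ev0, brain_surf), 2 * ct$spacing)
  # margin larger than the phantom: empty evaluation region
  expect_error(make_evaluation_surface(brain_mask, skull_mask, margin = 20),
               "margin")
})
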