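mkfs <- function(E, pts = NULL) {
  E <- matrix(E, ncol = 3, byrow = TRUE)
  if (is.null(pts)) pts <- cbind(seq_len(nrow(E)), 0, 0)
  field_set(pts, E)
}

test_that("relative error: pooled 3N-component definition", {
  ref <- mkfs(c(1, 0, 0, 0, 1, 0))
  expect_equal(relative_error(ref, ref), 0)
  ref2 <- ref; ref2$E <- 2 * ref$E
  expect_equal(relative_error(ref2, ref), 1)
  # ||diff|| = sqrt(2), ||ref|| = sqrt(2)
  e <- mkfs(c(1, 0, 0, 0, 0, 1))
  expect_equal(relative_error(e, ref), 1)
  # RE(alpha E, E) = |alpha - 1|
  for (a in c(0.3, 1.7, -2)) {
    ea <- ref; ea$E <- a * ref$E
    expect_equal(relative_error(ea, ref), abs(a - 1), tolerance = 1e-12)
  }
  zero <- ref; zero$E <- 0 * ref$E
  expect_error(relative_error(ref, zero), "zero")
})

test_that("correlation error: de-meaned, scale-invariant cosine", {
  ref <- mkfs(c(1, 0, 0, -1, 0.5, 0, 0.2, -0.5, 0))
  for (a in c(0.1, 3)) {
    ea <- ref; ea$E <- a * ref$E
    expect_equal(correlation_error(ea, ref), 0, tolerance = 1e-12)
  }
  anti <- ref; anti$E <- -ref$E
  expect_equal(correlation_error(anti, ref), 2, tolerance = 1e-12)
  # hand-computed case: component-wise de-meaning makes
  # E = {(1,0,0),(0,0,0)} perfectly correlated with {(1,0,0),(-1,0,0)}
  r2 <- mkfs(c(1, 0, 0, -1, 0, 0))
  e2 <- mkfs(c(1, 0, 0, 0, 0, 0))
  expect_equal(correlation_error(e2, r2), 0, tolerance = 1e-12)
  # hand-computed non-trivial value: ref x-components (1,-1), E = (1,0)
  # de-meaned and pooled with a y-component (0,1) vs (1,0):
  # a = (0.5,-0.5 | -0.5,0.5), b = (1,-1 | -0.5,0.5) after de-meaning
  r3 <- mkfs(c(1, -0.5, 0, -1, 0.5, 0))
  e3 <- mkfs(c(1, 0, 0, 0, 1, 0))
  a <- scale(e3$E, scale = FALSE); b <- scale(r3$E, scale = FALSE)
  expected <- 1 - sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  expect_equal(correlation_error(e3, r3), expected, tolerance = 1e-12)
  const <- mkfs(c(1, 1, 1, 1, 1, 1))
  expect_error(correlation_error(const, r3), "constant")
})

test_that("mean angular error averages per-point angles in degrees", {
  ref <- mkfs(c(1, 0, 0, 1, 0, 0, 1, 0, 0, 1, 0, 0))
  expect_equal(as.numeric(mean_angular_error(ref, ref)), 0)
  rot <- function(deg) c(cos(deg * pi / 180), sin(deg * pi / 180), 0)
  # all rotated 10 degrees
  e10 <- mkfs(rep(rot(10), 4))
  expect_equal(as.numeric(mean_angular_error(e10, ref)), 10,
               tolerance = 1e-9)
  # half rotated 30, half exact: mean 15
  e15 <- mkfs(c(rot(30), rot(30), rot(0), rot(0)))
  expect_equal(as.numeric(mean_angular_error(e15, ref)), 15,
               tolerance = 1e-9)
  # positive per-point rescaling never changes the angle
  e15b <- e15; e15b$E <- e15$E * c(0.1, 5, 2, 40)
  expect_equal(as.numeric(mean_angular_error(e15b, ref)), 15,
               tolerance = 1e-9)
  # zero vectors are excluded and counted
  ez <- e15; ez$E[1, ] <- 0
  out <- mean_angular_error(ez, ref)
  expect_equal(attr(out, "n_excluded"), 1L)
  allz <- ref; allz$E <- ref$E * 0
  expect_error(mean_angular_error(allz, ref), "no points")
})

test_that("hotspot restriction uses a strict sqrt(0.5) threshold", {
  mag <- function(m) mkfs(as.numeric(rbind(m, 0, 0)))
  expect_equal(hotspot_restrict(mag(c(1.0, 0.72, 0.70))), c(1L, 2L))
  # 0.71 > sqrt(0.5) = 0.7071..., so it is included
  expect_equal(hotspot_restrict(mag(c(1.0, 0.71, 0.70))), c(1L, 2L))
  expect_equal(hotspot_restrict(mag(c(1.0, 0.7071, 0.70))), 1L)
  # uniform magnitudes: everything included
  expect_equal(hotspot_restrict(mag(c(1, 1, 1))), 1:3)
  # single point; and the peak is always included
  expect_equal(hotspot_restrict(mag(1)), 1L)
})

test_that("peak distance uses deterministic lowest-index tie-breaking", {
  pts <- cbind(c(0, 3, 10), 0, 0)
  a <- field_set(pts, rbind(c(1, 0, 0), c(0, 0.5, 0), c(0, 0, 0.2)))
  expect_equal(peak_distance(a, a), 0)
  b <- field_set(pts, rbind(c(0.1, 0, 0), c(0, 0.5, 0), c(0, 0, 1)))
  expect_equal(peak_distance(a, b), 10)
  # two equal maxima in b: the lowest index wins
  tie <- field_set(pts, rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 0.2)))
  expect_equal(peak_distance(tie, a), 0)
})

test_that("compare_fields and summaries assemble all metrics", {
  set.seed(5)
  pts <- matrix(rnorm(30), 10, 3)
  ref <- field_set(pts, matrix(rnorm(30), 10, 3))
  noisy <- field_set(pts, ref$E * 1.05 + 0.01)
  cmp <- compare_fields(noisy, ref)
  expect_true(all(c("re", "cce", "ang", "peak_mm", "re_hot", "ang_hot")
                  %in% names(cmp)))
  expect_gt(cmp$re, 0)
  expect_lt(cmp$cce, 0.1)
  s <- summarize_metric(rnorm(100))
  expect_true(all(c("mean", "sd", "p2.3", "p16", "median", "p84", "p97.7")
                  %in% names(s)))
  expect_lte(s$p2.3, s$p16)
  expect_lte(s$p16, s$median)
})
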