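test_that("mesh statistics are exact on canonical solids", {
  # regular tetrahedron, edge 1
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) /
    (2 * sqrt(2))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  st <- mesh_statistics(orient_outward(trimesh(v, f)))
  expect_equal(st$n_vertices, 4L)
  expect_equal(st$n_edges, 6L)
  expect_equal(st$n_faces, 4L)
  expect_equal(st$mean_edge, 1, tolerance = 1e-12)
  expect_equal(st$sd_edge, 0, tolerance = 1e-12)
  expect_equal(st$euler, 2L)

  # subdivided icosahedron: V = 10 * 4^k + 2
  st3 <- mesh_statistics(make_icosphere(10, 3))
  expect_equal(st3$n_vertices, 642L)
  expect_equal(st3$n_faces, 1280L)
  expect_equal(st3$euler, 2L)

  # two disjoint closed spheres in one mesh: Euler characteristic adds
  s1 <- make_icosphere(5, 1)
  s2 <- make_icosphere(5, 1, center = c(20, 0, 0))
  both <- trimesh(rbind(s1$vertices, s2$vertices),
                  rbind(s1$faces, s2$faces + nrow(s1$vertices)))
  expect_equal(mesh_statistics(both)$euler, 4L)
  expect_error(mesh_statistics(trimesh(matrix(0, 0, 3),
                                       matrix(0L, 0, 3))), "empty")
})

test_that("validate_mesh reports closedness, orientation and defects", {
  s <- make_icosphere(10, 2)
  rep <- validate_mesh(s)
  expect_true(rep$closed)
  expect_true(rep$oriented)
  expect_length(rep$defects, 0)

  # one face removed: 3 boundary edges, not closed
  open_mesh <- trimesh(s$vertices, s$faces[-1, ])
  rep2 <- validate_mesh(open_mesh, require_closed = TRUE)
  expect_false(rep2$closed)
  expect_equal(rep2$n_boundary_edges, 3L)

  # all faces flipped: closed but inward (negative signed volume)
  rep3 <- validate_mesh(flip_faces(s))
  expect_true(rep3$closed)
  expect_false(rep3$oriented)
  expect_lt(signed_volume(flip_faces(s)), 0)
})

test_that("area-weighted normals of a closed mesh sum to zero", {
  for (m in list(make_icosphere(7, 2), make_ellipsoid(c(12, 7, 5)),
                 coarse_phantom()$skull)) {
    fg <- face_geometry(m)
    closure <- sqrt(sum(colSums(fg$normals * fg$areas)^2))
    expect_lt(closure, 1e-6 * sum(fg$areas))
  }
})

test_that("mesh files round-trip through STL, OFF and PLY", {
  m <- make_icosphere(8.5, 2)
  # OFF/PLY preserve vertex order and connectivity exactly
  for (fmt in c("off", "ply")) {
    path <- tempfile(fileext = paste0(".", fmt))
    write_mesh(m, path)
    m2 <- read_mesh(path)
    expect_lt(max(abs(m2$vertices - m$vertices)), 1e-6)
    expect_identical(m2$faces, m$faces)
  }
  # STL stores one vertex per facet corner: welding recovers the same
  # vertex set (order-free) and the same statistics
  match_verts <- function(a, b, tol) {
    worst <- max(vapply(seq_len(nrow(a)), function(i)
      min(colSums((t(b) - a[i, ])^2)), 0))
    expect_lt(sqrt(worst), tol)
  }
  for (binary in c(FALSE, TRUE)) {
    path <- tempfile(fileext = ".stl")
    write_mesh(m, path, binary = binary)
    m2 <- read_mesh(path)
    st <- mesh_statistics(m); st2 <- mesh_statistics(m2)
    expect_equal(st2$n_vertices, st$n_vertices)
    expect_equal(st2$n_faces, st$n_faces)
    expect_equal(st2$euler, st$euler)
    expect_equal(st2$area, st$area, tolerance = 1e-5)
    match_verts(m2$vertices, m$vertices, if (binary) 1e-4 else 1e-6)
  }
})

test_that("non-triangular faces are rejected", {
  path <- tempfile(fileext = ".off")
  writeLines(c("OFF", "4 1 0", "0 0 0", "1 0 0", "1 1 0", "0 1 0",
               "4 0 1 2 3"), path)
  expect_error(read_mesh(path), "non-triangular")
  expect_error(read_mesh(tempfile(fileext = ".off")), "not found")
})

test_that("remeshing reaches the target edge and preserves topology", {
  s <- make_icosphere(15, 3)   # mean edge ~2 mm
  r <- remesh_to_target_edge(s, 1.4)
  st <- mesh_statistics(r)
  expect_lt(abs(st$mean_edge - 1.4), 0.2 * 1.4)
  expect_equal(st$euler, 2L)
  expect_true(validate_mesh(r)$closed)
  expect_gt(signed_volume(r), 0)
  expect_lt(hausdorff_distance(r, s), 1.4)

  # near-identity when the target equals the current mean edge
  cur <- mesh_statistics(s)$mean_edge
  r2 <- remesh_to_target_edge(s, cur)
  expect_lt(abs(mesh_statistics(r2)$mean_edge - cur), 0.2 * cur)
  expect_lt(hausdorff_distance(r2, s), cur)
})

test_that("remeshing coarser than the feature size is refused", {
  # skull shell with a ~3-mm hole cannot be remeshed to 5-mm edges
  shell <- tmsfield:::make_skull_shell(
    c(13.5, 14.3, 12), c(12.8, 13.6, 11.3),
    list(list(direction = c(-1, 0, 0), angle = 7)), 1.2)
  expect_error(remesh_to_target_edge(shell, 5), "topology")
})
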