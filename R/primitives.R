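#' Icosphere
#'
#' Subdivided icosahedron projected to a sphere: the standard oracle
#' geometry for solver validation. Closed, outward-oriented, all vertices at
#' the requested radius.
#'
#' @param radius sphere radius (mm), > 0.
#' @param subdivisions number of 4-to-1 subdivision rounds (>= 0);
#'   level k has `10 * 4^k + 2` vertices and `20 * 4^k` faces.
#' @param center sphere centre (mm).
#' @return a closed `trimesh`.
#' @export
make_icosphere <- function(radius, subdivisions = 3L, center = c(0, 0, 0)) {
  stopifnot(radius > 0, subdivisions >= 0)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  v <- v / sqrt(rowSums(v^2))
  for (s in seq_len(subdivisions)) {
    sub <- subdivide_once(v, f)
    v <- sub$v / sqrt(rowSums(sub$v^2))
    f <- sub$f
  }
  orient_outward(trimesh(sweep(v * radius, 2L, -center), f))
}

# one 4-to-1 loop subdivision round (midpoint insertion, no smoothing)
subdivide_once <- function(v, f) {
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  uk <- unique(key)
  mididx <- nrow(v) + match(key, uk)
  firsts <- match(uk, key)
  mids <- (v[e[firsts, 1L], , drop = FALSE] +
             v[e[firsts, 2L], , drop = FALSE]) / 2
  nf <- nrow(f)
  m12 <- mididx[1:nf]; m23 <- mididx[nf + 1:nf]; m31 <- mididx[2 * nf + 1:nf]
  newf <- rbind(cbind(f[, 1L], m12, m31),
                cbind(f[, 2L], m23, m12),
                cbind(f[, 3L], m31, m23),
                cbind(m12, m23, m31))
  list(v = rbind(v, mids), f = newf)
}

#' Ellipsoid mesh
#'
#' Icosphere scaled anisotropically to the given semi-axes. The subdivision
#' level is chosen so the mean edge length comes as close as possible to
#' `target_edge`; pass `subdivisions` to fix it explicitly.
#'
#' @param semiaxes length-3 vector of semi-axes (mm).
#' @param target_edge requested mean edge length (mm); ignored when
#'   `subdivisions` is given.
#' @param subdivisions optional explicit subdivision level.
#' @param center ellipsoid centre (mm).
#' @return a closed `trimesh`.
#' @export
make_ellipsoid <- function(semiaxes, target_edge = NULL, subdivisions = NULL,
                           center = c(0, 0, 0)) {
  stopifnot(length(semiaxes) == 3L, all(semiaxes > 0))
  if (is.null(subdivisions)) {
    if (is.null(target_edge)) subdivisions <- 3L else {
      # icosahedron edge on unit sphere is ~1.0514; scale by mean semi-axis
      e0 <- 1.0514 * mean(semiaxes)
      subdivisions <- max(0L, round(log2(e0 / target_edge)))
    }
  }
  m <- make_icosphere(1, subdivisions)
  m$vertices <- sweep(sweep(m$vertices, 2L, semiaxes, `*`), 2L, -center)
  orient_outward(m)
}
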