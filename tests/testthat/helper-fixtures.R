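# Shared fixtures (memoised: heavy objects are built once per test run)
# and independent oracles used across test files.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# 15-mm sphere conductor, subdivision 4, deflated system (the main oracle
# geometry)
sphere15_system <- function() {
  fixture("sphere15", function() {
    s <- make_icosphere(15, 4)
    mod <- compartment_model(list(s), sigma_in = 0.33, sigma_out = 0)
    sys <- build_deflated_system(assemble_double_layer(mod))
    list(mesh = s, model = mod, system = sys)
  })
}

# coarse rat phantom for structural/solver tests (resolution chosen for
# test runtime; the package defaults are finer)
coarse_phantom <- function() {
  fixture("coarse_phantom", function()
    make_rat_phantom(phantom_spec(body_edge = 2.0, skull_edge = 1.1,
                                  eval_edge = 1.3)))
}

# default figure-of-eight coil placed PA on top of the 15-mm sphere at
# 2 mm standoff
placed_default_coil <- function() {
  fixture("placed_coil", function() {
    coil <- build_figure8_quadrature(coil_spec())
    pl <- coil_placement(c(0, 0, 15), angle = 0, normal = c(0, 0, 1))
    place_coil_tangential(coil, pl, standoff = 2)
  })
}

# --- independent oracles --------------------------------------------------

# Deterministic numerical quadrature of the linear-basis double-layer
# element integral: int_T psi_l (y-x).n/|y-x|^3 dS by barycentric grid
# midpoint rule with ns^2 subtriangles.
quad_element_integral <- function(tri, x, l, ns = 200) {
  g <- expand.grid(i = 0:(ns - 1), j = 0:(ns - 1))
  g <- g[g$i + g$j <= ns - 1, ]
  up <- cbind((g$i + 1 / 3) / ns, (g$j + 1 / 3) / ns)
  gd <- g[g$i + g$j <= ns - 2, ]
  dn <- cbind((gd$i + 2 / 3) / ns, (gd$j + 2 / 3) / ns)
  bary <- rbind(up, dn)
  w <- cbind(bary, 1 - rowSums(bary))
  pts <- w %*% tri
  e1 <- tri[2, ] - tri[1, ]; e2 <- tri[3, ] - tri[1, ]
  cr <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  area2 <- sqrt(sum(cr^2))
  nrm <- cr / area2
  d <- sweep(pts, 2, x)
  K <- (d %*% nrm) / rowSums(d^2)^1.5
  sub_area <- area2 / 2 / nrow(w)
  sum(w[, l] * K) * sub_area
}

# Spherical-harmonic Neumann oracle: surface potential of a current dipole
# in a homogeneous sphere (insulated outside). Independent of the BEM: the
# infinite-medium potential is evaluated analytically on a quadrature grid,
# projected on spherical harmonics, and each degree is scaled by the
# boundary-condition factor (2n+1)/n.
oracle_sphere_potential <- function(moment, position, sigma, R_mm, pts_mm,
                                    nmax = 40, ngrid = 120) {
  R <- R_mm * 1e-3; pts <- pts_mm * 1e-3; pos <- position * 1e-3
  phi_inf <- function(P) {
    d <- sweep(P, 2, pos)
    as.numeric(d %*% moment) / (4 * pi * sigma * rowSums(d^2)^1.5)
  }
  gl <- pracma::gaussLegendre(ngrid, -1, 1)
  ct <- gl$x; wt <- gl$w
  phis <- (seq_len(ngrid) - 0.5) * 2 * pi / ngrid
  grid <- expand.grid(i = seq_len(ngrid), j = seq_len(ngrid))
  st <- sqrt(1 - ct^2)
  G <- cbind(st[grid$i] * cos(phis[grid$j]),
             st[grid$i] * sin(phis[grid$j]), ct[grid$i]) * R
  w <- wt[grid$i] * (2 * pi / ngrid)
  f <- phi_inf(G)
  ptsn <- pts / sqrt(rowSums(pts^2))
  ct_p <- ptsn[, 3]; phi_p <- atan2(ptsn[, 2], ptsn[, 1])
  out <- numeric(nrow(pts))
  for (n in 1:nmax) {
    Pg <- pracma::legendre(n, ct[grid$i])
    Pp <- pracma::legendre(n, ct_p)
    for (m in 0:n) {
      for (tr in if (m == 0) "c" else c("c", "s")) {
        az_g <- if (tr == "c") cos(m * phis[grid$j]) else
          sin(m * phis[grid$j])
        az_p <- if (tr == "c") cos(m * phi_p) else sin(m * phi_p)
        Yg <- Pg[m + 1, ] * az_g
        Yp <- Pp[m + 1, ] * az_p
        nrm <- sum(w * Yg^2)
        if (nrm < 1e-300) next
        coef <- sum(w * f * Yg) / nrm
        out <- out + (2 * n + 1) / n * coef * Yp
      }
    }
  }
  out
}

# Brute-force line-current loop: E = -(mu0 dIdt / 4 pi) * contour integral
# of dl / |r - r'| for a circular loop, the oracle for a single magnetic
# dipole at distances much larger than the loop radius.
loop_primary_efield <- function(center_mm, normal, radius_mm, dIdt,
                                points_mm, nseg = 2000) {
  n <- normal / sqrt(sum(normal^2))
  t1 <- c(1, 0, 0) - n[1] * n
  if (sqrt(sum(t1^2)) < 1e-6) t1 <- c(0, 1, 0) - n[2] * n
  t1 <- t1 / sqrt(sum(t1^2))
  t2 <- c(n[2] * t1[3] - n[3] * t1[2], n[3] * t1[1] - n[1] * t1[3],
          n[1] * t1[2] - n[2] * t1[1])
  th <- (seq_len(nseg) - 0.5) * 2 * pi / nseg
  P <- matrix(points_mm, ncol = 3) * 1e-3
  c0 <- center_mm * 1e-3
  r <- radius_mm * 1e-3
  E <- matrix(0, nrow(P), 3)
  for (k in seq_len(nseg)) {
    pos <- c0 + r * (cos(th[k]) * t1 + sin(th[k]) * t2)
    dl <- r * (2 * pi / nseg) * (-sin(th[k]) * t1 + cos(th[k]) * t2)
    d <- sweep(P, 2, pos)
    E <- E + matrix(dl, nrow(P), 3, byrow = TRUE) / sqrt(rowSums(d^2))
  }
  -1e-7 * dIdt * E
}
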