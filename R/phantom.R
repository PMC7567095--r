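#' Synthetic rat-head phantom specification
#'
#' Parameters of the synthetic geometry standing in for a real rodent
#' micro-CT: an oblong ellipsoidal "front half" body, a thin ellipsoidal
#' skull shell floating inside it with spherical-cap holes (one posterior
#' foramen-magnum-like opening and two anterolateral orbital openings), and
#' a cortical evaluation surface at least `eval_margin` inside the inner
#' skull sheet. Defaults are deliberately rat-like in scale but are not
#' calibrated to any individual animal.
#'
#' @param body_semiaxes ellipsoid semi-axes of the body (mm); +x is
#'   anterior (nose), +z dorsal (up). The body stands for the front half of
#'   the animal: head plus anterior trunk.
#' @param skull_semiaxes semi-axes of the outer skull sheet (mm). The skull
#'   is a cranial capsule at the head end of the body, not a liner of the
#'   whole body: its posterior hole must open into the trunk volume for the
#'   path-of-least-resistance (funnelling) physics to exist.
#' @param skull_center centre of the skull capsule (mm), anterior and
#'   roughly centred in y/z.
#' @param skull_offset minimum clearance between the outer skull sheet and
#'   the scalp at the crown (mm); validated at build time.
#' @param skull_thickness bone shell thickness (mm), > 0.
#' @param holes list of holes, each `list(direction = <len-3>, angle =
#'   <angular radius, degrees>)` on the shell.
#' @param eval_margin minimum distance from the evaluation surface to the
#'   inner skull sheet (mm).
#' @param brainstem_length length (mm) of the brainstem-like extension of
#'   the brain volume through the posterior (first) hole into the trunk;
#'   0 disables it. The brainstem is what makes the hole-funnelling physics
#'   observable on the evaluation surface, as in a real rodent where the
#'   brainstem leaves the skull through the foramen magnum.
#' @param brainstem_radius radius (mm) of the brainstem tube, or `NULL` to
#'   derive it from the posterior hole size minus the evaluation margin.
#' @param body_edge,skull_edge,eval_edge target mean edge lengths (mm) of
#'   the generated meshes.
#' @param sigma_body,sigma_skull tissue conductivities (S/m); the
#'   skull-to-body ratio defaults to 1/50.
#' @param seed random seed used by CT synthesis.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(body_semiaxes = c(30, 16, 14),
                         skull_semiaxes = c(13.5, 14.3, 12),
                         skull_center = c(8, 0, -0.5),
                         skull_offset = 1.5,
                         skull_thickness = 0.7,
                         holes = default_phantom_holes(),
                         eval_margin = 1,
                         brainstem_length = 9,
                         brainstem_radius = NULL,
                         body_edge = 1.4,
                         skull_edge = 0.67,
                         eval_edge = 1,
                         sigma_body = 0.33,
                         sigma_skull = 0.33 / 50,
                         seed = 1L) {
  stopifnot(length(body_semiaxes) == 3L, all(body_semiaxes > 0),
            length(skull_semiaxes) == 3L, all(skull_semiaxes > 0),
            length(skull_center) == 3L,
            skull_offset > 0, skull_thickness > 0, eval_margin >= 0,
            body_edge > 0, skull_edge > 0, eval_edge > 0)
  if (length(holes) > 1L) {
    for (i in seq_along(holes)[-1L]) for (j in seq_len(i - 1L)) {
      di <- holes[[i]]$direction / sqrt(sum(holes[[i]]$direction^2))
      dj <- holes[[j]]$direction / sqrt(sum(holes[[j]]$direction^2))
      sep <- acos(pmin(1, pmax(-1, sum(di * dj)))) * 180 / pi
      if (sep <= holes[[i]]$angle + holes[[j]]$angle)
        stop("phantom_spec: holes ", j, " and ", i, " overlap")
    }
  }
  structure(list(body_semiaxes = body_semiaxes,
                 skull_semiaxes = skull_semiaxes,
                 skull_center = skull_center,
                 skull_offset = skull_offset,
                 skull_thickness = skull_thickness, holes = holes,
                 eval_margin = eval_margin,
                 brainstem_length = brainstem_length,
                 brainstem_radius = brainstem_radius,
                 body_edge = body_edge,
                 skull_edge = skull_edge, eval_edge = eval_edge,
                 sigma_body = sigma_body, sigma_skull = sigma_skull,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default skull holes of the rat phantom
#'
#' One posterior opening where the brainstem would leave the skull and two
#' anterolateral openings behind the orbits.
#' @return list of hole descriptors.
#' @export
default_phantom_holes <- function() {
  list(list(direction = c(-1, 0, -0.15), angle = 20),
       list(direction = c(0.75, 0.6, 0.28), angle = 10),
       list(direction = c(0.75, -0.6, 0.28), angle = 10))
}

#' Build the synthetic rat-head phantom
#'
#' Constructs the two-compartment volume conductor (body surface plus one
#' closed skull-with-holes surface floating inside it), the cortical
#' evaluation surface, and the brain (intracranial cavity) surface used to
#' derive ground-truth masks. The skull surface is a single closed
#' 2-manifold: outer and inner ellipsoidal sheets with matching cap cutouts
#' joined by rim strips, so a phantom with n holes has genus n - 1
#' (Euler characteristic `2 - 2 * (n - 1)`); with zero holes it degenerates
#' to two disjoint closed sheets (Euler characteristic 4).
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `model` (a `compartment_model`: body +
#'   floating skull), `scalp` (body `trimesh`), `skull`, `brain` (inner
#'   cavity surface), `evaluation` (cortical surface), and `spec`.
#' @export
make_rat_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  sa_body <- spec$body_semiaxes
  sa_out <- spec$skull_semiaxes
  ctr <- spec$skull_center
  sa_in <- sa_out - spec$skull_thickness
  if (any(sa_in <= 0))
    stop("make_rat_phantom: skull shell thicker than its semi-axes")
  body <- make_ellipsoid(sa_body, target_edge = spec$body_edge)
  body$label <- "body"
  skull <- make_skull_shell(sa_out, sa_in, spec$holes, spec$skull_edge,
                            center = ctr)
  skull$label <- "skull"
  # containment and crown clearance
  dist_to_body <- point_mesh_distance(skull$vertices, body)
  if (!all(inside_surface(body, skull$vertices)))
    stop("make_rat_phantom: skull not contained in the body")
  top <- skull$vertices[which.max(skull$vertices[, 3L]), , drop = FALSE]
  if (point_mesh_distance(top, body) < spec$skull_offset - 0.25)
    stop("make_rat_phantom: skull-to-scalp crown clearance below ",
         spec$skull_offset, " mm")
  # brain volume: intracranial ellipsoid, optionally extended by a
  # brainstem-like capsule through the posterior hole into the trunk
  inset <- spec$eval_margin + 0.5    # margin + discretisation allowance
  sa_eval <- sa_in - inset
  if (any(sa_eval <= 0))
    stop("make_rat_phantom: evaluation margin too large for the phantom")
  stem <- NULL
  if (spec$brainstem_length > 0 && length(spec$holes) > 0L) {
    hole <- spec$holes[[1L]]
    d <- hole$direction / sqrt(sum(hole$direction^2))
    r_hole <- sin(hole$angle * pi / 180) * mean(sa_in)
    r_bs <- if (is.null(spec$brainstem_radius))
      r_hole - inset else spec$brainstem_radius
    if (r_bs <= 0)
      stop("make_rat_phantom: posterior hole too small for a brainstem")
    # axis from the skull centre out through the hole, ending in the trunk
    len <- mean(sa_in) + spec$brainstem_length
    stem <- list(a = ctr, b = ctr + d * len, r = r_bs, r_brain = r_hole - 0.2)
  }
  brain <- implicit_brain_surface(sa_in - 0.2, ctr, stem, use_brain_r = TRUE,
                                  edge = spec$eval_edge)
  brain$label <- "evaluation"
  evaluation <- implicit_brain_surface(sa_eval, ctr, stem,
                                       use_brain_r = FALSE,
                                       edge = spec$eval_edge)
  # extraction + remeshing can eat into the inset; re-inset once if the
  # realised margin falls short
  for (tries in 1:2) {
    deficit <- spec$eval_margin -
      min(point_mesh_distance(evaluation$vertices, skull))
    if (deficit <= 0) break
    sa_eval <- sa_eval - deficit - 0.1
    if (!is.null(stem)) stem$r <- stem$r - deficit - 0.1
    if (any(sa_eval <= 0) || (!is.null(stem) && stem$r <= 0))
      stop("make_rat_phantom: evaluation margin too large for the phantom")
    evaluation <- implicit_brain_surface(sa_eval, ctr, stem,
                                         use_brain_r = FALSE,
                                         edge = spec$eval_edge)
  }
  evaluation$label <- "evaluation"
  model <- compartment_model(
    list(body, skull),
    sigma_in = c(spec$sigma_body, spec$sigma_skull),
    sigma_out = c(0, spec$sigma_body))
  list(model = model, scalp = body, skull = skull, brain = brain,
       evaluation = evaluation, spec = spec)
}

# Closed skull-with-holes surface: outer/inner ellipsoid sheets sharing the
# connectivity of one base icosphere, with cap faces removed and the two
# sheets joined by rim strips along the snapped cap circles.
make_skull_shell <- function(sa_out, sa_in, holes, target_edge,
                             center = c(0, 0, 0)) {
  base <- make_icosphere(1, subdivisions = pick_subdiv(sa_out, target_edge))
  u <- base$vertices
  f <- base$faces
  keep <- rep(TRUE, nrow(f))
  in_cap <- rep(FALSE, nrow(u))
  for (h in holes) {
    d <- h$direction / sqrt(sum(h$direction^2))
    ca <- cos(h$angle * pi / 180)
    cent <- (u[f[, 1L], ] + u[f[, 2L], ] + u[f[, 3L], ]) / 3
    cent <- cent / sqrt(rowSums(cent^2))
    keep <- keep & (cent %*% d)[, 1L] < ca
    in_cap <- in_cap | (u %*% d)[, 1L] > ca
  }
  fk <- f[keep, , drop = FALSE]
  if (nrow(fk) == nrow(f) && length(holes) > 0L)
    stop("make_skull_shell: holes finer than the shell discretisation")
  # rim vertices: used by kept faces but inside a cap -> snap onto the circle
  used <- unique(as.integer(fk))
  for (h in holes) {
    d <- h$direction / sqrt(sum(h$direction^2))
    alpha <- h$angle * pi / 180
    idx <- intersect(used, which((u %*% d)[, 1L] > cos(alpha)))
    for (i in idx) {
      v <- u[i, ]
      cb <- sum(v * d)
      t <- v - cb * d
      nt <- sqrt(sum(t^2))
      if (nt < 1e-12) stop("make_skull_shell: hole centred on a vertex")
      u[i, ] <- cos(alpha) * d + sin(alpha) * t / nt
    }
  }
  # rim (boundary) directed edges of the kept sheet
  de <- rbind(fk[, c(1L, 2L)], fk[, c(2L, 3L)], fk[, c(3L, 1L)])
  key <- paste(pmin(de[, 1L], de[, 2L]), pmax(de[, 1L], de[, 2L]))
  bnd <- de[key %in% names(which(table(key) == 1L)), , drop = FALSE]
  # assemble: outer sheet, flipped inner sheet, rounded rim strips (a
  # semicircular profile bulging into the hole: "smooth rim connection")
  nv <- length(used)
  map <- integer(nrow(u)); map[used] <- seq_len(nv)
  uo <- u[used, , drop = FALSE]
  v_out <- sweep(uo, 2L, sa_out, `*`)
  v_in <- sweep(uo, 2L, sa_in, `*`)
  f_out <- matrix(map[fk], ncol = 3L)
  f_in <- matrix(map[fk], ncol = 3L)[, c(1L, 3L, 2L), drop = FALSE] + nv
  verts <- rbind(v_out, v_in)
  rim <- NULL
  if (nrow(bnd) > 0L) {
    n_ring <- 3L   # intermediate rings of the rounded profile
    rim_ids <- map[sort(unique(as.integer(bnd)))]  # compact sheet ids
    # nearest hole axis per rim vertex (for the bulge direction)
    ring_start <- nrow(verts)
    ring_of <- matrix(0L, length(rim_ids), n_ring)
    for (ri in seq_along(rim_ids)) {
      id <- rim_ids[ri]
      uu <- uo[id, ]
      best <- which.max(vapply(holes, function(h) {
        d <- h$direction / sqrt(sum(h$direction^2)); sum(uu * d)
      }, 0))
      d <- holes[[best]]$direction /
        sqrt(sum(holes[[best]]$direction^2))
      tt <- d - sum(d * uu) * uu
      tt <- tt / sqrt(sum(tt^2))
      po <- v_out[id, ]; pi_ <- v_in[id, ]
      mmid <- (po + pi_) / 2
      ax <- (po - pi_) / 2
      r <- sqrt(sum(ax^2))
      # world-space bulge direction (tangent mapped through the scaling)
      tw <- tt * (sa_out + sa_in) / 2
      tw <- tw / sqrt(sum(tw^2))
      th <- seq_len(n_ring) * pi / (n_ring + 1L)
      pts <- t(vapply(th, function(a)
        mmid + cos(a) * ax + r * sin(a) * tw, numeric(3L)))
      ring_of[ri, ] <- nrow(verts) + seq_len(n_ring)
      verts <- rbind(verts, pts)
    }
    lookup <- integer(nv); lookup[rim_ids] <- seq_along(rim_ids)
    a <- map[bnd[, 1L]]; b <- map[bnd[, 2L]]
    lev <- function(ids, k) {   # vertex index of ring level k (0..n_ring+1)
      if (k == 0L) ids
      else if (k == n_ring + 1L) ids + nv
      else ring_of[cbind(lookup[ids], rep(k, length(ids)))]
    }
    for (k in 0:(n_ring)) {
      a0 <- lev(a, k); b0 <- lev(b, k)
      a1 <- lev(a, k + 1L); b1 <- lev(b, k + 1L)
      rim <- rbind(rim, cbind(b0, a0, a1), cbind(b0, a1, b1))
    }
  }
  m <- trimesh(sweep(verts, 2L, -center), rbind(f_out, f_in, rim))
  rep <- validate_mesh(m, require_closed = TRUE)
  if (!rep$closed || !isTRUE(rep$oriented))
    stop("make_skull_shell: construction failed: ",
         paste(rep$defects, collapse = "; "))
  # hit the requested resolution when the subdivision ladder lands far off
  st <- mesh_statistics(m)
  if (abs(st$mean_edge - target_edge) > 0.15 * target_edge)
    m <- remesh_to_target_edge(m, target_edge)
  m
}

pick_subdiv <- function(semiaxes, target_edge) {
  e0 <- 1.0514 * mean(semiaxes)
  max(1L, round(log2(e0 / target_edge)))
}

#' Synthesize a CT volume from a conductor model
#'
#' Voxelises the model surfaces on an isotropic grid and assigns Hounsfield
#' units by containment (air outside the body, soft tissue inside, bone
#' inside the skull surface), then adds seeded Gaussian noise. The default
#' HU targets (-1000 / +40 / +1500) give the three-peak histogram that the
#' threshold segmentation recipe assumes.
#'
#' @param model a `compartment_model` whose first surface is the body and
#'   whose remaining surfaces (if any) bound bone.
#' @param spacing isotropic voxel size (mm), default 0.17.
#' @param noise_sd Gaussian noise standard deviation (HU).
#' @param seed random seed for the noise.
#' @param hu named HU levels (`air`, `soft`, `bone`).
#' @param padding air margin around the model (mm), >= 2.
#' @return a `ct_volume`.
#' @export
synthesize_ct <- function(model, spacing = 0.17, noise_sd = 0, seed = 1L,
                          hu = c(air = -1000, soft = 40, bone = 1500),
                          padding = 2) {
  stopifnot(inherits(model, "compartment_model"), spacing > 0, padding >= 2)
  body <- model$surfaces[[1L]]
  grid <- empty_grid(apply(body$vertices, 2L, min),
                     apply(body$vertices, 2L, max), spacing, padding)
  vol <- grid
  vol$data[] <- hu[["air"]]
  inside_body <- voxelize_mesh(body, grid)
  vol$data[inside_body$data] <- hu[["soft"]]
  for (s in model$surfaces[-1L]) {
    inside <- voxelize_mesh(s, grid)
    vol$data[inside$data] <- hu[["bone"]]
  }
  if (noise_sd > 0) {
    set.seed(seed)
    vol$data <- vol$data + array(stats::rnorm(length(vol$data),
                                              sd = noise_sd),
                                 dim = dim(vol$data))
  }
  vol
}

# Brain / evaluation surface from an implicit ellipsoid-plus-capsule union,
# extracted with marching tetrahedra on a fine grid and remeshed.
implicit_brain_surface <- function(semiaxes, center, stem, use_brain_r,
                                   edge) {
  lo <- center - semiaxes
  hi <- center + semiaxes
  if (!is.null(stem)) {
    r <- if (use_brain_r) stem$r_brain else stem$r
    lo <- pmin(lo, pmin(stem$a, stem$b) - r)
    hi <- pmax(hi, pmax(stem$a, stem$b) + r)
  }
  spacing <- max(0.4, edge / 2)
  grid <- empty_grid(lo, hi, spacing, padding = 2)
  dm <- dim(grid$data)
  idx <- arrayInd(seq_along(grid$data), dm) - 1L
  P <- sweep(idx * grid$spacing, 2L, -grid$origin)
  q <- sweep(P, 2L, center)
  inside <- rowSums(sweep(q, 2L, semiaxes, `/`)^2) <= 1
  if (!is.null(stem)) {
    r <- if (use_brain_r) stem$r_brain else stem$r
    ab <- stem$b - stem$a
    t <- pmin(1, pmax(0, as.numeric(sweep(P, 2L, stem$a) %*% ab) /
                        sum(ab^2)))
    cp <- cbind(stem$a[1L] + t * ab[1L], stem$a[2L] + t * ab[2L],
                stem$a[3L] + t * ab[3L])
    inside <- inside | rowSums((P - cp)^2) <= r^2
  }
  grid$data[] <- inside
  grid$data <- array(as.logical(grid$data), dm)
  # smooth extraction: this is a synthetic smooth volume (no thin features
  # at the grid scale), so the box pre-filter only removes staircase ripple
  m <- iso_surface(grid, level = 0.5, smooth_mask = TRUE)
  m <- remesh_to_target_edge(m, edge)
  m
}
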