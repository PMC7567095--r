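#' Run configuration
#'
#' Configuration of an end-to-end comparison run: input geometry (a phantom
#' spec, or CT + masks for real data), the model variants to build, coil
#' and placement-grid parameters, and output options.
#'
#' @param phantom a [phantom_spec()] (synthetic input).
#' @param variants model variants to compute; subset of `"2C"` (body +
#'   floating skull), `"1C"` (body only), `"sphere"` (fitted spherically
#'   symmetric model), `"infinite"` (infinite homogeneous medium).
#' @param reference the variant used as reference for error metrics.
#' @param coil a [coil_spec()].
#' @param region_extent tangential extent (mm, length 2) of the placement
#'   region on the scalp.
#' @param position_spacing grid spacing (mm); the default 2.5 mm tiles a
#'   15 x 10 mm region with 7 x 5 = 35 positions.
#' @param angle_step orientation step (degrees); must divide 180.
#' @param orientation_equivalence treat orientations theta and theta + 180
#'   as the same placement (figure-of-eight field reversal); angles then
#'   span [0, 180).
#' @param standoff coil-to-scalp standoff (mm).
#' @param dIdt coil current rate of change (A/s); default 50 A/us.
#' @param seed random seed.
#' @param sphere_region_radius radius (mm) of the crown patch used for the
#'   sphere fit.
#' @return an object of class `run_config`.
#' @export
run_config <- function(phantom = phantom_spec(),
                       variants = c("2C", "sphere", "infinite"),
                       reference = "2C",
                       coil = coil_spec(),
                       region_extent = c(15, 10),
                       position_spacing = 2.5,
                       angle_step = 10,
                       orientation_equivalence = TRUE,
                       standoff = 0,
                       dIdt = 50e6,
                       seed = 1L,
                       sphere_region_radius = 8) {
  if (180 %% angle_step != 0)
    stop("run_config: angle_step must divide 180")
  if (any(region_extent <= 0) || position_spacing <= 0)
    stop("run_config: region extent and spacing must be positive")
  variants <- match.arg(variants, c("2C", "1C", "sphere", "infinite"),
                        several.ok = TRUE)
  if (!reference %in% variants)
    stop("run_config: reference variant must be among the variants")
  structure(list(phantom = phantom, variants = variants,
                 reference = reference, coil = coil,
                 region_extent = region_extent,
                 position_spacing = position_spacing,
                 angle_step = angle_step,
                 orientation_equivalence = orientation_equivalence,
                 standoff = standoff, dIdt = dIdt, seed = as.integer(seed),
                 sphere_region_radius = sphere_region_radius),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  ph <- do.call(phantom_spec, c(y$phantom, list()))
  cl <- do.call(coil_spec, c(y$coil, list()))
  args <- y[setdiff(names(y), c("phantom", "coil"))]
  do.call(run_config, c(list(phantom = ph, coil = cl), args))
}

#' Write a run configuration to YAML
#' @param config a `run_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  y <- unclass(config)
  y$phantom <- unclass(y$phantom)
  y$phantom$holes <- lapply(y$phantom$holes, function(h)
    list(direction = as.numeric(h$direction), angle = h$angle))
  y$coil <- unclass(y$coil)
  yaml::write_yaml(y, path)
  invisible(path)
}

# first-hit intersection of a downward ray with the mesh; returns position
# and outward triangle normal, or NULL
ray_down_hit <- function(mesh, x, y, from_z) {
  fc <- face_corners(mesh)
  orig <- c(x, y, from_z)
  dir <- c(0, 0, -1)
  e1 <- fc$b - fc$a
  e2 <- fc$c - fc$a
  h <- cross3(matrix(dir, nrow(e1), 3L, byrow = TRUE), e2)
  det <- rowSums(e1 * h)
  ok <- abs(det) > 1e-12
  s <- sweep(-fc$a, 2L, -orig)   # orig - a
  u <- rowSums(s * h) / det
  q <- cross3(s, e1)
  v <- (q %*% dir)[, 1L] / det
  t <- rowSums(e2 * q) / det
  hit <- ok & u >= 0 & v >= 0 & (u + v) <= 1 & t > 1e-9
  if (!any(hit)) return(NULL)
  i <- which(hit)[which.min(t[hit])]
  fg <- face_geometry(mesh)
  n <- fg$normals[i, ]
  if (n[3L] < 0) n <- -n
  list(position = orig + t[i] * dir, normal = n)
}

#' Placement grid on the scalp
#'
#' Regular grid of coil positions projected vertically onto the scalp crown,
#' combined with all tangential orientations at the configured angular
#' step. With orientation equivalence on, theta and theta + 180 degrees are
#' one placement (the figure-of-eight field merely reverses sign), so
#' angles span [0, 180); a 15 x 10 mm region at 2.5 mm spacing and a
#' 10-degree step gives 35 x 18 = 630 unique placements.
#'
#' @param scalp the body/scalp `trimesh`.
#' @param config a `run_config`.
#' @param center optional grid centre (mm, x/y); defaults to the scalp
#'   point of maximum z.
#' @return list of [coil_placement()] objects with attributes
#'   `n_positions` and `n_angles`.
#' @export
placement_grid <- function(scalp, config, center = NULL) {
  stopifnot(is_trimesh(scalp))
  if (is.null(center)) {
    top <- scalp$vertices[which.max(scalp$vertices[, 3L]), ]
    center <- top[1:2]
  }
  ext <- config$region_extent
  sp <- config$position_spacing
  xs <- seq(-ext[1L] / 2, ext[1L] / 2, by = sp) + center[1L]
  ys <- seq(-ext[2L] / 2, ext[2L] / 2, by = sp) + center[2L]
  from_z <- max(scalp$vertices[, 3L]) + 10
  angles <- if (config$orientation_equivalence)
    seq(0, 180 - config$angle_step, by = config$angle_step)
  else seq(0, 360 - config$angle_step, by = config$angle_step)
  placements <- list()
  failed <- integer(0)
  pos_id <- 0L
  for (y in ys) for (x in xs) {
    pos_id <- pos_id + 1L
    hit <- ray_down_hit(scalp, x, y, from_z)
    if (is.null(hit)) { failed <- c(failed, pos_id); next }
    for (a in angles) {
      pl <- coil_placement(hit$position, angle = a, normal = hit$normal)
      pl$position_id <- pos_id
      placements[[length(placements) + 1L]] <- pl
    }
  }
  if (length(failed) > 0L)
    stop("placement_grid: position(s) off the scalp: ",
         paste(failed, collapse = ", "))
  attr(placements, "n_positions") <- length(xs) * length(ys)
  attr(placements, "n_angles") <- length(angles)
  placements
}

#' Config-driven multi-model comparison run
#'
#' Builds the phantom geometry and the requested model variants, computes
#' the cortical E-field for every placement of the grid with every variant,
#' and compares each variant against the reference variant with the full
#' metric set. Per-placement failures are recorded and the run continues.
#'
#' @param config a `run_config`.
#' @param placements optional explicit placement list (defaults to
#'   [placement_grid()] on the phantom scalp).
#' @param keep_fields keep all computed `field_set`s in the report (memory
#'   permitting).
#' @return an object of class `comparison_report`: `per_placement` (data
#'   frame of metrics), `summaries` (per variant x metric), `errors`
#'   (failed placements), `overestimation` (peak |E| ratio of the
#'   infinite-medium model to the reference, when both are computed),
#'   plus run metadata.
#' @export
run_comparison <- function(config, placements = NULL, keep_fields = FALSE) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  ph <- make_rat_phantom(config$phantom)
  eval_pts <- ph$evaluation$vertices
  if (is.null(placements)) {
    # centre the grid above the cortex (skull crown), not the body apex
    crown <- eval_pts[which.max(eval_pts[, 3L]), ]
    placements <- placement_grid(ph$scalp, config, center = crown[1:2])
  }
  coil0 <- build_figure8_quadrature(config$coil)

  systems <- list()
  if ("2C" %in% config$variants)
    systems[["2C"]] <- build_deflated_system(
      assemble_double_layer(ph$model))
  if ("1C" %in% config$variants) {
    m1 <- compartment_model(list(ph$scalp),
                            sigma_in = config$phantom$sigma_body,
                            sigma_out = 0)
    systems[["1C"]] <- build_deflated_system(assemble_double_layer(m1))
  }
  sphere <- NULL
  n_excluded <- 0L
  if ("sphere" %in% config$variants) {
    # global sphere fitted once to the hole-free crown of the inner skull
    crown <- ph$brain$vertices[which.max(ph$brain$vertices[, 3L]), ]
    sphere <- fit_local_sphere(ph$brain, crown, config$sphere_region_radius)
    # the closed-form field is only valid for points at radii smaller than
    # the smallest origin-to-coil distance; restrict the shared point set
    # to the worst case over the grid so every variant sees the same points
    vmin <- min(vapply(placements, function(pl) {
      coil <- place_coil_tangential(coil0, pl, standoff = config$standoff)
      sphere_validity_radius(sphere, coil)
    }, 0))
    r <- sqrt(colSums((t(eval_pts) - sphere$origin)^2))
    keep <- r < vmin - 0.25
    if (sum(keep) < 10L)
      stop("run_comparison: sphere validity radius excludes the cortex")
    n_excluded <- sum(!keep)
    eval_pts <- eval_pts[keep, , drop = FALSE]
  }
  models <- list(`2C` = ph$model,
                 `1C` = if ("1C" %in% config$variants)
                   systems[["1C"]]$model else NULL)

  rows <- list(); errors <- list(); fields <- list()
  peak_inf <- c(); peak_ref <- c()
  for (pi in seq_along(placements)) {
    pl <- placements[[pi]]
    res <- tryCatch({
      coil <- place_coil_tangential(coil0, pl, standoff = config$standoff)
      fs <- list()
      for (v in config$variants) {
        fs[[v]] <- switch(v,
          "2C" = bem_efield(ph$model, systems[["2C"]], coil, config$dIdt,
                            eval_pts, check = (pi == 1L)),
          "1C" = bem_efield(systems[["1C"]]$model, systems[["1C"]], coil,
                            config$dIdt, eval_pts, check = (pi == 1L)),
          "sphere" = sphere_efield(sphere, coil, config$dIdt, eval_pts),
          "infinite" = primary_efield(coil, config$dIdt, eval_pts))
        fs[[v]]$placement_id <- pi
      }
      ref <- fs[[config$reference]]
      out <- list()
      for (v in setdiff(config$variants, config$reference)) {
        cmp <- compare_fields(fs[[v]], ref)
        cmp$variant <- v
        cmp$placement <- pi
        cmp$position_id <- pl$position_id
        cmp$angle <- pl$angle
        cmp$proj_angle <- projected_orientation_angle(fs[[v]], coil)
        out[[v]] <- cmp
      }
      if ("infinite" %in% config$variants) {
        peak_inf <- c(peak_inf, max(field_magnitude(fs[["infinite"]])))
        peak_ref <- c(peak_ref, max(field_magnitude(ref)))
      }
      if (keep_fields) fields[[pi]] <- fs
      do.call(rbind, out)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[length(errors) + 1L]] <- list(placement = pi,
                                            message = conditionMessage(res))
    } else rows[[length(rows) + 1L]] <- res
  }
  per_placement <- if (length(rows)) do.call(rbind, rows) else
    data.frame(re = numeric(0), cce = numeric(0), ang = numeric(0),
               peak_mm = numeric(0), variant = character(0))
  summaries <- NULL
  if (nrow(per_placement) > 0L) {
    summaries <- do.call(rbind, lapply(
      split(per_placement, per_placement$variant), function(dd) {
        metrics <- c("re", "cce", "ang", "peak_mm", "re_hot", "ang_hot")
        do.call(rbind, lapply(metrics, function(m) {
          s <- summarize_metric(dd[[m]])
          cbind(data.frame(variant = dd$variant[1L], metric = m), s)
        }))
      }))
    rownames(summaries) <- NULL
  }
  over <- if (length(peak_inf) > 0L) peak_inf / peak_ref else NULL
  structure(list(per_placement = per_placement, summaries = summaries,
                 errors = errors, overestimation = over,
                 fields = if (keep_fields) fields else NULL,
                 n_placements = length(placements),
                 n_points_excluded = n_excluded,
                 reference = config$reference,
                 variants = config$variants,
                 seed = config$seed),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("comparison_report: %d placements, reference %s, %d failed\n",
              x$n_placements, x$reference, length(x$errors)))
  if (!is.null(x$summaries)) print(x$summaries, digits = 3)
  invisible(x)
}

#' Export a comparison report
#'
#' Writes the per-placement metric table as CSV, the grid summaries as
#' JSON, and (optionally) VTK snapshots of the stored fields for a capped
#' number of placements.
#'
#' @param report a `comparison_report`.
#' @param outdir output directory (created if needed).
#' @param vtk_cap maximum number of placements to export as VTK point data.
#' @return character vector of files written, invisibly.
#' @export
export_report <- function(report, outdir, vtk_cap = 4L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("export_report: cannot create ", outdir)
  files <- character(0)
  f1 <- file.path(outdir, "per_placement.csv")
  utils::write.csv(report$per_placement, f1, row.names = FALSE)
  files <- c(files, f1)
  f2 <- file.path(outdir, "summary.json")
  jsonlite::write_json(list(
    n_placements = report$n_placements,
    reference = report$reference,
    variants = report$variants,
    seed = report$seed,
    n_failed = length(report$errors),
    overestimation_median = if (is.null(report$overestimation)) NULL else
      stats::median(report$overestimation),
    summaries = report$summaries), f2, auto_unbox = TRUE, digits = NA,
    pretty = TRUE, null = "null")
  files <- c(files, f2)
  if (!is.null(report$fields)) {
    nexp <- 0L
    for (pi in seq_along(report$fields)) {
      if (nexp >= vtk_cap) break
      fs <- report$fields[[pi]]
      if (is.null(fs)) next
      for (v in names(fs)) {
        fv <- file.path(outdir, sprintf("field_p%03d_%s.vtk", pi, v))
        write_fieldset_vtk(fs[[v]], fv)
        files <- c(files, fv)
      }
      nexp <- nexp + 1L
    }
  }
  invisible(files)
}

#' Read back an exported report summary
#' @param outdir directory written by [export_report()].
#' @return list with `per_placement` data frame and `summary` list.
#' @export
read_report <- function(outdir) {
  list(per_placement = utils::read.csv(file.path(outdir,
                                                 "per_placement.csv")),
       summary = jsonlite::read_json(file.path(outdir, "summary.json"),
                                     simplifyVector = TRUE))
}

#' Write a field set as CSV
#' @param fs a `field_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fieldset_csv <- function(fs, path) {
  mag <- field_magnitude(fs)
  utils::write.csv(data.frame(x = fs$points[, 1L], y = fs$points[, 2L],
                              z = fs$points[, 3L], Ex = fs$E[, 1L],
                              Ey = fs$E[, 2L], Ez = fs$E[, 3L],
                              Emag = mag),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a field set as legacy-VTK point data
#' @param fs a `field_set`.
#' @param path output path (`.vtk`).
#' @return `path`, invisibly.
#' @export
write_fieldset_vtk <- function(fs, path) {
  n <- nrow(fs$points)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "E-field point data", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.9g %.9g %.9g", fs$points[, 1L], fs$points[, 2L],
                     fs$points[, 3L]), con)
  writeLines(c(sprintf("POINT_DATA %d", n), "VECTORS E double"), con)
  writeLines(sprintf("%.9g %.9g %.9g", fs$E[, 1L], fs$E[, 2L],
                     fs$E[, 3L]), con)
  invisible(path)
}
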