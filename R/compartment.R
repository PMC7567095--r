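#' Piecewise-homogeneous volume conductor model
#'
#' An ordered set of closed boundary surfaces, outermost first, each with
#' the conductivity of the region just inside and just outside it (S/m).
#' A "floating skull" — one closed surface bounding the bone shell, holes
#' included, placed inside the body surface — is supported provided the
#' conductivity on both sides of the holes (i.e. intracranial and body) is
#' equal, which is expressed here by the skull surface's `sigma_out` being
#' the body conductivity.
#'
#' @param surfaces list of closed, outward-oriented `trimesh` objects,
#'   outermost first.
#' @param sigma_in numeric vector, conductivity just inside each surface.
#' @param sigma_out numeric vector, conductivity just outside each surface;
#'   the outermost surface must have `sigma_out = 0` (non-conducting air).
#' @param validate run [validate_mesh()] on every surface.
#' @return an object of class `compartment_model`.
#' @export
compartment_model <- function(surfaces, sigma_in, sigma_out,
                              validate = TRUE) {
  stopifnot(is.list(surfaces), length(surfaces) >= 1L,
            length(sigma_in) == length(surfaces),
            length(sigma_out) == length(surfaces))
  if (sigma_out[1L] != 0)
    stop("compartment_model: outermost surface must have sigma_out = 0")
  if (any(sigma_in < 0) || any(sigma_out < 0))
    stop("compartment_model: negative conductivity")
  if (validate) {
    for (i in seq_along(surfaces)) {
      rep <- validate_mesh(surfaces[[i]], require_closed = TRUE)
      if (!rep$closed || !isTRUE(rep$oriented))
        stop("compartment_model: surface ", i,
             " is not a closed outward-oriented manifold: ",
             paste(rep$defects, collapse = "; "))
    }
  }
  structure(list(surfaces = surfaces, sigma_in = as.numeric(sigma_in),
                 sigma_out = as.numeric(sigma_out)),
            class = "compartment_model")
}

#' @export
print.compartment_model <- function(x, ...) {
  cat(sprintf("compartment_model: %d surface(s)\n", length(x$surfaces)))
  for (i in seq_along(x$surfaces)) {
    st <- x$surfaces[[i]]
    cat(sprintf("  [%d] %s: %d vertices, sigma %.4g | %.4g S/m\n", i,
                if (is.null(st$label)) "surface" else st$label,
                nrow(st$vertices), x$sigma_in[i], x$sigma_out[i]))
  }
  invisible(x)
}

#' Nested concentric-spheres conductor model
#'
#' Oracle geometry for solver tests: strictly decreasing radii, one
#' conductivity per enclosed region (the j-th value is the conductivity
#' just inside the j-th sphere); outside the outermost sphere is air.
#'
#' @param radii strictly decreasing sphere radii (mm), outermost first.
#' @param conductivities conductivity (S/m) of the region bounded by each
#'   sphere, same length as `radii`.
#' @param subdivisions icosphere subdivision level for every sphere.
#' @param center common centre (mm).
#' @return a `compartment_model`.
#' @export
make_concentric_spheres_model <- function(radii, conductivities,
                                          subdivisions = 4L,
                                          center = c(0, 0, 0)) {
  if (length(radii) < 1L || any(diff(radii) >= 0))
    stop("make_concentric_spheres_model: radii must be strictly decreasing")
  if (length(conductivities) != length(radii))
    stop("make_concentric_spheres_model: need one conductivity per region")
  surfaces <- lapply(radii, make_icosphere, subdivisions = subdivisions,
                     center = center)
  sigma_in <- conductivities
  sigma_out <- c(0, conductivities[-length(conductivities)])
  compartment_model(surfaces, sigma_in, sigma_out, validate = FALSE)
}
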