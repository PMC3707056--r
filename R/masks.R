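#' Binary mask specifications
#'
#' Masks select voxel subsets for statistics and refinement.  Three kinds are
#' supported, mirroring the classification protocol: a sphere (mask A, "all
#' the density"), an axial cylinder (mask B, "the cavity"), and the set
#' difference of two masks (mask C = A and not B, the complex without its
#' cavity).  A spec is geometry only; [realize_mask()] turns it into a binary
#' [density_map] on a given grid.
#'
#' @param center Voxel coordinates (0-based) of the mask center; `NULL` means
#'   the grid-center voxel `floor(N/2)` used by rotations.
#' @param radius Radius in voxels.
#' @param height Full cylinder height in voxels (cylinder axis is Z).
#' @param a,b Operand [mask_spec]s for the difference `a AND NOT b`.
#' @return A `mask_spec` object.
#' @examples
#' a <- mask_sphere(radius = 10)
#' b <- mask_cylinder(radius = 4, height = 12)
#' cc <- mask_difference(a, b)
#' m <- realize_mask(cc, 32)
#' sum(m$data)
#' @name mask_spec
NULL

new_mask_spec <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "mask_spec")
}

#' @rdname mask_spec
#' @export
mask_sphere <- function(radius, center = NULL) {
  stopifnot(radius > 0)
  new_mask_spec("sphere", radius = radius, center = center)
}

#' @rdname mask_spec
#' @export
mask_cylinder <- function(radius, height, center = NULL) {
  stopifnot(radius > 0, height > 0)
  new_mask_spec("cylinder", radius = radius, height = height, center = center)
}

#' @rdname mask_spec
#' @export
mask_difference <- function(a, b) {
  stopifnot(inherits(a, "mask_spec"), inherits(b, "mask_spec"))
  new_mask_spec("difference", a = a, b = b)
}

#' Realize a mask spec on a cubic grid
#'
#' @param spec A [mask_spec].
#' @param n Grid extent in voxels (or a [density_map] to copy geometry from).
#' @param voxel_size Voxel size carried on the returned map (cosmetic; mask
#'   geometry is specified in voxels).
#' @return A binary (0/1) [density_map].
#' @export
realize_mask <- function(spec, n, voxel_size = 4.4) {
  stopifnot(inherits(spec, "mask_spec"))
  if (is_density_map(n)) { voxel_size <- n$voxel_size; n <- map_side(n) }
  n <- as.integer(n)
  data <- realize_mask_array(spec, n)
  density_map(data, voxel_size = voxel_size)
}

realize_mask_array <- function(spec, n) {
  if (spec$kind == "difference") {
    a <- realize_mask_array(spec$a, n)
    b <- realize_mask_array(spec$b, n)
    return(a * (1 - b))
  }
  ctr <- spec$center %||% rep(n %/% 2, 3)
  if (spec$radius > n / 2)
    abort(sprintf("mask radius %g exceeds half the box (%g)", spec$radius, n / 2))
  idx <- seq_len(n) - 1
  dx <- idx - ctr[1]; dy <- idx - ctr[2]; dz <- idx - ctr[3]
  if (spec$kind == "sphere") {
    r2 <- outer(outer(dx^2, dy^2, "+"), dz^2, "+")
    arr <- (r2 <= spec$radius^2) * 1
  } else { # cylinder, axis Z
    rho2 <- outer(dx^2, dy^2, "+")
    inplane <- (rho2 <= spec$radius^2) * 1
    axial <- (abs(dz) <= spec$height / 2) * 1
    arr <- outer(inplane, axial, "*")
  }
  dim(arr) <- c(n, n, n)
  arr
}

`%||%` <- function(x, y) if (is.null(x)) y else x
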