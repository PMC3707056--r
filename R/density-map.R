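#' Cubic density map
#'
#' The common 3-D volume container used throughout the package: a cubic voxel
#' grid of densities (arbitrary units) with an isotropic physical voxel size
#' in Angstrom.  Averages, references, masks and difference maps are all
#' `density_map` objects.
#'
#' @param data A numeric 3-D array with equal extent along all three axes.
#' @param voxel_size Voxel edge length in Angstrom (default 4.4, the
#'   tomographic sampling the package emulates).
#' @param origin Physical offset of the first voxel in Angstrom.
#'
#' @return An object of class `density_map` with fields `data`, `voxel_size`
#'   and `origin`.
#' @examples
#' m <- density_map(array(0, c(16, 16, 16)), voxel_size = 4.4)
#' map_side(m)
#' @export
density_map <- function(data, voxel_size = 4.4, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    abort("`data` must be a 3-D array")
  d <- dim(data)
  if (d[1] != d[2] || d[1] != d[3])
    abort(sprintf("volume must be cubic; got extents %d x %d x %d",
                  d[1], d[2], d[3]))
  if (!all(is.finite(data)))
    abort("all voxel values must be finite")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    abort("`voxel_size` must be a single positive number")
  structure(
    list(data = data, voxel_size = as.numeric(voxel_size),
         origin = as.numeric(origin)),
    class = "density_map"
  )
}

#' @export
print.density_map <- function(x, ...) {
  n <- dim(x$data)[1]
  cat(sprintf("<density_map> %d^3 voxels, %.3g A/voxel (%.0f A box)\n",
              n, x$voxel_size, n * x$voxel_size))
  cat(sprintf("  density range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @rdname density_map
#' @param x A `density_map`.
#' @export
is_density_map <- function(x) inherits(x, "density_map")

#' @rdname density_map
#' @export
map_side <- function(x) dim(x$data)[1]

as_map_data <- function(x) {
  if (is_density_map(x)) x$data
  else if (is_subtomogram(x)) x$map$data
  else if (is.array(x)) x
  else abort("expected a density_map, subtomogram or 3-D array")
}

check_same_grid <- function(a, b) {
  if (map_side(a) != map_side(b))
    abort(sprintf("maps have different box sizes (%d vs %d)",
                  map_side(a), map_side(b)))
  if (abs(a$voxel_size - b$voxel_size) > 1e-6 * a$voxel_size)
    abort(sprintf("maps have different voxel sizes (%g vs %g A)",
                  a$voxel_size, b$voxel_size))
  invisible(TRUE)
}
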