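#' Rotational correlation profile (C8 / D8 symmetry test)
#'
#' Correlates a map with itself rotated about the symmetry axis over a scan
#' of azimuths, inside a spherical mask (radius 0.45 times the box) that
#' suppresses corner effects.  Two series are computed: `cc_c8`, plain
#' azimuthal rotation (eightfold symmetry shows as peaks every 45 degrees);
#' and `cc_d8`, the two-fold flip about the in-plane axis exchanging the two
#' rings followed by the azimuthal rotation (the standard dihedral
#' generator).  A localized mass inside the cavity produces a u-shaped "dip"
#' of the profile around 180 degrees.
#'
#' @param map A [density_map] (or `spt_average`), pre-oriented with the
#'   symmetry axis along `axis`.
#' @param axis Symmetry axis; only `"z"` (the pipeline frame) is supported.
#' @param step Azimuthal step in degrees; must divide 360.
#' @param mask_radius_frac Spherical mask radius as a fraction of the box.
#' @return An `spt_rotational_profile` tibble: `azimuth`, `cc_c8`, `cc_d8`.
#' @export
rotational_profile <- function(map, axis = "z", step = 5,
                               mask_radius_frac = 0.45) {
  if (!identical(axis, "z"))
    abort("symmetry axis must be 'z'; rotate the map into the pipeline frame first")
  if (360 %% step != 0) abort("`step` must divide 360")
  map <- as_item(map)$map
  n <- map_side(map)
  sph <- realize_mask_array(mask_sphere(radius = mask_radius_frac * n), n) >= 0.5
  ref <- map$data[sph]
  flipped <- rotate_array(map$data, euler_matrix(c(0, 180, 180)), c(0, 0, 0))
  az <- seq(0, 360 - step, by = step)
  cc_c8 <- cc_d8 <- numeric(length(az))
  for (i in seq_along(az)) {
    Rm <- euler_matrix(c(az[i], 0, 0))
    cc_c8[i] <- if (az[i] == 0) 1
      else cor(ref, rotate_array(map$data, Rm, c(0, 0, 0))[sph])
    cc_d8[i] <- cor(ref, rotate_array(flipped, Rm, c(0, 0, 0))[sph])
  }
  out <- tibble(azimuth = az, cc_c8 = cc_c8, cc_d8 = cc_d8)
  class(out) <- c("spt_rotational_profile", class(out))
  attr(out, "step") <- step
  out
}

#' Count symmetry peaks in a rotational profile
#'
#' Finds local maxima of the chosen correlation series (treated circularly)
#' with at least the given topographic prominence.  An ideal C8-symmetric map
#' yields 8 peaks at 45-degree spacing.
#'
#' @param profile An `spt_rotational_profile` (step at most 5 degrees for
#'   reliable counting).
#' @param prominence Minimum prominence (correlation units).
#' @param series `"c8"` or `"d8"`.
#' @return A tibble of peaks (`azimuth`, `height`, `prominence`), with the
#'   peak count as attribute `n_peaks`.
#' @export
count_symmetry_peaks <- function(profile, prominence = 0.02,
                                 series = c("c8", "d8")) {
  series <- match.arg(series)
  if (!is.null(attr(profile, "step")) && attr(profile, "step") > 5)
    abort("profile must be sampled at steps of 5 degrees or finer")
  y <- if (series == "c8") profile$cc_c8 else profile$cc_d8
  az <- profile$azimuth
  m <- length(y)
  nxt <- c(2:m, 1); prv <- c(m, 1:(m - 1))
  is_peak <- y > y[prv] & y >= y[nxt]
  prom <- vapply(seq_len(m), function(i) {
    if (!is_peak[i]) return(NA_real_)
    circular_prominence(y, i)
  }, numeric(1))
  keep <- which(is_peak & prom >= prominence)
  out <- tibble(azimuth = az[keep], height = y[keep], prominence = prom[keep])
  attr(out, "n_peaks") <- nrow(out)
  out
}

# prominence of peak i on a circular series: height minus the higher of the
# two saddle minima on the paths (left/right) to the nearest strictly higher
# value; an all-dominant peak uses the global minimum.
circular_prominence <- function(y, i) {
  m <- length(y)
  h <- y[i]
  walk <- function(dir) {
    lo <- h
    j <- i
    for (k in seq_len(m - 1)) {
      j <- ((j - 1 + dir) %% m) + 1
      if (y[j] > h) return(lo)
      lo <- min(lo, y[j])
    }
    lo
  }
  h - max(min(walk(1L), h), min(walk(-1L), h))
}

#' Fourier shell correlation between two maps
#'
#' Per-shell normalized complex correlation over integer-radius Fourier
#' shells of two pre-aligned maps on the same grid.  Resolution is quoted at
#' a threshold crossing (conventionally 0.5 against a much higher-resolution
#' reference, 0.333 between two independent maps of similar quality), found
#' by linear interpolation at the first downward crossing.
#'
#' @param a,b [density_map]s (or `spt_average`s) with identical grid and
#'   voxel size.
#' @return An `spt_fsc` tibble: `shell`, `freq` (1/Angstrom), `fsc`,
#'   `n_voxels`.
#' @export
fsc <- function(a, b) {
  a <- as_item(a)$map; b <- as_item(b)$map
  check_same_grid(a, b)
  n <- map_side(a)
  si <- shell_index(n)
  Fa <- fft(a$data); Fb <- fft(b$data)
  num <- as.vector(tapply(Re(Fa * Conj(Fb)), si, sum))
  pa <- as.vector(tapply(abs(Fa)^2, si, sum))
  pb <- as.vector(tapply(abs(Fb)^2, si, sum))
  cnt <- as.vector(tapply(rep(1, length(si)), si, sum))
  keep <- seq_len(n %/% 2 + 1)
  # shells with negligible power in either map carry no signal (for example
  # beyond a hard low-pass): report 0 rather than round-off correlations
  live <- pa[keep] > 1e-24 * max(pa) & pb[keep] > 1e-24 * max(pb)
  denom <- sqrt(pa[keep] * pb[keep])
  vals <- ifelse(live & denom > 0, num[keep] / denom, 0)
  out <- tibble(
    shell = keep - 1L,
    freq = (keep - 1) / (n * a$voxel_size),
    fsc = vals,
    n_voxels = cnt[keep]
  )
  class(out) <- c("spt_fsc", class(out))
  attr(out, "voxel_size") <- a$voxel_size
  out
}

#' Resolution at an FSC threshold
#'
#' Linear interpolation at the first shell where the curve drops below the
#' threshold; a curve that never crosses reports the Nyquist resolution
#' (2 voxels).
#'
#' @param curve An `spt_fsc` tibble from [fsc()].
#' @param threshold FSC threshold (0.5 or 0.333 conventionally).
#' @return Resolution in Angstrom.
#' @export
fsc_resolution <- function(curve, threshold = 0.5) {
  stopifnot(inherits(curve, "spt_fsc"))
  vs <- attr(curve, "voxel_size")
  f <- curve$fsc[-1]      # skip the DC shell
  fr <- curve$freq[-1]
  below <- which(f < threshold)
  if (length(below) == 0) return(2 * vs)  # Nyquist
  i <- below[1]
  if (i == 1) return(1 / fr[1])
  # interpolate between shells i-1 and i
  f1 <- f[i - 1]; f2 <- f[i]
  x <- fr[i - 1] + (f1 - threshold) / (f1 - f2) * (fr[i] - fr[i - 1])
  1 / x
}
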