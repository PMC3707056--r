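#' @title Fourier utilities: grids, shells, wedge masks, spectrum matching
#' @name spectral
#' @keywords internal
NULL

# signed integer frequency index along one axis of an unshifted FFT array
freq_index <- function(n) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k
}

# list of kx, ky, kz arrays (n^3 each), memoized per grid size
fourier_grid <- local({
  cache <- new.env(parent = emptyenv())
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    k <- freq_index(n)
    kx <- array(k, c(n, n, n))
    ky <- array(rep(k, each = n), c(n, n, n))
    kz <- array(rep(k, each = n * n), c(n, n, n))
    g <- list(kx = kx, ky = ky, kz = kz,
              radius = sqrt(kx^2 + ky^2 + kz^2))
    cache[[key]] <- g
    g
  }
})

# integer-radius shell index (0-based shells, 1-based for R indexing)
shell_index <- local({
  cache <- new.env(parent = emptyenv())
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    s <- as.integer(round(fourier_grid(n)$radius)) + 1L
    cache[[key]] <- s
    s
  }
})

ifft <- function(x) fft(x, inverse = TRUE) / length(x)

# fftshift / ifftshift for 3-D arrays (DC moved to index n%/%2, 0-based)
fftshift3 <- function(x) {
  n <- dim(x)[1]
  i <- c((n %/% 2 + 1):n, 1:(n %/% 2))
  x[i, i, i]
}

ifftshift3 <- function(x) {
  n <- dim(x)[1]
  i <- c((n - n %/% 2 + 1):n, 1:(n - n %/% 2))
  x[i, i, i]
}

#' Missing-wedge specification
#'
#' Describes the single-axis tilt range of a tomographic acquisition; the
#' complement of the sampled region is the "missing wedge" of Fourier space.
#' The default `(-60, 60)` about Y reproduces a standard +/-60 degree tilt
#' series, which retains 2/3 of Fourier space.
#'
#' @param tilt_min,tilt_max Tilt range in degrees, `-90 <= min < max <= 90`.
#' @param tilt_axis Tilt axis, `"y"` (default) or `"x"`.
#' @return A `wedge_spec` object.
#' @export
wedge_spec <- function(tilt_min = -60, tilt_max = 60, tilt_axis = "y") {
  if (!(tilt_min >= -90 && tilt_min < tilt_max && tilt_max <= 90))
    abort("need -90 <= tilt_min < tilt_max <= 90")
  tilt_axis <- match.arg(tilt_axis, c("y", "x"))
  structure(list(tilt_min = tilt_min, tilt_max = tilt_max,
                 tilt_axis = tilt_axis),
            class = "wedge_spec")
}

#' Realize a wedge mask in Fourier space
#'
#' Returns the logical mask (unshifted FFT layout) of Fourier coefficients
#' sampled by a tilt series with the given range: a frequency is retained iff
#' some tilt plane passes through it.  The beam is along Z at zero tilt.  An
#' optional rotation evaluates the mask of a particle that has itself been
#' rotated (`M_rot(k) = M(R^-1 k)`), analytically and without interpolation.
#' The mask always obeys Friedel symmetry.
#'
#' @param n Grid extent.
#' @param wedge A [wedge_spec].
#' @param rot Optional 3x3 rotation matrix applied to the particle.
#' @return A logical `n^3` array.
#' @export
wedge_mask <- function(n, wedge, rot = NULL) {
  g <- fourier_grid(n)
  kx <- g$kx; ky <- g$ky; kz <- g$kz
  if (!is.null(rot)) {
    # evaluate at R^T k
    kx2 <- rot[1, 1] * kx + rot[2, 1] * ky + rot[3, 1] * kz
    ky2 <- rot[1, 2] * kx + rot[2, 2] * ky + rot[3, 2] * kz
    kz2 <- rot[1, 3] * kx + rot[2, 3] * ky + rot[3, 3] * kz
    kx <- kx2; ky <- ky2; kz <- kz2
  }
  u <- if (wedge$tilt_axis == "y") kx else ky
  alpha <- atan2(-kz, u) * 180 / pi
  alpha[alpha > 90] <- alpha[alpha > 90] - 180
  alpha[alpha <= -90] <- alpha[alpha <= -90] + 180
  alpha >= wedge$tilt_min & alpha <= wedge$tilt_max
}

# Fourier coverage of an aligned item: analytic rotated wedge for raw
# particles, trilinear-rotated explicit coverage for averages.
rotate_coverage <- function(cov, Rmat) {
  sh <- fftshift3(cov * 1)
  rot <- rotate_array(sh, Rmat, c(0, 0, 0))
  ifftshift3(rot) >= 0.5
}

#' Match the radial power spectrum of one map to another
#'
#' Scales the Fourier amplitudes of `source`, per integer-radius shell, so
#' that its rotationally averaged amplitude profile equals `target`'s, while
#' preserving the source's phases.  Shells where the source amplitude is
#' below a relative floor (`eps` times the strongest source shell) are left
#' at zero rather than amplified.
#'
#' @param source,target [density_map]s on the same grid.
#' @param eps Relative amplitude floor (default `1e-6`).
#' @return A [density_map] with the filtered density.
#' @export
match_power_spectrum <- function(source, target, eps = 1e-6) {
  check_same_grid(source, target)
  if (all(source$data == 0)) abort("source map is all zero")
  n <- map_side(source)
  si <- shell_index(n)
  Fs <- fft(source$data)
  Ft <- fft(target$data)
  amp_s <- as.vector(tapply(abs(Fs), si, mean))
  amp_t <- as.vector(tapply(abs(Ft), si, mean))
  gain <- rep(0, length(amp_s))
  ok <- amp_s > eps * max(amp_s)
  gain[ok] <- amp_t[ok] / amp_s[ok]
  out <- Re(ifft(Fs * gain[si]))
  dim(out) <- dim(source$data)
  density_map(out, voxel_size = source$voxel_size, origin = source$origin)
}

# mean amplitude per integer-radius shell (shells 0..n/2)
shell_amplitudes <- function(map) {
  n <- map_side(map)
  si <- shell_index(n)
  amp <- as.vector(tapply(abs(fft(map$data)), si, mean))
  keep <- seq_len(n %/% 2 + 1)
  tibble(shell = keep - 1L, amplitude = amp[keep])
}
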