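#' Missing-wedge constrained cross-correlation
#'
#' Correlation between two subtomograms computed only over the Fourier-space
#' overlap of the first particle's sampled region and the second particle's
#' sampled region rotated by `t`.  Within the overlap, each spectrum is
#' mean-subtracted (the zero-frequency coefficient is removed, the exact
#' Fourier counterpart of real-space mean subtraction) and normalized to unit
#' power before the inner product, so the score does not depend on how much
#' of Fourier space either wedge retains, nor on uniform density scaling or
#' offsets of either input.
#'
#' With both wedges fully sampled the score equals the real-space Pearson
#' correlation of the two volumes.
#'
#' @param a,b [subtomogram]s (or wedge-free [density_map]s) on the same grid.
#' @param t A [rigid_transform] applied to `b` before comparison.
#' @return A single correlation in `[-1, 1]`.
#' @export
constrained_cc <- function(a, b, t = rigid_transform()) {
  a <- as_item(a); b <- as_item(b)
  check_same_grid(a$map, b$map)
  n <- map_side(a$map)
  Rmat <- euler_matrix(t$euler)
  bt <- apply_transform(b$map, t)
  O <- item_coverage(a, n) & item_coverage(b, n, rot = Rmat)
  O[1, 1, 1] <- FALSE  # drop DC: mean subtraction
  if (!any(O)) abort("incompatible wedges: empty Fourier overlap")
  va <- fft(a$map$data)[O]
  vb <- fft(bt$data)[O]
  na <- sqrt(sum(abs(va)^2)); nb <- sqrt(sum(abs(vb)^2))
  if (na == 0 || nb == 0) abort("zero power inside the Fourier overlap")
  Re(sum(Conj(va) * vb)) / (na * nb)
}

as_item <- function(x) {
  if (is_subtomogram(x)) x
  else if (is_density_map(x)) subtomogram(x, wedge = NULL, id = "map")
  else if (inherits(x, "spt_average")) subtomogram(x$map, coverage = x$coverage,
                                                  id = "avg")
  else abort("expected a subtomogram, density_map or spt_average")
}

#' Orientation grid over SO(3)
#'
#' A product grid of ZYZ Euler angles at a given step, optionally restricted
#' to a fundamental domain of the D8 point group (used when the alignment
#' target is D8-symmetric: `psi` in `[0, 45)`, `theta` in `[0, 90]`).
#'
#' @param step Angular step in degrees.
#' @param quotient `"none"` for the full rotation group, `"d8"` for the
#'   D8 fundamental domain.
#' @return A tibble with columns `phi`, `theta`, `psi`.
#' @export
so3_grid <- function(step, quotient = c("none", "d8")) {
  quotient <- match.arg(quotient)
  stopifnot(step > 0)
  phi <- seq(0, 360 - step, by = step)
  theta <- seq(0, if (quotient == "d8") 90 else 180, by = step)
  psi <- if (quotient == "d8") seq(0, 45 - step, by = step)
         else seq(0, 360 - step, by = step)
  if (!length(psi)) psi <- 0
  g <- expand.grid(phi = phi, theta = theta, psi = psi,
                   KEEP.OUT.ATTRS = FALSE)
  # at the poles the in-plane angle is degenerate: keep phi only
  g <- g[!(g$theta %in% c(0, 180) & g$psi != 0), , drop = FALSE]
  as_tibble(g)
}

# --- scoring internals -------------------------------------------------------
# Score one candidate rotation of item b against item a, optimizing the
# integer shift over |s| <= max_shift via the constrained correlation map.
# `Fa_masked_env` caches a's fft. Returns list(score, shift).
score_rotation <- function(Fa, cov_a, b, Rmat, max_shift, n) {
  bt <- rotate_array(as_map_data(b), Rmat, c(0, 0, 0))
  Fb <- fft(bt)
  O <- cov_a & item_coverage(b, n, rot = Rmat)
  O[1, 1, 1] <- FALSE
  if (!any(O)) abort("incompatible wedges: empty Fourier overlap")
  va <- Fa[O]; vb <- Fb[O]
  na <- sqrt(sum(abs(va)^2)); nb <- sqrt(sum(abs(vb)^2))
  if (na == 0 || nb == 0) return(list(score = -Inf, shift = c(0, 0, 0)))
  X <- array(0 + 0i, c(n, n, n))
  X[O] <- Conj(va / na) * (vb / nb)
  ccmap <- Re(fft(X))
  win <- shift_window(n, max_shift)
  sub <- ccmap[win$idx, win$idx, win$idx]
  best <- which.max(sub)
  pos <- arrayInd(best, dim(sub))
  list(score = sub[best],
       shift = c(win$shift[pos[1]], win$shift[pos[2]], win$shift[pos[3]]))
}

shift_window <- function(n, max_shift) {
  m <- min(max_shift, n %/% 2 - 1)
  shift <- c(0:m, -(m:1))
  idx <- ifelse(shift >= 0, shift + 1L, n + shift + 1L)
  list(idx = idx, shift = shift)
}

#' Exhaustive-then-local rigid alignment of two subtomograms
#'
#' Scores an exhaustive grid of orientations at `coarse_step` degrees, each
#' at its translational optimum found on the constrained correlation map,
#' then refines the best candidate by hill-climbing at each step in
#' `refine_steps`.  The search is deterministic; ties resolve to the earliest
#' grid point.
#'
#' @param a,b [subtomogram]s; the result maps `b` onto `a`.
#' @param coarse_step Coarse orientation grid step (degrees).
#' @param refine_steps Angular steps for the local refinement stages.
#' @param max_shift Largest translation searched, in voxels; must be below
#'   half the box to avoid wrap-around ambiguity.
#' @param quotient Orientation-grid restriction when `a` is known to be
#'   point-group symmetric (see [so3_grid()]).
#' @return An `spt_alignment`: list with `transform` (a [rigid_transform])
#'   and `score`.
#' @export
align_pair <- function(a, b, coarse_step = 15, refine_steps = c(5, 2),
                       max_shift = 4, quotient = "none") {
  a <- as_item(a); b <- as_item(b)
  check_same_grid(a$map, b$map)
  stopifnot(coarse_step > 0, all(refine_steps > 0))
  n <- map_side(a$map)
  if (max_shift >= n / 2)
    abort(sprintf("max_shift (%g) must be below half the box (%g)",
                  max_shift, n / 2))
  Fa <- fft(a$map$data)
  cov_a <- item_coverage(a, n)
  grid <- so3_grid(coarse_step, quotient)

  best <- list(score = -Inf, euler = c(0, 0, 0), shift = c(0, 0, 0))
  for (i in seq_len(nrow(grid))) {
    e <- c(grid$phi[i], grid$theta[i], grid$psi[i])
    r <- score_rotation(Fa, cov_a, b, euler_matrix(e), max_shift, n)
    if (r$score > best$score + 1e-12)
      best <- list(score = r$score, euler = e, shift = r$shift)
  }
  best <- refine_alignment(Fa, cov_a, b, best, refine_steps, max_shift, n)
  structure(list(transform = rigid_transform(best$euler, best$shift),
                 score = best$score),
            class = "spt_alignment")
}

refine_alignment <- function(Fa, cov_a, b, best, refine_steps, max_shift, n) {
  for (step in refine_steps) {
    repeat {
      moves <- expand.grid(dp = c(-step, 0, step), dt = c(-step, 0, step),
                           ds = c(-step, 0, step))
      improved <- FALSE
      for (j in seq_len(nrow(moves))) {
        if (moves$dp[j] == 0 && moves$dt[j] == 0 && moves$ds[j] == 0) next
        e <- best$euler + c(moves$dp[j], moves$dt[j], moves$ds[j])
        r <- score_rotation(Fa, cov_a, b, euler_matrix(e), max_shift, n)
        if (r$score > best$score + 1e-9) {
          best <- list(score = r$score, euler = e %% 360, shift = r$shift)
          improved <- TRUE
        }
      }
      if (!improved) break
    }
  }
  best
}

#' @export
print.spt_alignment <- function(x, ...) {
  cat(sprintf("<spt_alignment> score %.4f\n", x$score))
  print(x$transform)
  invisible(x)
}

#' Wedge-compensated average of aligned subtomograms
#'
#' Sums the particles' Fourier coefficients in a common frame and divides by
#' the per-voxel count of particles whose (rotated) wedge covers that
#' frequency; frequencies covered by no particle are zero.  This is the
#' standard correction that keeps subtomogram averages unbiased by the
#' missing wedge.
#'
#' @param particles List of [subtomogram]s.
#' @param transforms List of [rigid_transform]s mapping each particle into
#'   the common frame (defaults to identity for all).
#' @return An `spt_average`: list with `map` (a [density_map]) and `coverage`
#'   (the per-voxel Fourier coverage counts).
#' @export
wedge_average <- function(particles, transforms = NULL) {
  stopifnot(length(particles) >= 1)
  n <- map_side(particles[[1]]$map)
  if (is.null(transforms))
    transforms <- replicate(length(particles), rigid_transform(),
                            simplify = FALSE)
  stopifnot(length(transforms) == length(particles))
  S <- array(0 + 0i, c(n, n, n))
  cnt <- array(0, c(n, n, n))
  for (i in seq_along(particles)) {
    p <- as_item(particles[[i]])
    t <- transforms[[i]]
    Rmat <- euler_matrix(t$euler)
    pt <- apply_transform(p$map, t)
    cov <- item_coverage(p, n, rot = Rmat)
    S <- S + fft(pt$data) * cov
    cnt <- cnt + cov
  }
  avgF <- S / pmax(cnt, 1)
  avgF[cnt < 1] <- 0
  avg <- Re(ifft(avgF))
  dim(avg) <- c(n, n, n)
  structure(list(map = density_map(avg,
                                   voxel_size = particles[[1]]$map$voxel_size),
                 coverage = cnt),
            class = "spt_average")
}

#' @export
print.spt_average <- function(x, ...) {
  cat(sprintf("<spt_average> %d^3, mean Fourier coverage %.2f\n",
              map_side(x$map), mean(x$coverage)))
  invisible(x)
}
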