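#' Subtomogram
#'
#' One boxed particle volume together with its missing-wedge specification
#' and, for simulated data, the ground truth that produced it.
#'
#' @param map A [density_map].
#' @param wedge A [wedge_spec], or `NULL` for a fully sampled volume (e.g. a
#'   wedge-free reference).
#' @param id Particle identifier.
#' @param truth Optional list with `transform` ([rigid_transform]),
#'   `class_label` (`"empty"`, `"occupied"` or `"fibril"`) and
#'   `interior_mass_kda`.
#' @param coverage Optional explicit Fourier coverage array (used by
#'   wedge-compensated averages in place of an analytic wedge).
#' @return A `subtomogram` object.
#' @export
subtomogram <- function(map, wedge = NULL, id = "p1", truth = NULL,
                        coverage = NULL) {
  stopifnot(is_density_map(map))
  if (!is.null(wedge)) stopifnot(inherits(wedge, "wedge_spec"))
  structure(list(map = map, wedge = wedge, id = id, truth = truth,
                 coverage = coverage),
            class = "subtomogram")
}

#' @rdname subtomogram
#' @param x Object to test.
#' @export
is_subtomogram <- function(x) inherits(x, "subtomogram")

# Fourier coverage (logical array) of a subtomogram-like item, optionally
# under an extra rotation of the particle.
item_coverage <- function(x, n, rot = NULL) {
  if (!is.null(x$coverage)) {
    cov <- x$coverage >= 1
    if (is.null(rot)) cov else rotate_coverage(cov, rot)
  } else if (!is.null(x$wedge)) {
    wedge_mask(n, x$wedge, rot = rot)
  } else {
    array(TRUE, c(n, n, n))
  }
}

# run code with a private RNG stream, restoring the caller's stream after
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Simulate a subtomogram from a phantom
#'
#' Applies a rigid transform to the phantom, imposes the missing wedge by
#' zeroing Fourier coefficients outside the sampled region, and adds
#' zero-mean Gaussian noise calibrated against the signal variance inside the
#' particle's support mask.  The wedge acts in the particle frame (after the
#' rotation), as tomographic distortion does for differently oriented
#' particles in a real tomogram.
#'
#' @param phantom A [density_map].
#' @param t A [rigid_transform] (the particle's true pose).
#' @param wedge A [wedge_spec].
#' @param snr Signal-to-noise ratio, defined as signal variance over noise
#'   variance within the particle support (voxels where the rotated clean
#'   density exceeds 5 percent of its maximum); `Inf` for noise-free.
#' @param seed Integer seed; the result is bit-reproducible given the seed.
#' @param id,class_label,interior_mass_kda Ground-truth bookkeeping stored in
#'   the result.
#' @return A [subtomogram].
#' @export
simulate_subtomogram <- function(phantom, t, wedge, snr = 0.5, seed = 1L,
                                 id = "p1", class_label = "empty",
                                 interior_mass_kda = 0) {
  stopifnot(is_density_map(phantom), inherits(t, "rigid_transform"),
            inherits(wedge, "wedge_spec"))
  if (!(is.infinite(snr) || snr > 0)) abort("`snr` must be > 0 or Inf")
  n <- map_side(phantom)
  posed <- apply_transform(phantom, t)
  mask <- wedge_mask(n, wedge)
  Fw <- fft(posed$data)
  Fw[!mask] <- 0
  sig <- Re(ifft(Fw))
  dim(sig) <- dim(posed$data)
  if (is.finite(snr)) {
    support <- posed$data > 0.05 * max(posed$data)
    if (!any(support)) abort("empty particle support; cannot calibrate noise")
    sd_noise <- sqrt(var(sig[support]) / snr)
    noise <- with_seed(seed, array(rnorm(n^3, 0, sd_noise), dim(sig)))
    sig <- sig + noise
  }
  subtomogram(
    density_map(sig, voxel_size = phantom$voxel_size),
    wedge = wedge, id = id,
    truth = list(transform = t, class_label = class_label,
                 interior_mass_kda = interior_mass_kda)
  )
}

# uniform rotation via a random unit quaternion -> ZYZ euler
random_euler <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)), 3, 3)
  matrix_euler(R)
}

#' Generate a synthetic subtomogram cohort
#'
#' Draws particle poses uniformly over rotation space (seeded), simulates
#' cavity-empty, cavity-occupied and fibril-bound particles from the
#' corresponding phantoms, and returns the particles together with a
#' ground-truth manifest.  The default preset sizes
#' ([cohort_preset_emulation()]) emulate the study population: 890
#' freestanding particles (445 empty + 445 occupied) and 326 fibril-bound.
#'
#' @param n_empty,n_occupied,n_fibril Particle counts per class.
#' @param spec A [phantom_spec]; its `occupancy_fraction` is used for the
#'   occupied class (the empty/fibril classes use 0) and its
#'   `apical_fraction` (or 0.1 if unset) for the fibril class.
#' @param wedge A [wedge_spec].
#' @param snr Per-particle signal-to-noise ratio (see
#'   [simulate_subtomogram()]).
#' @param seed Master seed; regenerating with the same seed reproduces
#'   identical volumes.
#' @param max_shift_vox Particle centering error: true shifts are drawn
#'   uniformly in `[-max_shift_vox, max_shift_vox]` voxels per axis.
#' @param dir Optional directory; when given, each particle is written as an
#'   MRC file and the manifest as a tab-separated table there.
#' @param m_tric_kda Reference mass (kDa) used to express the interior mass.
#' @return A list with `particles` (list of [subtomogram]s) and `manifest`
#'   (a tibble: id, file, class_label, euler angles, shifts, snr, seed).
#' @export
generate_cohort <- function(n_empty, n_occupied, n_fibril = 0,
                            spec = phantom_spec(occupancy_fraction = 60 / 950),
                            wedge = wedge_spec(),
                            snr = 0.5, seed = 1L,
                            max_shift_vox = 2, dir = NULL,
                            m_tric_kda = 950) {
  stopifnot(n_empty >= 0, n_occupied >= 0, n_fibril >= 0)
  n_tot <- n_empty + n_occupied + n_fibril
  if (n_tot == 0) abort("cohort must contain at least one particle")

  f_occ <- if (spec$occupancy_fraction > 0) spec$occupancy_fraction else 60 / 950
  f_api <- if (spec$apical_fraction > 0) spec$apical_fraction else 0.1
  ph <- list(
    empty = build_phantom(modify_spec(spec, occupancy_fraction = 0,
                                      apical_fraction = 0)),
    occupied = build_phantom(modify_spec(spec, occupancy_fraction = f_occ,
                                         apical_fraction = 0)),
    fibril = build_phantom(modify_spec(spec, occupancy_fraction = 0,
                                       apical_fraction = f_api))
  )
  labels <- rep(c("empty", "occupied", "fibril"),
                c(n_empty, n_occupied, n_fibril))

  draws <- with_seed(seed, {
    eulers <- t(vapply(seq_len(n_tot), function(i) random_euler(), numeric(3)))
    shifts <- matrix(runif(3 * n_tot, -max_shift_vox, max_shift_vox),
                     ncol = 3)
    seeds <- sample.int(.Machine$integer.max - 1L, n_tot)
    list(eulers = eulers, shifts = shifts, seeds = seeds)
  })

  particles <- vector("list", n_tot)
  files <- rep(NA_character_, n_tot)
  for (i in seq_len(n_tot)) {
    lab <- labels[i]
    tr <- rigid_transform(draws$eulers[i, ], draws$shifts[i, ])
    id <- sprintf("%s_%04d", lab, i)
    particles[[i]] <- simulate_subtomogram(
      ph[[lab]], tr, wedge, snr = snr, seed = draws$seeds[i], id = id,
      class_label = lab,
      interior_mass_kda = if (lab == "occupied") f_occ * m_tric_kda else 0
    )
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      files[i] <- file.path(dir, paste0(id, ".mrc"))
      write_map(particles[[i]]$map, files[i])
    }
  }

  manifest <- tibble(
    id = vapply(particles, `[[`, character(1), "id"),
    file = files,
    class_label = labels,
    phi = draws$eulers[, 1], theta = draws$eulers[, 2], psi = draws$eulers[, 3],
    sx = draws$shifts[, 1], sy = draws$shifts[, 2], sz = draws$shifts[, 3],
    snr = snr, seed = draws$seeds
  )
  attr(manifest, "phantom_spec") <- spec
  attr(manifest, "wedge_spec") <- wedge
  attr(manifest, "m_tric_kda") <- m_tric_kda
  if (!is.null(dir)) {
    write_tsv_plain(manifest, file.path(dir, "manifest.tsv"))
    write_config_echo(
      c(list(n_empty = n_empty, n_occupied = n_occupied, n_fibril = n_fibril,
             snr = snr, seed = seed, max_shift_vox = max_shift_vox,
             m_tric_kda = m_tric_kda,
             tilt_min = wedge$tilt_min, tilt_max = wedge$tilt_max,
             tilt_axis = wedge$tilt_axis),
        spec[!vapply(spec, is.null, logical(1))]),
      file.path(dir, "cohort_config.txt"))
  }
  list(particles = particles, manifest = manifest)
}

modify_spec <- function(spec, ...) {
  new <- modifyList(unclass(spec), list(...))
  do.call(phantom_spec, new)
}

#' @rdname generate_cohort
#' @details `cohort_preset_emulation()` returns the class counts of the
#'   emulation preset: 445 cavity-empty + 445 cavity-occupied freestanding
#'   particles (890 total) and 326 fibril-bound.
#' @export
cohort_preset_emulation <- function() {
  list(n_empty = 445L, n_occupied = 445L, n_fibril = 326L,
       n_freestanding = 890L, n_total = 1216L)
}

# plain-text table/config writers (kept dependency-light)
write_tsv_plain <- function(df, path) {
  df <- as.data.frame(df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_config_echo <- function(values, path) {
  lines <- vapply(names(values), function(k) {
    v <- values[[k]]
    sprintf("%s = %s", k, paste(format(v, digits = 12), collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
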