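#' Hollow-template-guided, D8-restricted refinement of cavity density
#'
#' Starting from each particle's alignment to a hollow D8-symmetric
#' reference, iteratively re-scores every particle at the sixteen D8-related
#' alternatives of that alignment - using only the voxels inside the cavity
#' mask - assigns the best, and re-averages.  The barrel-frame alignment is
#' never revisited, so the chaperonin stays fixed while any density inside
#' the chamber is free to converge to a consistent position.  Scoring ties
#' (including the degenerate case of an empty, noise-free cavity) keep the
#' current assignment, making iteration a fixed point once converged.
#'
#' @param particles List of [subtomogram]s (the cavity-occupied set).
#' @param alignments An `spt_ranked` tibble from [rank_by_reference()]
#'   holding each particle's transform into the reference frame.
#' @param cavity_mask A [mask_spec] or binary [density_map] for the chamber.
#' @param n_iter Maximum iterations (default 17).
#' @param tol Early-stop threshold: RMS change of the average inside the
#'   cavity, relative to the cavity RMS (default `1e-4`).
#' @param switch_margin Hysteresis: a particle moves off its current
#'   orientation only when an alternative scores at least this much higher
#'   (correlation units).  Prevents noise- and ringing-driven shuffling of
#'   assignments between near-equivalent orientations.
#' @param init_elements Optional integer vector of starting D8 element
#'   indices (1-16) per particle, e.g. the `assignments` of a previous run
#'   for a warm restart; defaults to the identity element.
#' @return A list with `average` (the refined `spt_average`), `assignments`
#'   (tibble: id, chosen D8 element index per particle), and `history`
#'   (tibble: iteration, n_changed, convergence).
#' @export
hollow_template_refine <- function(particles, alignments, cavity_mask,
                                   n_iter = 17, tol = 1e-4,
                                   switch_margin = 0.01,
                                   init_elements = NULL) {
  stopifnot(length(particles) >= 1, n_iter >= 1)
  n <- map_side(particles[[1]]$map)
  cav <- if (inherits(cavity_mask, "mask_spec"))
    realize_mask_array(cavity_mask, n) >= 0.5
  else as_map_data(cavity_mask) >= 0.5
  if (!any(cav)) abort("cavity mask is empty")

  g16 <- d8_elements()
  base_t <- lapply(particles, function(p) ranked_transform(alignments, p$id))
  # candidate transforms: g o t_p for each of the 16 group elements
  cand <- lapply(seq_along(particles), function(i)
    lapply(g16, function(g) compose_transforms(g, base_t[[i]])))

  assign_idx <- if (is.null(init_elements)) rep(1L, length(particles))
                else as.integer(init_elements)
  stopifnot(length(assign_idx) == length(particles),
            all(assign_idx %in% 1:16))
  avg <- wedge_average(particles,
                       lapply(seq_along(particles),
                              function(i) cand[[i]][[assign_idx[i]]]))
  history <- list()
  for (it in seq_len(n_iter)) {
    ref_cav <- avg$map$data[cav]
    ref_sd <- sd(ref_cav)
    n_changed <- 0L
    for (i in seq_along(particles)) {
      cur <- assign_idx[i]
      score_of <- function(j) {
        t <- cand[[i]][[j]]
        pv <- rotate_array(particles[[i]]$map$data, euler_matrix(t$euler),
                           t$shift)[cav]
        if (ref_sd == 0 || sd(pv) == 0) -Inf else cor(pv, ref_cav)
      }
      cur_s <- score_of(cur)
      alt <- setdiff(seq_len(16L), cur)
      alt_s <- vapply(alt, score_of, numeric(1))
      k <- which.max(alt_s)
      # hysteresis: leave the incumbent only for a clear improvement
      if (is.finite(alt_s[k]) && alt_s[k] > cur_s + switch_margin) {
        assign_idx[i] <- alt[k]
        n_changed <- n_changed + 1L
      }
    }
    new_avg <- wedge_average(particles,
                             lapply(seq_along(particles),
                                    function(i) cand[[i]][[assign_idx[i]]]))
    delta <- sqrt(mean((new_avg$map$data[cav] - avg$map$data[cav])^2))
    scale <- sqrt(mean(avg$map$data[cav]^2))
    conv <- if (scale > 0) delta / scale else 0
    history[[it]] <- tibble(iteration = it, n_changed = n_changed,
                            convergence = conv)
    avg <- new_avg
    if (conv < tol && n_changed == 0L) break
  }
  list(average = avg,
       assignments = tibble(
         id = vapply(particles, `[[`, character(1), "id"),
         d8_element = assign_idx),
       history = dplyr::bind_rows(history))
}

#' Power-spectrum-matched difference map
#'
#' Subtracts a cavity-empty average from a cavity-occupied average after
#' (optionally) refining their rigid alignment, filtering the empty map's
#' power spectrum to match the occupied map, and fitting a least-squares
#' intensity scale and offset over the region the two maps share (mask C,
#' the complex without its cavity).  The result isolates the encapsulated
#' density.
#'
#' @param occupied_avg,empty_avg [density_map]s (or `spt_average`s) on the
#'   same grid, already in a common frame.
#' @param norm_mask A [mask_spec] or binary [density_map] over which the
#'   intensity scale/offset is fitted (defaults to the whole box).
#' @param align If `TRUE`, hill-climb a small rigid alignment of the empty
#'   map onto the occupied map before subtracting.
#' @return A [density_map] difference map (occupied minus matched empty).
#' @export
difference_map <- function(occupied_avg, empty_avg, norm_mask = NULL,
                           align = FALSE) {
  occ <- as_item(occupied_avg)$map
  emp <- as_item(empty_avg)$map
  check_same_grid(occ, emp)
  n <- map_side(occ)
  if (align) {
    Fa <- fft(occ$data)
    cov_a <- array(TRUE, c(n, n, n))
    best <- list(score = constrained_cc(occ, emp), euler = c(0, 0, 0),
                 shift = c(0, 0, 0))
    best <- refine_alignment(Fa, cov_a, subtomogram(emp), best,
                             refine_steps = c(2), max_shift = 3, n = n)
    emp <- apply_transform(emp, rigid_transform(best$euler, best$shift))
  }
  m <- if (is.null(norm_mask)) array(TRUE, c(n, n, n))
  else if (inherits(norm_mask, "mask_spec")) realize_mask_array(norm_mask, n) >= 0.5
  else as_map_data(norm_mask) >= 0.5
  # amplitude matching: a relative-B-factor (Guinier) gain, exp(a + b s^2),
  # fitted to the shell-amplitude ratios of the two maps over the shared
  # region (the normalization mask).  Estimating on the shared region keeps
  # the genuine cavity difference out of the filter; the smooth two-
  # parameter form keeps per-shell estimation noise from being stamped into
  # the difference map.
  if (any(emp$data != 0)) {
    si <- shell_index(n)
    amp_s <- as.vector(tapply(abs(fft(emp$data * m)), si, mean))
    amp_t <- as.vector(tapply(abs(fft(occ$data * m)), si, mean))
    pow_s <- as.vector(tapply(abs(fft(emp$data * m))^2, si, sum))
    shells <- seq_along(amp_s) - 1
    ok <- amp_s > 1e-6 * max(amp_s) & amp_t > 0 & shells <= n %/% 2
    s2 <- shells^2
    fit <- stats::lm.wfit(cbind(1, s2[ok]), log(amp_t[ok] / amp_s[ok]),
                          w = pow_s[ok])
    gain <- exp(fit$coefficients[1] + fit$coefficients[2] * s2)
    gain[!is.finite(gain)] <- 0
    filt <- Re(ifft(fft(emp$data) * gain[si]))
    dim(filt) <- dim(emp$data)
    emp <- density_map(filt, voxel_size = emp$voxel_size)
  }
  x <- emp$data[m]; y <- occ$data[m]
  if (var(x) > 0) {
    s <- cov(x, y) / var(x)
    o <- mean(y) - s * mean(x)
  } else { s <- 1; o <- 0 }
  density_map(occ$data - (s * emp$data + o), voxel_size = occ$voxel_size)
}

new_mass_estimate <- function(method, mass_kda, m_tric_kda, inputs) {
  raw_kda <- mass_kda
  if (!is.na(mass_kda) && mass_kda < 0 &&
      method %in% c("integration", "histogram")) {
    warn(sprintf("%s mass estimate was negative (%.1f kDa); clamped to 0",
                 method, mass_kda))
    mass_kda <- 0
  }
  structure(list(method = method, mass_kda = mass_kda, raw_kda = raw_kda,
                 m_tric_kda = m_tric_kda, inputs = inputs),
            class = "spt_mass_estimate")
}

#' @export
print.spt_mass_estimate <- function(x, ...) {
  cat(sprintf("<spt_mass_estimate> %s: %.1f kDa (reference mass %.0f kDa)\n",
              x$method, x$mass_kda, x$m_tric_kda))
  invisible(x)
}

#' @export
glance.spt_mass_estimate <- function(x, ...) {
  tibble(method = x$method, mass_kda = x$mass_kda,
         m_tric_kda = x$m_tric_kda)
}

#' Encapsulated-mass estimators
#'
#' Three estimators of the mass enclosed in the chaperonin chamber, each
#' scaled by the complex's known mass (`m_tric_kda`, ~950 kDa):
#'
#' * `mass_integration()`: integrates the difference map over the cavity mask
#'   and the empty average over the complex-only mask; the cavity integral is
#'   converted to kDa through the ratio to the complex integral.
#' * `mass_histogram()`: works from the group mean-density comparisons - the
#'   empty group's cavity mean is the background subtracted from the occupied
#'   group's cavity mean, scaled by cavity/complex volumes and the pooled
#'   complex-region density.
#' * `mass_rotational()`: reads the depth of the 180-degree dip of the
#'   rotational correlation profile (mean of the peaks at 45 and 315 degrees
#'   minus the peak at 180) and scales it by the complex mass; indirect, and
#'   known to underestimate.
#'
#' Negative integration/histogram estimates are clamped to zero with a
#' warning (noise can legitimately drive small estimates below zero); the
#' unclamped value is kept in the `raw_kda` field.
#'
#' @param empty_avg Cavity-empty average ([density_map] or `spt_average`).
#' @param diff_map Difference map from [difference_map()].
#' @param mask_tric,mask_cavity Disjoint [mask_spec]s (or binary maps) for
#'   the complex-without-cavity and the cavity.
#' @param m_tric_kda Reference mass in kDa (default 950).
#' @return An `spt_mass_estimate`.
#' @export
mass_integration <- function(empty_avg, diff_map, mask_tric, mask_cavity,
                             m_tric_kda = 950) {
  emp <- as_item(empty_avg)$map
  dif <- as_item(diff_map)$map
  check_same_grid(emp, dif)
  n <- map_side(emp)
  mt <- realize_any_mask(mask_tric, n)
  mc <- realize_any_mask(mask_cavity, n)
  if (any(mt & mc)) abort("cavity mask must be disjoint from the complex mask")
  tric_integral <- sum(emp$data[mt])
  if (tric_integral <= 0) abort("non-positive integral over the complex mask")
  cavity_integral <- sum(dif$data[mc])
  new_mass_estimate("integration",
                    m_tric_kda * cavity_integral / tric_integral,
                    m_tric_kda,
                    list(cavity_integral = cavity_integral,
                         tric_integral = tric_integral))
}

realize_any_mask <- function(m, n) {
  if (inherits(m, "mask_spec")) realize_mask_array(m, n) >= 0.5
  else as_map_data(m) >= 0.5
}

#' @rdname mass_integration
#' @param comparison_B,comparison_C `spt_group_comparison`s computed under
#'   the cavity (B) and complex-only (C) masks.
#' @param cavity_voxels,tric_voxels Voxel counts of the two masks.
#' @export
mass_histogram <- function(comparison_B, comparison_C, cavity_voxels,
                           tric_voxels, m_tric_kda = 950) {
  stopifnot(inherits(comparison_B, "spt_group_comparison"),
            inherits(comparison_C, "spt_group_comparison"))
  mb <- comparison_B$means
  mean_b_empty <- mean(mb$mean_density[mb$group == "empty"])
  mean_b_occ <- mean(mb$mean_density[mb$group == "occupied"])
  mean_c <- mean(comparison_C$means$mean_density)
  if (mean_c <= 0) abort("non-positive mean density under mask C")
  est <- m_tric_kda * ((mean_b_occ - mean_b_empty) * cavity_voxels) /
    (mean_c * tric_voxels)
  new_mass_estimate("histogram", est, m_tric_kda,
                    list(mean_b_empty = mean_b_empty, mean_b_occ = mean_b_occ,
                         mean_c = mean_c, cavity_voxels = cavity_voxels,
                         tric_voxels = tric_voxels))
}

#' @rdname mass_integration
#' @param profile An `spt_rotational_profile` of the refined cavity-occupied
#'   average, with identifiable peaks at 45-degree spacing.
#' @param prominence Peak prominence used to detect the eight symmetry peaks.
#' @export
mass_rotational <- function(profile, m_tric_kda = 950, prominence = 0.005) {
  peaks <- count_symmetry_peaks(profile, prominence = prominence,
                                series = "c8")
  if (nrow(peaks) < 8)
    abort(sprintf("need 8 detectable symmetry peaks, found %d", nrow(peaks)))
  at <- function(target) {
    i <- which.min(pmin(abs(peaks$azimuth - target),
                        360 - abs(peaks$azimuth - target)))
    peaks$height[i]
  }
  # peak 1 (azimuth 0) is unusable: self-correlation of every voxel; use the
  # flanking peaks 2 and 8 against the opposing peak 5
  delta <- mean(c(at(45), at(315))) - at(180)
  new_mass_estimate("rotational", m_tric_kda * delta, m_tric_kda,
                    list(cc_45 = at(45), cc_315 = at(315), cc_180 = at(180)))
}
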