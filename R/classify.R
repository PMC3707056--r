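#' Rank particles by correlation with a reference
#'
#' Aligns every particle against a (wedge-free, typically hollow and
#' D8-symmetric) reference and ranks the particles by their best constrained
#' correlation, descending.  Cavity-empty particles score higher against a
#' hollow reference than cavity-occupied ones, which is the basis of the
#' quintile classification.
#'
#' The search rotates the reference over an orientation grid (restricted to
#' the reference's point-group fundamental domain when `ref_symmetry = "d8"`),
#' scores the coarse grid at zero shift against all particles at once, then
#' refines the best candidate per particle with a translational peak search
#' and local angular hill-climbing.  Because the reference is wedge-free, the
#' Fourier overlap is each particle's own wedge, identical across
#' orientations.
#'
#' @param particles List of [subtomogram]s (non-empty).
#' @param reference A [density_map] (or subtomogram) reference.
#' @param coarse_step,refine_steps,max_shift Search parameters as in
#'   [align_pair()].
#' @param ref_symmetry `"d8"` (default) restricts the orientation grid to the
#'   D8 fundamental domain; `"none"` searches all of SO(3).
#' @return An `spt_ranked` tibble with one row per particle, sorted by score
#'   (ties broken by id): `rank`, `id`, `score`, and the particle-to-
#'   reference transform (`phi`, `theta`, `psi`, `sx`, `sy`, `sz`).
#' @export
rank_by_reference <- function(particles, reference, coarse_step = 15,
                              refine_steps = c(5, 2), max_shift = 4,
                              ref_symmetry = c("d8", "none")) {
  if (length(particles) == 0) abort("empty particle set")
  ref_symmetry <- match.arg(ref_symmetry)
  ref <- as_item(reference)
  n <- map_side(ref$map)
  for (p in particles) check_same_grid(ref$map, p$map)

  # all particles share the standard (unrotated) wedge in their own frame
  cov <- item_coverage(particles[[1]], n)
  cov[1, 1, 1] <- FALSE
  O_idx <- which(cov)
  np <- length(particles)

  P <- matrix(0 + 0i, length(O_idx), np)
  for (i in seq_len(np)) {
    v <- fft(particles[[i]]$map$data)[O_idx]
    P[, i] <- v / sqrt(sum(abs(v)^2))
  }

  grid <- so3_grid(coarse_step,
                   quotient = if (ref_symmetry == "d8") "d8" else "none")
  ng <- nrow(grid)
  best_score <- rep(-Inf, np)
  best_orient <- integer(np)
  chunk <- 64L
  for (start in seq(1L, ng, by = chunk)) {
    rows <- start:min(start + chunk - 1L, ng)
    Vb <- matrix(0 + 0i, length(O_idx), length(rows))
    for (j in seq_along(rows)) {
      e <- c(grid$phi[rows[j]], grid$theta[rows[j]], grid$psi[rows[j]])
      rr <- rotate_array(ref$map$data, euler_matrix(e), c(0, 0, 0))
      v <- fft(rr)[O_idx]
      Vb[, j] <- v / sqrt(sum(abs(v)^2))
    }
    sc <- Re(t(Conj(Vb)) %*% P)      # orientations x particles
    for (i in seq_len(np)) {
      m <- which.max(sc[, i])
      if (sc[m, i] > best_score[i] + 1e-12) {
        best_score[i] <- sc[m, i]
        best_orient[i] <- rows[m]
      }
    }
  }

  # per-particle translational optimum + local angular refinement
  out <- vector("list", np)
  for (i in seq_len(np)) {
    p <- particles[[i]]
    Fa <- fft(p$map$data)
    cov_p <- item_coverage(p, n)
    e0 <- unlist(grid[best_orient[i], ], use.names = FALSE)
    r0 <- score_rotation(Fa, cov_p, ref, euler_matrix(e0), max_shift, n)
    best <- list(score = r0$score, euler = e0, shift = r0$shift)
    best <- refine_alignment(Fa, cov_p, ref, best, refine_steps, max_shift, n)
    # best maps the reference onto the particle; invert for particle -> ref
    t_ref_to_p <- rigid_transform(best$euler, best$shift)
    t_p <- invert_transform(t_ref_to_p)
    out[[i]] <- tibble(id = p$id, score = best$score,
                       phi = t_p$euler[1], theta = t_p$euler[2],
                       psi = t_p$euler[3],
                       sx = t_p$shift[1], sy = t_p$shift[2],
                       sz = t_p$shift[3])
  }
  ranked <- dplyr::bind_rows(out)
  ranked <- dplyr::arrange(ranked, dplyr::desc(.data$score), .data$id)
  ranked <- dplyr::mutate(ranked, rank = dplyr::row_number(),
                          .before = "id")
  class(ranked) <- c("spt_ranked", class(ranked))
  attr(ranked, "reference_id") <- ref$id
  ranked
}

ranked_transform <- function(ranked, id) {
  row <- ranked[ranked$id == id, ]
  stopifnot(nrow(row) == 1)
  rigid_transform(c(row$phi, row$theta, row$psi), c(row$sx, row$sy, row$sz))
}

#' Quintile split of a ranked particle set
#'
#' Divides particles ranked by similarity to a hollow reference into
#' quintiles of `floor(n/5)`: the two top quintiles form the cavity-empty
#' set, the two bottom quintiles the cavity-occupied set, and the middle
#' quintile (plus any remainder when 5 does not divide n) is discarded.  For
#' n = 890 this reproduces quintiles of 178 and final sets of 356 (40 percent
#' of the input each).  `mode = "halves"` instead splits at the median into
#' an empty top half and an occupied bottom half (the per-tomogram variant).
#'
#' @param ranked An `spt_ranked` tibble (or any tibble with `rank` and `id`).
#' @param mode `"quintile"` (default) or `"halves"`.
#' @return An `spt_split`: list with `empty_ids`, `occupied_ids`,
#'   `discarded_ids`, `quintile_size` and `table` (the input plus a
#'   `set` column).
#' @export
quintile_split <- function(ranked, mode = c("quintile", "halves")) {
  mode <- match.arg(mode)
  n <- nrow(ranked)
  stopifnot(!is.null(ranked$id), !is.null(ranked$rank))
  ord <- ranked[order(ranked$rank), ]
  if (mode == "quintile") {
    if (n < 5) abort("need at least 5 ranked particles for quintiles")
    q <- n %/% 5L
    set <- rep("discarded", n)
    set[1:(2 * q)] <- "empty"
    set[(n - 2 * q + 1):n] <- "occupied"
  } else {
    if (n < 2) abort("need at least 2 ranked particles for halves")
    q <- n %/% 2L
    set <- rep("discarded", n)
    set[1:q] <- "empty"
    set[(n - q + 1):n] <- "occupied"
  }
  tab <- dplyr::mutate(as_tibble(ord), set = set)
  structure(list(
    empty_ids = tab$id[tab$set == "empty"],
    occupied_ids = tab$id[tab$set == "occupied"],
    discarded_ids = tab$id[tab$set == "discarded"],
    quintile_size = if (mode == "quintile") q else NA_integer_,
    mode = mode,
    table = tab
  ), class = "spt_split")
}

#' @export
print.spt_split <- function(x, ...) {
  cat(sprintf("<spt_split> %s: %d empty / %d occupied / %d discarded\n",
              x$mode, length(x$empty_ids), length(x$occupied_ids),
              length(x$discarded_ids)))
  invisible(x)
}

#' @export
tidy.spt_split <- function(x, ...) x$table

#' Mean density under a binary mask
#'
#' @param p A [subtomogram] or [density_map], already aligned to the mask's
#'   frame (for ranked particles, apply the transform from
#'   [rank_by_reference()] first).
#' @param mask A binary [density_map] (e.g. from [realize_mask()]).
#' @return The arithmetic mean of the voxel values where the mask is 1.
#' @export
mask_mean_density <- function(p, mask) {
  arr <- as_map_data(p)
  m <- as_map_data(mask) >= 0.5
  if (!any(m)) abort("empty mask")
  mean(arr[m])
}

#' Welch comparison of two particle groups under a mask
#'
#' Computes each particle's mean density under the mask (particles must be in
#' the mask's frame; pass `transforms` to apply their reference alignments)
#' and compares the two groups with a two-sided Welch (unequal-variance)
#' two-sample t-test, flagging significance at the 95 and 99.9 percent
#' confidence levels.
#'
#' @param empty,occupied Lists of [subtomogram]s / [density_map]s, or plain
#'   numeric vectors of precomputed per-particle mask means.
#' @param mask A [mask_spec] or binary [density_map]; ignored when numeric
#'   vectors are given.
#' @param transforms_empty,transforms_occupied Optional lists of
#'   [rigid_transform]s applied to the particles before masking.
#' @param mask_label Label stored on the result (`"A"`, `"B"` or `"C"`).
#' @return An `spt_group_comparison`: `mask_label`, `means` (tidy tibble of
#'   per-particle means), `t_score`, `df`, `p_value`, `significant_95`,
#'   `significant_999`.
#' @export
compare_groups <- function(empty, occupied, mask = NULL,
                           transforms_empty = NULL,
                           transforms_occupied = NULL,
                           mask_label = "A") {
  group_means <- function(g, transforms) {
    if (is.numeric(g)) return(as.numeric(g))
    if (inherits(mask, "mask_spec"))
      mask <- realize_mask(mask, map_side(as_item(g[[1]])$map))
    vapply(seq_along(g), function(i) {
      p <- as_item(g[[i]])
      m <- if (!is.null(transforms)) apply_transform(p$map, transforms[[i]])
           else p$map
      mask_mean_density(m, mask)
    }, numeric(1))
  }
  me <- group_means(empty, transforms_empty)
  mo <- group_means(occupied, transforms_occupied)
  if (length(me) < 2 || length(mo) < 2)
    abort("both groups need at least 2 particles")
  if (var(me) == 0 && var(mo) == 0 && isTRUE(all.equal(mean(me), mean(mo)))) {
    tt <- list(statistic = 0, parameter = length(me) + length(mo) - 2,
               p.value = 1)
  } else {
    if (var(me) == 0) abort("zero variance in the empty group")
    if (var(mo) == 0) abort("zero variance in the occupied group")
    tt <- t.test(me, mo, var.equal = FALSE)
  }
  structure(list(
    mask_label = mask_label,
    means = dplyr::bind_rows(
      tibble(group = "empty", mean_density = me),
      tibble(group = "occupied", mean_density = mo)
    ),
    t_score = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    significant_95 = tt$p.value < 0.05,
    significant_999 = tt$p.value < 0.001
  ), class = "spt_group_comparison")
}

#' @export
print.spt_group_comparison <- function(x, ...) {
  cat(sprintf(
    "<spt_group_comparison> mask %s: t = %.3f (df %.1f), p = %.3g%s\n",
    x$mask_label, x$t_score, x$df, x$p_value,
    if (x$significant_999) " ***" else if (x$significant_95) " *" else ""))
  invisible(x)
}

#' @export
tidy.spt_group_comparison <- function(x, ...) x$means

#' @export
glance.spt_group_comparison <- function(x, ...) {
  tibble(mask_label = x$mask_label, t_score = x$t_score, df = x$df,
         p_value = x$p_value, significant_95 = x$significant_95,
         significant_999 = x$significant_999)
}
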