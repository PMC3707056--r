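#' Hierarchical ascendant classification (HAC) with wedge-compensated
#' averaging
#'
#' Reference-free agglomerative clustering of subtomograms: all current item
#' pairs are aligned with the constrained correlation, the highest-scoring
#' pair is merged into a wedge-compensated average carrying the union Fourier
#' coverage, and the procedure repeats until `stop_k` items remain.  No
#' symmetry is imposed at any point.  Ties break deterministically toward the
#' lowest item indices; pairwise alignments between unchanged items are
#' cached across merge rounds.
#'
#' @param particles List of [subtomogram]s (at least two).
#' @param stop_k Number of items to stop at (1 runs to a single average).
#' @param ... Passed to [align_pair()] (e.g. `coarse_step`, `max_shift`).
#' @return An `spt_hac` object: `merges` (tibble with one row per merge
#'   event: `event`, `left`, `right`, `score`, `n_members`), `items` (the
#'   remaining averages as `spt_average`s), `members` (particle ids per
#'   remaining item), and `leaves` (all particle ids).
#' @export
hac_average <- function(particles, stop_k = 1, ...) {
  stopifnot(length(particles) >= 2, stop_k >= 1)
  items <- lapply(particles, as_item)
  ids <- vapply(items, `[[`, character(1), "id")
  members <- as.list(ids)
  active <- seq_along(items)
  cache <- new.env(parent = emptyenv())

  pair_key <- function(i, j) paste0(i, "_", j)
  get_align <- function(i, j) {
    key <- pair_key(i, j)
    if (is.null(cache[[key]]))
      cache[[key]] <- align_pair(items[[i]], items[[j]], ...)
    cache[[key]]
  }

  merges <- list()
  next_id <- length(items)
  while (length(active) > stop_k) {
    best <- NULL
    for (ii in seq_along(active)) {
      for (jj in seq_len(ii - 1L)) {
        i <- active[jj]; j <- active[ii]   # i < j
        al <- get_align(i, j)
        if (is.null(best) || al$score > best$score + 1e-12)
          best <- list(i = i, j = j, score = al$score, al = al)
      }
    }
    # merge j into i's frame
    merged <- merge_items(items[[best$i]], items[[best$j]], best$al$transform)
    next_id <- next_id + 1L
    items[[next_id]] <- merged
    members[[next_id]] <- c(members[[best$i]], members[[best$j]])
    merges[[length(merges) + 1L]] <- tibble(
      event = length(merges) + 1L,
      left = paste(members[[best$i]], collapse = ","),
      right = paste(members[[best$j]], collapse = ","),
      score = best$score,
      n_members = length(members[[next_id]])
    )
    active <- c(setdiff(active, c(best$i, best$j)), next_id)
  }
  structure(list(
    merges = dplyr::bind_rows(merges),
    items = lapply(items[active], function(x) {
      if (inherits(x, "spt_average")) x
      else structure(list(map = x$map,
                          coverage = item_coverage(x, map_side(x$map)) * 1),
                     class = "spt_average")
    }),
    members = members[active],
    leaves = ids
  ), class = "spt_hac")
}

# weighted Fourier merge of two items, j brought into i's frame by t
merge_items <- function(item_i, item_j, t) {
  n <- map_side(item_i$map)
  cov_i <- item_cov_counts(item_i, n)
  Fi <- fft(as_map_data(item_i))
  jt <- apply_transform(as_item(item_j)$map, t)
  Rmat <- euler_matrix(t$euler)
  cov_j <- rotate_counts(item_cov_counts(item_j, n), Rmat)
  Fj <- fft(jt$data)
  S <- Fi * (cov_i >= 1) * pmax(cov_i, 1) + Fj * (cov_j >= 1) * pmax(cov_j, 1)
  cnt <- cov_i * (cov_i >= 1) + cov_j * (cov_j >= 1)
  avgF <- S / pmax(cnt, 1)
  avgF[cnt < 1] <- 0
  avg <- Re(ifft(avgF))
  dim(avg) <- c(n, n, n)
  item <- structure(
    list(map = density_map(avg, voxel_size = item_i$map$voxel_size),
         coverage = cnt),
    class = "spt_average")
  item
}

item_cov_counts <- function(x, n) {
  x <- as_item(x)
  if (!is.null(x$coverage)) x$coverage
  else item_coverage(x, n) * 1
}

rotate_counts <- function(cnt, Rmat) {
  out <- ifftshift3(rotate_array(fftshift3(cnt), Rmat, c(0, 0, 0)))
  out[out < 0] <- 0
  out
}

#' @export
print.spt_hac <- function(x, ...) {
  cat(sprintf("<spt_hac> %d leaves, %d merge events, %d items remaining\n",
              length(x$leaves), nrow(x$merges), length(x$items)))
  invisible(x)
}

#' @export
tidy.spt_hac <- function(x, ...) x$merges
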