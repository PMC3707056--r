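#' Pipeline configuration
#'
#' Assembles and validates the configuration of the end-to-end analysis:
#' simulate a cohort, rank against the hollow reference, quintile-split,
#' validate the split with mask t-tests, build wedge-compensated class
#' averages, assess symmetry and FSC, localize cavity density by
#' D8-restricted refinement, and estimate the encapsulated mass three ways.
#' Unknown keys are rejected up front, before any computation.
#'
#' @param n_empty,n_occupied,n_fibril Cohort composition.
#' @param spec A [phantom_spec] (the study conditions).
#' @param wedge A [wedge_spec].
#' @param snr Simulation signal-to-noise ratio.
#' @param seed Master seed for all randomness.
#' @param max_shift_vox True particle centering error (voxels).
#' @param coarse_step,refine_steps,max_shift Alignment search parameters.
#' @param split_mode `"quintile"` or `"halves"`.
#' @param mask_a_radius_frac Mask A (sphere) radius as a fraction of the box.
#' @param profile_step Rotational profile step in degrees.
#' @param n_iter_refine D8-restricted refinement iterations.
#' @param m_tric_kda Reference complex mass in kDa.
#' @param out_dir Output directory, or `NULL` for an in-memory run.
#' @return A validated `spt_config` list.
#' @export
pipeline_config <- function(n_empty = 40L, n_occupied = 40L, n_fibril = 0L,
                            spec = phantom_spec(occupancy_fraction = 60 / 950),
                            wedge = wedge_spec(),
                            snr = 0.5, seed = 1L, max_shift_vox = 2,
                            coarse_step = 15, refine_steps = c(5, 2),
                            max_shift = 4,
                            split_mode = "quintile",
                            mask_a_radius_frac = 0.45,
                            profile_step = 5,
                            n_iter_refine = 17L,
                            m_tric_kda = 950,
                            out_dir = NULL) {
  cfg <- as.list(environment())
  structure(cfg, class = "spt_config")
}

check_config <- function(config) {
  if (!inherits(config, "spt_config")) {
    if (!is.list(config)) abort("config must come from pipeline_config()")
    known <- names(formals(pipeline_config))
    bad <- setdiff(names(config), known)
    if (length(bad))
      abort(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
    config <- do.call(pipeline_config, config)
  }
  config
}

#' Run the end-to-end analysis pipeline
#'
#' Executes every stage in dependency order on a simulated cohort and
#' returns all intermediate and final results; when `out_dir` is set, every
#' table is written as a tab-separated file, every map as MRC, plus a
#' config echo and a timestamped log, so a run is fully reproducible from
#' its directory.  Re-running with the same config and seed reproduces all
#' tables exactly.
#'
#' @param config An `spt_config` from [pipeline_config()], or a plain list of
#'   overrides for its arguments.
#' @return An `spt_run` list: `manifest`, `ranked`, `split`, `comparisons`
#'   (list A/B/C), `avg_empty`, `avg_occupied`, `refined`, `profile_empty`,
#'   `profile_refined`, `fsc_curve`, `diff_map`, `masses` (list of three
#'   `spt_mass_estimate`s), `accuracy`, and `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  config <- check_config(config)
  log_lines <- character()
  note <- function(fmt, ...) {
    line <- sprintf("%s  %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                    sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
  }

  note("simulate: %d empty + %d occupied + %d fibril, snr %.3g, seed %d",
       config$n_empty, config$n_occupied, config$n_fibril, config$snr,
       config$seed)
  cohort <- generate_cohort(
    config$n_empty, config$n_occupied, config$n_fibril,
    spec = config$spec, wedge = config$wedge, snr = config$snr,
    seed = config$seed, max_shift_vox = config$max_shift_vox,
    m_tric_kda = config$m_tric_kda)
  manifest <- cohort$manifest
  freestanding <- cohort$particles[manifest$class_label != "fibril"]

  reference <- build_phantom(modify_spec(config$spec, occupancy_fraction = 0,
                                         apical_fraction = 0))
  n <- map_side(reference)

  note("rank: %d freestanding particles against hollow D8 reference",
       length(freestanding))
  ranked <- rank_by_reference(freestanding, reference,
                              coarse_step = config$coarse_step,
                              refine_steps = config$refine_steps,
                              max_shift = config$max_shift)

  split <- quintile_split(ranked, mode = config$split_mode)
  note("split: %d empty / %d occupied / %d discarded",
       length(split$empty_ids), length(split$occupied_ids),
       length(split$discarded_ids))

  mask_a <- mask_sphere(radius = config$mask_a_radius_frac * n)
  mask_b <- phantom_cavity_mask(config$spec)
  mask_c <- mask_difference(mask_a, mask_b)

  by_id <- stats::setNames(freestanding,
                           vapply(freestanding, `[[`, character(1), "id"))
  pick <- function(ids) by_id[ids]
  trans <- function(ids) lapply(ids, function(i) ranked_transform(ranked, i))

  comparisons <- lapply(stats::setNames(c("A", "B", "C"), c("A", "B", "C")),
    function(lab) {
      mk <- switch(lab, A = mask_a, B = mask_b, C = mask_c)
      compare_groups(pick(split$empty_ids), pick(split$occupied_ids),
                     mask = realize_mask(mk, n),
                     transforms_empty = trans(split$empty_ids),
                     transforms_occupied = trans(split$occupied_ids),
                     mask_label = lab)
    })
  note("stats: mask A t=%.2f, B t=%.2f, C t=%.2f",
       comparisons$A$t_score, comparisons$B$t_score, comparisons$C$t_score)

  avg_empty <- wedge_average(pick(split$empty_ids), trans(split$empty_ids))
  avg_occupied <- wedge_average(pick(split$occupied_ids),
                                trans(split$occupied_ids))

  profile_empty <- rotational_profile(avg_empty, step = config$profile_step)
  fsc_curve <- fsc(avg_empty, avg_occupied)
  note("fsc(empty, occupied): %.1f A at 0.333", fsc_resolution(fsc_curve, 1 / 3))

  note("refine: D8-restricted, %d iterations", config$n_iter_refine)
  refined <- hollow_template_refine(pick(split$occupied_ids), ranked,
                                    mask_b, n_iter = config$n_iter_refine)
  profile_refined <- rotational_profile(refined$average,
                                        step = config$profile_step)

  diff_map <- difference_map(refined$average, avg_empty,
                             norm_mask = realize_mask(mask_c, n))

  masses <- list(
    integration = mass_integration(avg_empty, diff_map, mask_c, mask_b,
                                   m_tric_kda = config$m_tric_kda),
    histogram = mass_histogram(comparisons$B, comparisons$C,
                               cavity_voxels = sum(realize_mask_array(mask_b, n)),
                               tric_voxels = sum(realize_mask_array(mask_c, n)),
                               m_tric_kda = config$m_tric_kda),
    rotational = tryCatch(
      mass_rotational(profile_refined, m_tric_kda = config$m_tric_kda),
      error = function(e) new_mass_estimate("rotational", NA_real_,
                                            config$m_tric_kda,
                                            list(error = conditionMessage(e))))
  )
  note("mass: integration %.1f, histogram %.1f, rotational %.1f kDa",
       masses$integration$mass_kda, masses$histogram$mass_kda,
       masses$rotational$mass_kda)

  accuracy <- split_accuracy(split, manifest)
  if (!is.na(accuracy)) note("classification accuracy: %.1f%%", accuracy)

  run <- structure(list(
    manifest = manifest, ranked = ranked, split = split,
    comparisons = comparisons,
    avg_empty = avg_empty, avg_occupied = avg_occupied,
    refined = refined, profile_empty = profile_empty,
    profile_refined = profile_refined, fsc_curve = fsc_curve,
    diff_map = diff_map, masses = masses, accuracy = accuracy,
    config = config, log = log_lines
  ), class = "spt_run")

  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

#' Fraction of non-discarded particles assigned to their true class
#'
#' @param split An `spt_split`.
#' @param manifest A cohort manifest with `id` and `class_label`.
#' @return Percent correct among particles the split did not discard, or
#'   `NA` when the manifest carries no truth labels.
#' @export
split_accuracy <- function(split, manifest) {
  tab <- split$table
  truth <- manifest$class_label[match(tab$id, manifest$id)]
  keep <- tab$set != "discarded" & !is.na(truth)
  if (!any(keep)) return(NA_real_)
  100 * mean(tab$set[keep] == truth[keep])
}

write_run <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(df, name) write_tsv_plain(df, file.path(dir, name))
  wt(run$manifest, "manifest.tsv")
  wt(as_tibble(run$ranked), "ranked.tsv")
  wt(run$split$table, "split.tsv")
  wt(dplyr::bind_rows(lapply(run$comparisons, glance)), "comparisons.tsv")
  wt(dplyr::bind_rows(lapply(run$comparisons, function(x)
    dplyr::mutate(tidy(x), mask_label = x$mask_label))), "mask_means.tsv")
  wt(as_tibble(run$fsc_curve), "fsc.tsv")
  wt(as_tibble(run$profile_empty), "profile_empty.tsv")
  wt(as_tibble(run$profile_refined), "profile_refined.tsv")
  wt(dplyr::bind_rows(lapply(run$masses, glance)), "mass.tsv")
  wt(run$refined$history, "refine_history.tsv")
  write_map(run$avg_empty$map, file.path(dir, "avg_empty.mrc"))
  write_map(run$avg_occupied$map, file.path(dir, "avg_occupied.mrc"))
  write_map(run$refined$average$map, file.path(dir, "refined_occupied.mrc"))
  write_map(run$diff_map, file.path(dir, "difference.mrc"))
  cfg <- run$config
  flat <- c(cfg[c("n_empty", "n_occupied", "n_fibril", "snr", "seed",
                  "max_shift_vox", "coarse_step", "max_shift", "split_mode",
                  "mask_a_radius_frac", "profile_step", "n_iter_refine",
                  "m_tric_kda")],
            list(refine_steps = cfg$refine_steps),
            unclass(cfg$spec), unclass(cfg$wedge))
  write_config_echo(flat, file.path(dir, "config_echo.txt"))
  writeLines(run$log, file.path(dir, "log.txt"))
  invisible(dir)
}

#' @export
print.spt_run <- function(x, ...) {
  cat("<spt_run>\n")
  cat(sprintf("  particles: %d (%d discarded by split)\n",
              nrow(x$manifest), length(x$split$discarded_ids)))
  if (!is.na(x$accuracy))
    cat(sprintf("  classification accuracy: %.1f%%\n", x$accuracy))
  cat(sprintf("  FSC(empty, occupied) at 0.333: %.1f A\n",
              fsc_resolution(x$fsc_curve, 1 / 3)))
  for (m in x$masses)
    cat(sprintf("  mass (%s): %.1f kDa\n", m$method, m$mass_kda))
  invisible(x)
}
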