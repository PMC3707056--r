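# Shared fixtures: all synthetic, built in code at test time.

# small grid with the same physical field of view as the 48^3 default
spec_small <- function(...) {
  phantom_spec(box = 32L, voxel_size = 6.6, ...)
}

# fully asymmetric object (no C8, no flip symmetry): barrel + off-axis
# interior globule + on-axis apical blob
asym_phantom <- function(box = 32L, voxel_size = 6.6) {
  build_phantom(phantom_spec(box = box, voxel_size = voxel_size,
                             occupancy_fraction = 0.3, interior_offset = 20,
                             apical_fraction = 0.3))
}

full_wedge <- function() wedge_spec(-90 + 1e-9, 90)

# per-session cache so expensive cohorts/runs are computed once
.spt_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.spt_cache[[key]])) .spt_cache[[key]] <- force(expr)
  .spt_cache[[key]]
}

# the reference end-to-end run at the package's study conditions
# (40 empty + 40 occupied, 48^3 box, snr 0.5, +/-60 degree wedge)
reference_run <- function() {
  cached("reference_run", run_pipeline(pipeline_config(seed = 42)))
}

# noise-free small cohort in the small box, with its ranking
small_cohort_ranked <- function() {
  cached("small_cohort_ranked", {
    sp <- spec_small(occupancy_fraction = 60 / 950)
    coh <- generate_cohort(5, 5, 0, spec = sp, snr = Inf, seed = 3)
    ref <- build_phantom(phantom_spec(box = 32L, voxel_size = 6.6))
    rk <- rank_by_reference(coh$particles, ref)
    list(spec = sp, cohort = coh, reference = ref, ranked = rk)
  })
}
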