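# sptkit

Missing-wedge-aware single particle tomography (SPT) in R, built around the
analysis that distinguishes cavity-empty from cavity-occupied particles of a
barrel-shaped, double-ring chaperonin (the TRiC/CCT family) and estimates
the mass encapsulated in its central chamber.

## The problem

Cryo-electron tomography images whole fields of macromolecules in 3-D, but a
±60° tilt series leaves a *missing wedge* of Fourier space unmeasured, so
every extracted subtomogram is anisotropically distorted, noisy, and
randomly oriented. SPT recovers interpretable structures by aligning,
classifying and averaging many such subtomograms. For a chaperonin that may
or may not hold substrate inside its folding chamber, the analysis must
answer: which particles are cavity-empty and which cavity-occupied, is the
distinction statistically real and localized to the chamber, and how much
mass is inside?

sptkit implements that pipeline end to end, exercised on synthetic cohorts
with known ground truth:

* **Simulation** — a D8-symmetric double-ring phantom (2×8 Gaussian
  subunits, hollow chamber, optional off-axis interior globule or apical
  density), posed uniformly over SO(3), wedge-filtered in the particle
  frame, with calibrated Gaussian noise (`phantom_spec()`,
  `generate_cohort()`).
* **Alignment** — constrained cross-correlation computed only over the
  Fourier overlap of the two particles' wedges, mean-subtracted and
  normalized within the overlap so the score is wedge-occupancy
  independent; exhaustive-then-local search; wedge-compensated averaging;
  reference-free hierarchical ascendant classification (`constrained_cc()`,
  `align_pair()`, `wedge_average()`, `hac_average()`).
* **Classification** — ranking against a hollow D8 reference, quintile
  split (top two quintiles cavity-empty, bottom two cavity-occupied, middle
  discarded), and Welch t-tests of per-particle mean densities under three
  masks: A (everything), B (the cavity), C = A∖B
  (`rank_by_reference()`, `quintile_split()`, `compare_groups()`).
* **Validation** — rotational correlation profiles testing C8/D8 symmetry,
  peak counting, Fourier shell correlation with threshold-crossing
  resolution (`rotational_profile()`, `count_symmetry_peaks()`, `fsc()`).
* **Cavity mass** — D8-restricted hollow-template refinement localizing the
  interior density, Guinier-matched difference mapping, and three mass
  estimators scaled by the complex's ~950 kDa reference mass:

  * integration: `m = 950 · ∫_B diff / ∫_C empty`
  * histogram: `m = 950 · (ΔmeanB · V_B) / (meanC · V_C)`
  * rotational: `m = 950 · [mean(cc₄₅, cc₃₁₅) − cc₁₈₀]`

  (`hollow_template_refine()`, `difference_map()`, `mass_integration()`,
  `mass_histogram()`, `mass_rotational()`).

Volumes are MRC mode-2 files (`read_map()`/`write_map()`); tabular results
are tibbles with `tidy()`/`glance()`/`autoplot()` methods.

## Worked example

The whole analysis on a simulated cohort of 40 cavity-empty + 40
cavity-occupied particles (48³ boxes at 4.4 Å/voxel, ±60° wedge, SNR 0.5,
interior mass equivalent to 60 kDa):

```r
library(sptkit)
run <- run_pipeline(pipeline_config(seed = 1))
print(run)
#> <spt_run>
#>   particles: 80 (16 discarded by split)
#>   classification accuracy: 100.0%
#>   FSC(empty, occupied) at 0.333: 20.7 A
#>   mass (integration): 62.3 kDa
#>   mass (histogram): 70.5 kDa
#>   mass (rotational): 122.1 kDa

run$comparisons$B; run$comparisons$C
#> <spt_group_comparison> mask B: t = -6.084 (df 55.0), p = 1.18e-07 ***
#> <spt_group_comparison> mask C: t = 0.022 (df 54.9), p = 0.983
```

Reading: the quintile split assigned every non-discarded particle to its
true class; the cavity mask (B) separates the two groups far beyond the
99.9% confidence level while the cavity-excluded mask (C) shows no
difference, so the signal is localized to the chamber; the direct
(integration) estimator recovers the 60 kDa ground truth within a few
percent, the histogram estimator runs somewhat high (its groups are
score-selected extremes), and the dip-based rotational estimator gives the
expected order-of-magnitude cross-check. `autoplot()` renders the ranked
correlation curve, the per-mask histograms, the C8/D8 rotational profiles
(the cavity-occupied average dips at 180°), and the FSC curve.

Setting `out_dir` in the config writes every table (TSV), every map (MRC),
a config echo and a timestamped log to a run directory; rerunning the same
config and seed reproduces all tables exactly.

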