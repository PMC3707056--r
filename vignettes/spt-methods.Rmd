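---
title: "Single-particle tomography of a double-ring chaperonin: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-particle tomography of a double-ring chaperonin: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

sptkit implements a complete single-particle tomography (SPT) workflow for a
barrel-shaped, double-ring chaperonin of the TRiC/CCT family: simulation of
subtomogram cohorts distorted by the tomographic missing wedge,
missing-wedge-aware alignment and averaging, reference-ranked classification
of cavity-empty versus cavity-occupied particles with statistical
validation, point-group symmetry and resolution analysis, and estimation of
the mass encapsulated in the chaperonin's central chamber.  This vignette
explains the underlying models, the numerical choices, and the limits of
what the synthetic experiments can show.

## The measurement model

A tilt series collected from -60 to +60 degrees samples only part of
Fourier space: every frequency whose normal direction falls outside the
tilt range is unmeasured.  For a single-axis scheme this unsampled region
is a wedge of half-angle 30 degrees around the beam axis, independent of
the position along the tilt axis; two thirds of Fourier space is retained.
`wedge_spec()` describes the tilt geometry and `wedge_mask()` realizes the
retained region analytically on the FFT grid (the mask of a rotated
particle is evaluated at rotated frequency coordinates, so no mask
interpolation is ever needed for raw particles).

`simulate_subtomogram()` poses a phantom with a rigid transform, zeroes the
Fourier coefficients inside the wedge *in the particle frame* (after the
rotation), and then adds white Gaussian noise.  Applying the wedge after
rotation reflects how tomographic distortion acts on differently oriented
particles in the same tomogram: each particle's wedge is tied to its pose.
The signal-to-noise ratio is defined as the variance of the wedge-filtered
signal within the particle's support (voxels above 5% of the posed
phantom's maximum) divided by the noise variance.  Referencing the support
rather than the whole box prevents empty padding from inflating the nominal
SNR.  The default `snr = 0.5` is a deliberate package choice for
moderately binned cryo-tomographic data of a 1 MDa particle; the true
per-particle SNR of real tomograms is not a measured constant, and all
statistical conclusions below are demonstrated at this default.

## The phantom

`build_phantom()` realizes the complex as two stacked rings of eight
Gaussian subunits (sigma 13 Å, ring radius 55 Å, rings at z = ±28 Å), an
equatorial wall, and a chamber carved exactly hollow inside a cylinder of
radius 38 Å and half-height 40 Å.  The carve window is rotationally and
flip symmetric, so the hollow phantom is exactly D8.  The geometry gives a
~160 Å barrel in a 48³ box at 4.4 Å/voxel, matching the deposited maps'
scale; the 38 Å chamber radius reflects the anatomy of the chaperonin's
folding chamber (~80–90 Å across).

The cavity-occupied state adds an interior globule (sigma 9 Å — the size
of a compact ~60 kDa oligomer) displaced 13 Å off the symmetry axis and
rescaled so that its realized integral is `occupancy_fraction` times the
barrel integral; the default `f = 60/950` emulates a 60 kDa cargo inside a
950 kDa complex.  The off-axis placement makes the cargo D8-asymmetric, so
symmetry-restricted refinement has a well-defined site to find, and it
produces the characteristic u-shaped dip of the rotational correlation
profile at 180 degrees.  The fibril-bound state instead adds an on-axis
apical blob beyond one ring.

What the phantom does *not* model: contrast transfer, dose damage,
conformational flexibility, neighboring density (fibrils, crowding), or
gold fiducials.  Passing tests on these synthetics therefore demonstrate
the correctness of the pipeline's algorithms under controlled conditions,
not the attainable quality on real tomograms.

## Missing-wedge-aware scoring and alignment

`constrained_cc()` computes correlation only over the Fourier-space
overlap of the two particles' sampled regions (the second particle's wedge
rotated with it).  Within the overlap, the zero-frequency coefficient is
removed — the exact Fourier counterpart of real-space mean subtraction —
and each spectrum is normalized to unit power, which makes the score
independent of wedge occupancy, density scaling, and offsets.  With full
coverage the score equals real-space Pearson correlation to machine
precision, which is how the implementation is cross-checked.

`align_pair()` scans an exhaustive Euler grid (default 15 degrees) and
finds, for every orientation, the translational optimum on the constrained
correlation map (an inverse FFT of the masked, normalized cross-power),
then hill-climbs locally at 5- and 2-degree steps.  Translations are
integer-voxel; at the ~50 Å resolutions relevant here sub-voxel shifts are
immaterial.  `rank_by_reference()` uses the same machinery against a
wedge-free reference with two structural economies: the orientation grid is
restricted to a fundamental domain of D8 (the reference's point group, 16
times smaller), and the coarse scan is scored at zero shift for all
particles at once (one matrix product per orientation block), with the
translational search and angular refinement applied at each particle's
coarse optimum.  Because the reference is wedge-free, the Fourier overlap
equals each particle's own wedge and is identical across orientations.

Rotations resample trilinearly about the voxel at index `floor(N/2)`
(0-based).  Two numerical consequences are worth knowing.  First,
quarter-turns about this center map one boundary row outside the grid, so
maps whose content reaches the box edge (e.g. wedge ringing) lose a sliver
under 90-degree rotations; the score-symmetry property
`cc(a,b,t) = cc(b,a,t⁻¹)` therefore holds to machine precision only for
compactly supported, fully sampled inputs and to ~1e-2 for wedged ones.
Second, trilinear interpolation costs about 0.1% correlation per resampling
at 4.4 Å/voxel on this phantom — negligible against the ~50 Å feature
scale.

`wedge_average()` compensates the missing wedge the standard way: Fourier
coefficients of the aligned particles are summed and divided by the
per-voxel count of contributing wedges; voxels covered by no particle are
zeroed.  Averaging eight or more random orientations refills the wedge
(reconstruction correlation > 0.99 against the phantom).
`hac_average()` builds on this for reference-free hierarchical ascendant
classification: all item pairs are aligned, the best-scoring pair is merged
into a wedge-compensated average carrying the union coverage, and the
process repeats; ties break toward the lowest particle index, and pairwise
alignments between unchanged items are cached.  Merge scores are *not*
guaranteed monotone: merged averages are less noisy than raw particles and
can legitimately correlate better with remaining items than any raw pair
did.

## Classification and validation

The classification protocol ranks every freestanding particle by its best
constrained correlation against the hollow D8 reference; cavity-empty
particles score higher.  `quintile_split()` takes quintiles of
`floor(n/5)`: the top two quintiles become the cavity-empty set, the bottom
two the cavity-occupied set, and the middle quintile (plus any remainder,
kept central so the two sets stay equal-sized) is discarded.  For n = 890
this yields quintiles of 178 and final sets of 356 — 40% of the input
each.  A `mode = "halves"` variant splits at the median, for small
per-tomogram sets.

`compare_groups()` validates a split by comparing the two groups'
per-particle mean densities under three masks — A, a sphere of radius 0.45
box; B, the cavity cylinder taken from the phantom spec; C = A AND NOT B —
with a two-sided Welch t-test (no variance-equality assumption is
defensible here) flagged at the 95% and 99.9% confidence levels.  At the
package's study conditions the cavity mask separates the groups beyond the
99.9% level while the cavity-excluded mask shows no significant
difference, localizing the distinction to the chamber.

One statistical subtlety is documented rather than hidden: the quintile
sets are selected by the same ranking score that correlates with each
particle's apparent cavity content, so group differences measured on the
selected extremes are inflated relative to the population difference
(about +15–40% depending on the noise draw).  This propagates into the
histogram-based mass estimator below and parallels the spread between the
original study's two estimates.

## Symmetry, resolution, and the 180-degree dip

`rotational_profile()` correlates a map with itself rotated about Z over a
5-degree azimuth scan inside a spherical mask of radius 0.45 box (corners
carry no signal and would dilute the correlation).  The C8 series uses
plain azimuthal rotations; the D8 series first applies the two-fold flip
about X — the in-plane axis exchanging the two rings, the standard dihedral
generator — then scans.  An ideal D8 map peaks above 0.99 every 45 degrees
in both series.  `count_symmetry_peaks()` finds circular local maxima with
a topographic prominence threshold.  A localized off-axis cavity mass
coincides with itself at 0 degrees and opposes itself at 180, producing a
u-shaped dip whose depth grows with the mass.

`fsc()` computes per-shell normalized complex correlation over
integer-radius Fourier shells (shell width one voxel, no smoothing), and
`fsc_resolution()` interpolates the first downward crossing of a
threshold; shells with negligible power report zero rather than round-off
noise.  Conventions follow standard practice: 0.5 against a
much-higher-resolution reference, 0.333 between two independent maps of
similar quality.

## Cavity localization and the three mass estimators

`hollow_template_refine()` localizes intra-cavity density without template
bias: starting from each particle's alignment to the hollow reference, the
particle may only visit the sixteen D8-related versions of that alignment,
scored by cavity-masked correlation against the evolving average, for up to
17 iterations (with early stop when the cavity changes by less than 1e-4
relative RMS).  The barrel frame is never revisited, so the chaperonin
stays put while the cargo converges to a consistent site.  A reassignment
hysteresis of 0.01 correlation units keeps noise- and ringing-level score
differences from shuffling assignments; at the study noise level an
all-empty cohort undergoes no reassignments at all.  Because the reference
is D8-symmetric, the converged site is defined up to a global D8 branch: the
cargo localizes to radius `interior_offset` in the equatorial plane, at an
azimuth chosen by the initial average.

`difference_map()` subtracts the cavity-empty average from the
cavity-occupied (refined) average after matching intensity and amplitude
falloff.  The amplitude matching is a two-parameter Guinier fit
(gain = exp(a + b·s²)) to the shell-amplitude ratios computed over the
*shared* region (mask C): estimating the filter on the region where the
maps should agree keeps the genuine cavity difference out of the filter,
and the smooth form keeps per-shell estimation noise from being stamped
into the difference map.  A least-squares intensity scale and offset over
mask C follows, then voxel-wise subtraction.  Negative difference values
are kept during integration so that noise cancels.

The three estimators, each scaled by the complex's reference mass
(`m_tric_kda = 950`):

* **Integration** — mass = 950 × (difference-map integral over the cavity
  mask) / (empty-average integral over the complex-only mask).  The most
  direct estimator and the most accurate on synthetics (within a few
  percent of the 60 kDa ground truth at study conditions).
* **Histogram** — works from the per-particle group means under masks B
  and C: the empty group's cavity mean is the background subtracted from
  the occupied group's cavity mean, scaled by the cavity/complex volumes
  and the pooled complex-region density.  Inherits the selection inflation
  discussed above (typically +15–40% on 40+40 cohorts).
* **Rotational** — 950 × (mean of the 45- and 315-degree peaks minus the
  180-degree peak) of the refined average's C8 profile.  The first peak is
  unusable (everything correlates with itself at 0 degrees), so the
  flanking peaks stand in.  The linear scaling of a correlation difference
  by the complex mass is an interpretation — the correlation deficit scales
  with the cargo's squared density rather than its integral — and on a
  compact high-contrast synthetic cargo it overestimates by roughly a
  factor of two; it is reported as an order-of-magnitude cross-check, and
  the scaling lives in one place (`mass_rotational()`) for revision.

Clamped (at zero) integration/histogram estimates keep their unclamped
value in `raw_kda`; on all-empty control cohorts the raw estimates sit at
the small-cohort noise floor (|raw| well under half the 60 kDa signal)
and the cavity t-test is non-significant.

## Problem sizes and determinism

The bundled tests and the acceptance script run the full pipeline on a
cohort of 40 empty + 40 occupied particles in 48³ boxes — large enough for
the quintile protocol to operate and for the estimators to stabilize,
small enough for a laptop-scale run.  Unit tests use 32³ boxes at 6.6
Å/voxel (the same physical field of view) and fewer particles.  All
randomness flows from explicit integer seeds through a private RNG stream
(`generate_cohort()` regenerated with the same seed is bit-identical), and
every pipeline stage is deterministic, so a run directory plus its config
echo reproduces exactly.

## Known limitations

* Orientation grids are product grids in Euler angles, denser near the
  poles; for the quotient searches used here the redundancy is harmless
  but costs some speed.
* Wedge coverage of averages is rotated by trilinear resampling and
  thresholded, a slight erosion of partial-coverage shells.
* The difference-map localization figure (fraction of |difference| inside
  the cavity) degrades on small cohorts: residual barrel mismatch between
  two 8-particle wedge-compensated averages spreads |difference| widely
  even though the signed cavity integral — what the mass estimate uses —
  remains accurate.
* The histogram estimator's selection inflation is inherent to measuring
  group differences on score-selected extremes; the package documents it
  rather than correcting it, because the correction would depart from the
  protocol being reproduced.
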