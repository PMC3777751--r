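---
title: "Methods: a pulsed-ASL perfusion pipeline on digital phantoms"
author: "aslcbf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a pulsed-ASL perfusion pipeline on digital phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## What this package computes

`aslcbf` implements a complete analysis chain for pulsed arterial spin
labeling (PASL) perfusion MRI as used in multi-site neurodegeneration
studies: a resting PICORE/Q2TIPS acquisition (one M0 calibration volume
followed by alternating label/control volumes) is denoised, subtracted
pairwise, quantified to cerebral blood flow (CBF) with a one-compartment
QUIPSS-II model, cleaned by an adaptive correlation-based outlier
procedure, partial-volume corrected, and summarized as mean gray-matter
CBF in a composite spherical "meta-ROI". At the cohort level the package
fits the associated statistical battery: dummy-coded group regression with
planned contrasts against the cognitively normal (CN) group, partial
correlations of the biomarkers with disease severity, and a hierarchical
stepwise regression in which age and education are forced and meta-ROI CBF
and normalized hippocampal volume compete for entry.

Because the raw clinical scans such analyses are developed on are
access-controlled, the package ships a first-class synthetic-data module: a
digital perfusion phantom whose forward signal model is the *exact inverse*
of the quantification model, and a cohort generator with group-graded
perfusion and hippocampal effects. All tests and the acceptance script run
end-to-end on these synthetic data.

## The quantification model

For each adjacent (label, control) pair the difference signal
$\Delta M = \text{control} - \text{label}$ is converted to CBF per voxel as

$$
\mathrm{CBF} \;=\;
\frac{6000\,\lambda\,\Delta M}
     {2\,\alpha\, M_0\, (\mathrm{TI_1}/1000)\,
      e^{-\mathrm{TI}_{2,k}/T_{1,\mathrm{blood}}}}
\quad\left[\tfrac{\mathrm{ml}}{100\,\mathrm{g\,min}}\right],
$$

with $\mathrm{TI}_{2,k} = \mathrm{TI_2} + k\,\Delta t_{\mathrm{slice}}$ for
0-based slice index $k$ (sequential ascending 2D readout). Defaults:
bolus duration $\mathrm{TI_1} = 700$ ms and inversion-to-imaging time
$\mathrm{TI_2} = 1900$ ms (the acquisition protocol), blood--brain
partition coefficient $\lambda = 0.9$ ml/g, labeling efficiency
$\alpha = 0.95$, arterial blood $T_1 = 1664$ ms at 3 T, and a 45 ms
per-slice increment. $\lambda$, $\alpha$, $T_{1,\mathrm{blood}}$ and the
slice increment are standard literature constants, not protocol values;
they live in one `quant_params()` object, every piece of code that needs
them takes that object, and nothing downstream depends on the defaults
implicitly. The per-slice increment in particular is an assumption — the
product sequence's actual value is not documented — and is exposed as
`slice_time_ms`.

Negative CBF values are retained at quantification time; deciding whether
a subject has "too much" negative gray matter is the job of the QC stage.
Voxels whose M0 falls below 10% of its robust (98th percentile) maximum
are excluded and flagged, since dividing by a near-zero M0 produces
unbounded nonsense.

The phantom's forward model computes $\Delta M$ from a ground-truth CBF
map by inverting exactly this formula with the same `quant_params` object,
which gives the package a machine-precision round-trip invariant
(`simulate -> subtract -> quantify` recovers the truth to $10^{-12}$
relative error on noise-free data) that pins down every constant and unit
in both directions.

## The denoising chain

The order is fixed and not configurable: motion correction, spatial
smoothing, temporal high-pass filtering, nuisance regression. Each stage
preserves the grid.

**Motion correction.** Each volume is rigidly aligned to the M0 reference
by minimizing the mean squared intensity difference over the brain mask.
The minimization is Gauss--Newton least squares: steepest-descent images
are formed from the central-difference spatial gradient of the reference,
and the linearized 6-parameter update (3 translations in mm, 3 rotations
in degrees about the volume center) is iterated to sub-voxel convergence.
A derivative-free simplex search was tried first and could not resolve
sub-degree rotations (the cost curvature along rotation axes is tiny on a
smooth phantom) while being two orders of magnitude slower; Gauss--Newton
recovers translations and rotations with correlation > 0.99 against the
phantom's known motion schedule. All-zero volumes are flagged and skipped
with zero parameters.

**Spatial smoothing.** Isotropic Gaussian at FWHM 4 mm, applied per volume
as separable 1D convolutions with a kernel *sampled* at integer voxel
offsets and normalized to unit sum. At these voxel sizes (3.4 mm in-plane,
5 mm slice pitch) the kernel sigma is about half a voxel, where a sampled
kernel and the continuous Gaussian differ noticeably; tests therefore
check the sampled-kernel prediction, which is what the code computes.
Boundaries are zero-padded; mass is conserved only away from the edges,
and the edge bias is the reason ROI-level checks erode their masks.

**Temporal high-pass filter.** A second-order Butterworth high-pass at
0.01 Hz, applied forward and backward (zero phase) to every voxel
timecourse of the non-M0 volumes. Order 2 and the zero-phase application
are choices made for stability on a 104-point series. Two details matter:

* the per-voxel temporal mean is re-added after filtering, so the absolute
  signal scale — and with it M0-relative quantification — survives;
* the series is extended by *symmetric (even) reflection* before
  filtering and trimmed afterwards. Zero-padding (what `signal::filtfilt`
  does natively) produces edge transients that visibly corrupt the first
  and last difference maps; even reflection continues a label/control
  alternation seamlessly, so the perfusion frequency (at Nyquist,
  $1/(2\cdot 3.4\,\mathrm{s}) \approx 0.147$ Hz) passes the filter edges
  undistorted. The filter is materialized once per series length as a
  $T \times T$ linear operator and applied to all voxels with one matrix
  product.

**Nuisance regression.** Per voxel, ordinary least squares on an
intercept, the six motion timecourses, the global-mean, WM-mean and
CSF-mean signals (WM/CSF segments at probability > 0.9), and a protected
$\pm 1$ label/control alternation covariate. The fitted nuisance
components are subtracted; the intercept and alternation components are
retained. The protection is essential: in an ASL series the perfusion
signal *is* the alternation component, and the global/WM/CSF timecourses
contain it, so unprotected global-signal regression would delete the very
signal being measured. The implementation orthogonalizes the nuisance
block against the protected columns before fitting, and drops nuisance
columns whose residual norm after orthogonalization is below $10^{-8}$ of
their original norm — such a column is numerically collinear with the
protected block, and the *direction* of its rounding residue is arbitrary
(on noise-free data it overlaps the alternation and would silently delete
the perfusion signal; this failure mode is covered by a test). The
protection is switchable (`protect_alternation = FALSE`) for the classical
fully-orthogonal residual behavior.

**Brain mask.** Threshold at 30% of the robust maximum of M0, largest
6-connected component. This replaces an external skull-stripping tool; on
phantoms (and any data without extracranial structure) it is adequate, and
it is scale-free by construction.

## Adaptive cleaning of the CBF time series

The 52 per-pair CBF maps are screened in two stages.

*Initial screening* flags pairs by framewise displacement
(sum of absolute translation increments plus 50 mm times absolute rotation
increments in radians; threshold 1.5 mm, pooled per pair by the maximum of
its two volumes) or by whole-brain mean CBF outside mean $\pm$ 2.5 SD of
the series. These thresholds follow common ASL-toolbox practice and are
exposed as parameters.

*Adaptive cleaning* then iterates: for each kept map, the Pearson
correlation (CC) over gray-matter voxels between that map and the
voxelwise mean of the *other* kept maps (leave-one-out) is computed; maps
with CC below 0.15, or outside mean $\pm$ 2 SD of the image CCs, are
removed; repeat until no new outlier appears. Two readings of the
reference band were possible, and the package deliberately uses the one
over *all* maps' CCs (including already-removed ones, whose CCs are
recomputed against the current kept set each iteration):

* with the band over currently-kept maps only, each iteration trims the
  ~5% tails of an ever-tighter, approximately normal CC distribution, so
  the procedure keeps nibbling at clean maps for many iterations and its
  precision as an outlier detector collapses;
* with the band over all CCs, genuinely corrupted maps keep the band wide,
  the procedure converges in one or two iterations, and on 100 seeded
  phantoms with 2--6 injected corruptions it recovers the injected set
  with recall and precision at or near 1.0.

The kept-only variant remains available (`band_scope = "kept"`), as does
the include-self reading of the reference mean (`include_self = TRUE`).
When the kept CCs are numerically degenerate (SD below $10^{-8}$, e.g.
identical maps), the band rule is inactive — otherwise it would flag
machine-epsilon differences. Maps flagged by the initial screen never
contribute to reference means. The kept maps are averaged voxelwise into
the final CBF image.

Two subject-level flags close the QC stage: `coverage_ok` (at least 90% of
brain-mask voxels carry nonzero signal in every volume) and
`negativity_ok` (at most 10% of gray-matter voxels negative in the final
CBF image). Subjects failing either are excluded from group statistics
with the reason recorded.

One emergent behavior worth knowing: when a corrupted volume passes
through the zero-phase temporal filter, a little of its energy rings into
neighboring volumes, so the full pipeline typically removes a few maps
*around* each injected corruption in addition to the corruption itself.
Real multi-site series show the same pattern (roughly 8--13 of 52 points
removed per subject); the module-level recall/precision characterization
therefore runs the cleaning on smoothed-only data, where the injected set
is exactly separable, while pipeline-level tests accept the collateral
removals as part of the method.

## Partial-volume correction and ROIs

Gray-matter CBF is corrected for partial-volume dilution by the linear
two-tissue model: for voxels with $P_{GM} \ge 0.3$,

$$\mathrm{CBF}_{corr} = \frac{\mathrm{CBF}}{P_{GM} + 0.4\,P_{WM}},$$

treating white matter as perfused at 40% of the gray-matter rate. The
upstream method citation for this step does not print formulas, so this
standard linear correction is the package's documented interpretation; the
`wm_ratio` and the GM floor are parameters, voxels below the floor are
zeroed and excluded from ROI means via an attribute, and the correction
never changes sign.

ROIs are unions of spheres defined in template millimeter coordinates and
rasterized by voxel-center inclusion. The composite meta-ROI
(three spheres in the gray-matter shell) and a single-sphere control ROI
are *derived from the phantom geometry* by `phantom_roi_specs()` rather
than hard-coded, because the published composite ROI's coordinates live in
a PET meta-analysis, not in the protocol itself; configurations round-trip
through YAML. Normalized hippocampal volume is the mean of left and right
volumes divided by intracranial volume (GM + WM + CSF); segmentation
itself is out of scope — volumes are pipeline inputs.

In this synthetic setting all subjects share one grid, so template
registration is a no-op; the registration seam is where a deformable
registration would slot in for real data.

## The statistical battery

All tests are two-sided; missing values are deleted listwise per analysis;
no multiple-testing correction is applied (the contrasts are planned
comparisons), which the documentation states rather than hides.

* `ttest_from_summary()` — pooled-variance two-sample t from printed
  means/SDs/sizes, the form needed to recompute demographic-table
  comparisons.
* `chi2_frequencies()` — Pearson chi-square on a 2x2 table without
  continuity correction.
* `group_model()` — OLS with three group dummies (CN reference) and age;
  overall F, partial F for the dummy block, and per-group contrasts.
  Cohen's d is reported twice: the primary value from raw
  (covariate-unadjusted) group means over the pooled raw SD, signed so
  that a deficit relative to CN is positive, and an age-adjusted variant
  from the model coefficient. Published d values rarely state which
  convention was used; emitting both makes the choice inspectable.
* `partial_correlation()` — correlation of OLS residuals after removing
  the covariates from both variables, $p$ from
  $t = r\sqrt{df/(1-r^2)}$, $df = n - k - 2$. "Correlation with age and
  education as covariates" is read as exactly this; the plain correlation
  is the no-covariate special case.
* `stepwise_hierarchical()` — forced covariates always retained; at each
  step the candidate with the smallest partial-F p value enters if below
  `p_enter = 0.05`; standardized betas come from refitting the final model
  on z-scored variables. With two candidates the procedure is equivalent
  to an exhaustive evaluation of the four possible models under the same
  entry rule, which is how it is tested.

## The synthetic cohort: what it emulates, and what it does not

`cohort_spec()` fixes the study conditions. Group sizes default to the
analyzed sample n = (44, 31, 30, 15) for CN / early MCI / late MCI / AD —
the sizes the published test statistics' degrees of freedom correspond
to — with demographics (age, education, sex ratios) matching the published
demographic table. The graded biomarker structure follows the published
standardized effect sizes: meta-ROI CBF deficits of about 0.27 / 0.58 /
1.09 pooled SD for EMCI / LMCI / AD (spacing set on the *measured* scale,
i.e. true between-subject SD 8 ml/100g/min combined with 2.5 ml/100g/min
measurement noise, since reported effect sizes are always on measured
values), and hippocampal effects of about $-0.35$ / 0.26 / 1.30 SD
(the early-MCI group's slightly *larger* volumes included). The
control-ROI CBF carries no group effect by construction, mirroring the
regional-specificity control.

Severity scores (CDR sum of boxes, MMSE, delayed logical memory) are noisy
linear functions of the *true* biomarkers, floored/capped to their scales.
Coefficients were chosen so both biomarkers carry independent signal and
the severity--biomarker partial correlations land in the −0.3 to −0.5
band. Two consequences are documented rather than patched: severity is
*purely* biomarker-mediated, so group spreads of CDR-SB/MMSE are narrower
than in a real clinical table; and nothing in the generator encodes the
published correlation values themselves, so recovered correlations are the
synthetic cohort's, not reproductions.

The single-subject phantom is three concentric ellipsoidal shells (CSF
core, WM shell, GM shell; in-plane anisotropic so that in-plane rotation
is identifiable for motion estimation) with probabilities softened by a
0.6-voxel Gaussian to create genuine partial-volume voxels, on the
acquisition grid: 64 x 64 x 24 voxels of 3.4 x 3.4 x 5.0 mm (4 mm slices
with a 25% gap; the in-plane size approximates the protocol's
field of view — exact FOV fidelity is not needed by any computation).
Proton densities are 850 / 700 / 1000 scanner units for GM / WM / CSF.
The acquisition protocol states no noise or drift magnitudes, so these are
assumptions, chosen once: thermal noise SD 0.75 units, so that the
per-pair voxel-level CBF SNR is far below 1 (as in real PASL) while the
whole-GM leave-one-out CCs fall at 0.2--0.6, the regime in which a 0.15 CC
floor is meaningful; and a sinusoidal global drift of amplitude 5 units
with a 200 s period, comfortably inside the high-pass stopband.

Corrupted volumes come in two shapes. A `"noise"` corruption *adds* a
spatially decorrelated Gaussian burst at 1.5% of mean brain signal: an
additive burst (rather than replacing the volume) is deliberate, because a
replacement leaves an anatomical residual in the difference image whose
correlation with the perfusion pattern is large and sign-dependent on pair
position — the opposite of "decorrelated". An `"offset"` corruption adds a
global 5% intensity jump, which shifts the pair's whole-brain CBF level
and is the initial screen's job to catch. Burst and jump magnitudes are
spec parameters.

What the phantom does *not* emulate: real cortical anatomy and folding,
vascular territories and transit-time heterogeneity, physiological
(cardiac/respiratory) noise, coil or B0 artifacts, EPI distortion, or
between-site hardware differences. Passing tests on these phantoms
demonstrates that the pipeline's *computations* are correct and its
detection procedures behave as designed under controlled corruption; they
do not certify performance on clinical data.

## Numerical choices and degenerate inputs

* Affines are diagonal voxel-size matrices (0-based voxel index to mm);
  rotations act about the volume center; resampling is trilinear with
  zero outside the field of view.
* Sampled (not integrated) Gaussian kernels; radius 4 sigma.
* The filter operator is rebuilt per series length; even-reflection pad
  length is `min(T-1, 12 * (order + 1))`.
* Collinear nuisance columns are dropped with a warning, protected columns
  never are.
* Leave-one-out means use a running-sum identity, so cleaning cost is
  linear in maps per iteration; the kept set shrinks strictly, bounding
  iterations by the map count.
* All simulation randomness flows from integer seeds in the spec objects;
  identical spec implies bit-identical output. The pipeline derives
  per-subject seeds from the master seed.
* Degenerate inputs have defined behavior: all-zero volumes in motion
  correction are flagged; an empty WM/CSF segment, an empty brain mask, an
  empty ROI intersection, all maps removed, or a missing CN reference each
  raise a named error.

## Problem sizes used by the tests

The test suite and acceptance script choose sizes that keep the full run
in minutes while preserving the regimes that matter: module tests use
24 x 24 x 10 to 32 x 32 x 14 grids with 9--105 volumes; the quantification
round trip runs at the full 64 x 64 x 24 acquisition geometry; the
cleaning characterization runs 100 phantoms at 48 x 48 x 20 (the CC
sampling spread scales with gray-matter voxel count, and this size keeps
the clean-CC distribution comfortably clear of the 0.15 floor, as the full
grid does); cohort-level statistics run at the full n = 120; the null
calibration of the group F test uses 1000 replicates.

## Known limitations

* The linear PVE correction is one published family among several; a
  regression-based correction would slot behind the same interface.
* The meta-ROI here is phantom-space; real use requires template
  registration and the published sphere coordinates.
* The cleaning's CC p-value interpretation (effective degrees of freedom
  under spatial autocorrelation) is not implemented; the CC floor is used
  as a plain threshold.
* Motion estimation assumes small displacements (a few voxels); large
  abrupt motion would need a coarse search stage.
* The severity models are linear with additive noise; threshold effects
  and floor effects of real clinical scales are not modeled beyond simple
  clamping.
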