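---
title: "Native-space DMN connectivity: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Native-space DMN connectivity: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nativefc)
```

## The problem

Resting-state BOLD fMRI measures slow, spontaneous fluctuations of the
blood-oxygen-level-dependent signal. Regions of the default-mode network
(DMN) fluctuate coherently at rest, and the strength of that coherence —
functional connectivity, quantified as the Pearson correlation between
regional mean time series — changes with age. Conventional analyses warp
every brain to a common template (spatial normalization) before comparing
subjects; in aging cohorts the large morphological differences between
young and old brains make that warp unreliable, smearing a region's mask
over neighbouring tissue and diluting group contrasts. The alternative
implemented here extracts each subject's regional signals in their own
anatomical (native) space from subject-specific label volumes, so a
region's mask is correct by construction, and connectivity can be studied
separately per hemisphere rather than after left/right averaging.

`nativefc` implements that pipeline end to end, together with a synthetic
cohort generator that reproduces the statistical structure of a two-group
(young/elder) study design, so every stage is testable without access to
scanner data.

## The pipeline

Per subject, in order:

1. **Motion QC.** Framewise displacement from the six rigid-body motion
   parameters: `FD(i) = Σ|Δtrans| + r·Σ|Δrot|`, backward differences, with
   rotations converted to arc length on a sphere of radius `r = 50` mm
   (the standard convention for this summary; exposed as a parameter).
   An intensity-based companion, RMSD, is the root mean square across brain
   voxels of the volume-to-volume difference expressed as percent of each
   voxel's temporal mean, computed on motion-corrected, unfiltered data.
   The first volume has no predecessor: FD(1) = RMSD(1) = 0 by convention.
2. **Scrubbing.** Volumes with FD > 0.5 mm *or* RMSD > 0.3 % (strict
   inequalities) are flagged and each maximal flagged run is replaced by
   linear interpolation between the nearest clean volumes; runs touching
   the series boundary take the nearest clean volume, since two-sided
   interpolation is undefined there. Flags are computed once from the
   original QC series, a single-pass procedure.
3. **Band-pass filtering.** A 4th-order digital Butterworth band-pass
   (0.01–0.08 Hz at TR = 2 s) applied forward and backward (zero phase).
   Zero-phase application matters: a causal filter would add frequency-
   dependent phase shifts that bias pairwise correlations. The
   forward-backward pass squares the magnitude response, giving roughly
   24 dB attenuation one octave outside the band with under 1 dB of
   pass-band ripple. Edge transients are controlled with odd-reflection
   padding and steady-state initial conditions.
4. **Lag discard.** The first 5 volumes (about the filter order, i.e. "a
   few") are dropped from the signals and every aligned series after
   filtering.
5. **Nuisance residualization.** Each regional signal is replaced by its
   OLS residual against an intercept plus FD, RMSD, left and right
   white-matter signals, and the ventricular signal. The compartment
   signals are band-passed identically to the data first, so the
   regressors are frequency-matched; the intercept is always included
   (correlations are mean-invariant). Collinear or constant columns are
   dropped with a warning; residuals are exactly orthogonal to every
   retained column.
6. **Regional extraction.** Unweighted voxel means over each label, with
   nearest-neighbour label resampling under a *single composed* transform
   when alignment steps are involved — composing the matrices and
   resampling once preserves boundary voxels that chained resampling
   corrupts. Only gray-matter labels enter the 20 DMN columns; white
   matter and CSF compartments feed the nuisance set.
7. **Connectivity.** Pearson correlation for all 45 unordered pairs of the
   10 canonical regions (Hi, En, IP, IC, MOF, PHi, PoC, PCu, SF, SM)
   within each hemisphere — 90 Fisher-Z values per subject, no
   cross-hemisphere pairs — plus an interhemispheric-averaging variant
   (45 values) for comparison with the common practice. `|r|` within
   1e-12 of 1 errors rather than clipping, since it indicates duplicated
   signals upstream.
8. **Group statistics.** Pooled-variance two-sample t-tests per pair on
   the Fisher-Z scale (Welch available via `var_equal = FALSE`), flagged
   uncorrected at p < 0.05 and Bonferroni-corrected at p < 0.05/m with m
   the family size actually tested (90 hemisphere-resolved, 45 averaged);
   Cohen's d on the Z scale as effect size; a group × hemisphere
   interaction OLS on stacked per-hemisphere observations; and per-group
   cognition regressions `factor ~ z + age`.

## The synthetic cohort

`default_dmn_spec()` fixes the study conditions: 25 young and 26 elder
subjects, 285 volumes at TR 2 s (a 9.5-minute acquisition), pass band
0.01–0.08 Hz. Regional signals are drawn as multivariate Gaussian noise
with a group-specific 20×20 population correlation matrix, band-limited
with an exact spectral mask, and standardized. Because the same linear
filter is applied to every channel, the zero-lag correlation structure is
preserved exactly, and the brick-wall mask leaves essentially no power
outside the band — the generator's band edge is exact by design, while
the analysis pipeline uses the Butterworth filter above. Band-limiting
leaves roughly `2·(0.08−0.01)·TR·T ≈ 80` independent samples in a
285-volume run, which sets the subject-level dispersion of sample
correlations (SD of z about `1/√(T_eff−3) ≈ 0.11`).

The population matrices use a moderate positive background — 0.2 within
hemisphere, 0.1 between hemispheres — so the cross-correlogram is
non-trivial while the one designed group contrast dominates: the right
supramarginal–superior-frontal (SM–SF) pair is set to 0.5 in young and
0.04 in elder subjects, the left pair stays at background in both groups.
User-supplied matrices are repaired to the nearest positive semi-definite
correlation matrix by eigenvalue clipping at 1e-6 and rescaling to unit
diagonal, with a message whenever the repair changes anything.

Rendered subjects paint each region's signal into a 24×24×18-voxel label
grid (3 mm isotropic; block regions of 64 voxels, two per-hemisphere
white-matter and ventricle compartments) on a scanner-intensity baseline
of 1000, with:

* voxelwise white noise (SD 1 intensity unit),
* a shared low-frequency drift below 0.01 Hz (amplitude 2),
* a shared respiratory-band component above 0.1 Hz (amplitude 0.5),
* a regional-signal amplitude of 5 intensity units, i.e. 0.5 % BOLD
  fluctuation — a realistic resting-state magnitude, and one that keeps
  clean-frame RMSD safely under the 0.3 % scrubbing threshold while a 1 %
  global intensity spike clears it decisively,
* motion spikes: Bernoulli per volume (rate 0.02, sparing three frames at
  each end so interpolation always has clean neighbours), realized as
  alternating-sign 0.6 mm translation steps — FD then exceeds 0.5 mm
  exactly at the spike frames — paired with a 1 % global intensity
  perturbation of the spiked volume,
* smooth sinusoidal motion drift of 0.05 mm amplitude, far below the FD
  threshold.

Cognition is modelled as four factor scores (memory, speed of processing,
general fluid ability, vocabulary) generated linearly from each subject's
*realized* right SM–SF Fisher-Z: slope 1 with N(0, 0.5) noise for elder
memory and general fluid ability and for young speed of processing, zero
slope elsewhere — mirroring the qualitative pattern the design emulates.
Ages are drawn per group (young 25.4 ± 2.7, elder 65.1 ± 3.0 years).

What the generator does *not* emulate: anatomical realism (no cortical
geometry, no T1 contrast), EPI distortion, spatially correlated noise,
cardiac aliasing, and — importantly — between-subject variability in the
population correlations themselves. Subjects differ only through sampling
noise, so group effect sizes on the synthetic cohort are much larger than
in real cohorts (Cohen's d ≈ 4 for the designed contrast); passing tests
demonstrate the pipeline's statistical machinery, not realistic power.

## Numerical choices

* **Quartiles** in boxplot summaries use type-7 linear interpolation
  (R's default), whiskers at the most extreme values within 1.5 IQR.
* **Geometry** comparisons check affines within 1e-6; voxel indices are
  0-based in affine arithmetic.
* **Gaussian smoothing** (normalization emulation) truncates the kernel at
  4 SD and renormalizes at grid edges.
* **Seeds**: every random draw goes through a locally seeded RNG derived
  from the cohort seed and subject index, so identical (spec, seed) give
  bit-identical subjects and byte-identical run directories, and the
  caller's RNG state is never disturbed.
* **Degenerate inputs** error early with context: all-flagged series,
  empty masks or overlay maps, |r| at 1, constant connectivity in a
  cognition regression, bands at or above Nyquist.

## Open design points, and how they were resolved

* The rotation radius in FD and the rotation units of motion files are
  conventions, not physics: defaults 50 mm and radians, both
  configurable.
* RMSD needs a reference to define "percent signal": each voxel's
  temporal mean.
* How runs of consecutive contaminated volumes were to be interpolated is
  underdetermined: run-wise linear interpolation with nearest-neighbour
  fill at the series edges is the package's documented choice, and
  replacement is idempotent for fixed flags.
* The number of discarded lag volumes ("a few") defaults to 5,
  configurable.
* The group × hemisphere interaction uses plain OLS on stacked
  observations with age as the group indicator, ignoring the within-
  subject pairing of hemispheres — the literal model description; a
  mixed-model alternative is out of scope.
* Interhemispheric averaging: for unit-variance signals the averaged pair
  correlation is `(rl + rr + 2c) / (2(1 + h))` with homologous coupling
  `h` and non-homologous cross-correlation `c`. With the default
  `h = c = 0.1`, weak pairs inflate (0.2 → 3/11) while the lateralized
  SM–SF pair dilutes (right 0.5 → 0.41) — the "mixed effect". For fully
  independent hemispheres the expression reduces to the original
  correlation: inflation requires cross-hemisphere coupling, which real
  brains (and the default spec) have.

## Problem sizes used in the test suite

Simulation-based checks run at sizes chosen to keep Monte-Carlo error
well inside the asserted tolerances: convergence checks at T = 4096–16384
with 60 replicates; survivor-uniqueness across 100 reseeded cohorts at
the full T = 285; null calibration across 500 cohorts at T = 128 (which
preserves subject-level z dispersion while keeping the study cheap);
scrubbing-efficacy and containment properties over 20 replicates.

## A minimal run

```{r example, eval = FALSE}
spec <- default_dmn_spec(seed = 1)
records <- cohort_records(spec)           # 51 subjects, signal-level
gs <- group_compare(records, family = "both")
subset(as.data.frame(gs), sig_bonferroni,
       select = c(pair, hemisphere, mean_r_young, mean_r_elder, p_value))

# full volume-rendered run with outputs on disk
out <- run_pipeline(run_config(default_dmn_spec(seed = 1),
                               families = c("left", "right", "avg"),
                               render_volumes = TRUE,
                               out_dir = "run1"))
```
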