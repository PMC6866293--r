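---
title: "Modelling vascular reactivity from block-design BOLD fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling vascular reactivity from block-design BOLD fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vasoreact)
```

## The problem

When the visual cortex is driven by a strong periodic stimulus — here an
8 Hz flashing checkerboard shown for 20 s followed by 28 s of rest, seven
times — the BOLD signal in responsive voxels rises, plateaus, and decays
back to baseline each block. The *shape* of that stimulus-locked response
is a functional readout of cortical vascular reactivity: how quickly the
vasculature ramps up (time-to-peak), how long it takes to relax after
stimulus offset (time-to-baseline), and how strongly it responds
(amplitude, in percent BOLD change). These three numbers summarise each
subject and can then be compared between clinical groups — for example
healthy controls versus premanifest and manifest Huntington's disease gene
carriers — alongside structural measures (regional cortical thickness) and
visual cognitive performance.

`vasoreact` implements that subject-level extraction chain and the cohort
statistics around it, plus a seeded synthetic-data generator so that every
stage can be validated against planted ground truth.

## The subject-level pipeline

For one 4D BOLD run the chain is:

1. **GLM activation map.** Each voxel's timeseries is regressed on a task
   regressor (the stimulus boxcar convolved with a canonical double-gamma
   haemodynamic response function) plus an intercept and, optionally,
   discrete-cosine drift columns. The task-coefficient t statistic
   (df = n − rank) is mapped to a standard normal quantile, preserving
   sign, to give the Z-statistic map.
2. **Functional ROI.** The top 20% most activated in-mask voxels
   (`k = ceiling(fraction * N)`) form a binary mask. Ties at the cut are
   broken by ascending voxel index so the selection is deterministic.
3. **ROI-mean timeseries**, averaged unweighted over ROI voxels.
4. **Block segmentation.** The series is cut into 48 s blocks of 16
   samples (20 s stimulus + 28 s rest at TR = 3 s).
5. **Percent change.** Every sample becomes `100 * (x - m) / m`, with `m`
   the grand mean over *all* blocks, computed once, before any rejection.
6. **Artifact rejection.** A block whose maximum absolute percent change
   exceeds 3% is discarded; a block peaking exactly at 3.0% is retained
   (strict inequality). The normalisation mean is *not* recomputed after
   rejection — discarding a spike block therefore still leaves its imprint
   on the denominator, a coupling that is deliberate and tested.
7. **Averaging and trapezoid fitting** over retained blocks only.

```{r pipeline, eval = FALSE}
p <- stimulus_paradigm()              # 7 x (20 s on + 28 s off), TR 3 s
run <- read_bold_volume("run.nii.gz", "brain_mask.nii.gz")
report <- fit_subject(run, p)
tidy(report)
autoplot(report)
```

## The trapezoid model and its fitter

Within one block the response is modelled as a piecewise-linear trapezoid
with four free parameters: baseline `b`, amplitude `a`, plateau onset
`t_peak`, and baseline-return time `t_return`. The signal rises linearly
from `b` at block onset (t = 0) to `b + a` at `t_peak`, holds, then falls
linearly from stimulus offset (t = 20 s, fixed, not fitted) to regain `b`
at `t_return`. The reported metrics are `time_to_peak = t_peak`,
`time_to_baseline = t_return - 20`, and `amplitude = a`.

Three modelling conventions are deliberate choices where the measurement
definitions leave freedom:

- **Sample timing**: sample k of a block is at `t = k * TR` with the first
  sample at block onset, because response timing is defined from the
  beginning of the block at t = 0.
- **Rise anchored at t = 0**: the response is assumed to depart baseline
  at block onset. Freeing the rise onset would add a fifth parameter to a
  16-sample fit and costs identifiability for no measurable gain.
- **Descent anchored at stimulus offset**: time-to-baseline is defined
  from the end of the stimulus, so the descending edge starts there.

**Fitting.** For fixed breakpoints the model is linear in `(b, a)`, so the
fitter profiles: on a regular breakpoint grid (default 0.25 s, well below
TR) it solves the two-parameter least squares in closed form for every
`(t_peak, t_return)` pair, fully vectorised. The profiled SSE surface is
piecewise smooth with kinks wherever a breakpoint crosses a sample time,
so a single local descent from the grid optimum can settle in the wrong
cell; instead the fitter re-profiles a fine local grid (resolution / 25)
around the 100 best coarse candidates and then polishes the winner with
box-constrained L-BFGS-B. The returned SSE is never above the SSE at any
grid point, and on random noisy inputs it matches an exhaustive 0.05 s
grid oracle to machine precision (tested at 1e-9 relative slack).

**Degenerate inputs.** A perfectly flat series is fitted with amplitude 0
and `t_peak` at the smallest grid value (all breakpoints fit equally well;
the tie-break is documented and tested). Inputs with fewer than 6 samples
are refused as underdetermined. Because a flat trapezoid is in the model
family, the fitted SSE never exceeds the total sum of squares of the
de-meaned input.

**GLM degeneracies.** A voxel with numerically zero residual variance
cannot support a t statistic: if its task beta is materially nonzero the Z
value is set to a finite sentinel (40, with a warning); if the beta is
also zero (a constant voxel) Z is 0. Infinities never enter the Z map.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `n_blocks`, `stim_duration`, `rest_duration`, `tr` | 7, 20, 28, 3 | –, s, s, s | the study paradigm; block length must be a multiple of TR |
| ROI `fraction` | 0.2 | – | top 20% most activated voxels |
| rejection `threshold` | 3 | % change | physiological plausibility bound for a block peak |
| `grid_resolution` | 0.25 | s | breakpoint grid; ≪ TR so grid error is negligible against noise |
| `refine` | TRUE | – | zoom + continuous polish of the grid optimum |
| GLM `highpass` | off | s | drift columns for a 48 s cutoff; synthetic runs carry no drift by default |
| `z_sentinel` | 40 | – | finite stand-in for a perfect-fit Z |

The rejection statistic is the **maximum absolute** percent change within
the block. "Greater than 3%" does not pin down the statistic (max, mean,
or range); the maximum is the natural spike detector and is the
implemented rule. The run length is taken from the paradigm (7 × 48 s =
336 s = 112 volumes). Acquisition protocols sometimes report a slightly
shorter scan duration because initial dummy volumes are discarded at the
scanner; `fit_subject(n_discard_initial_volumes = )` and the generator's
`n_extra_volumes` exist so either convention can be reproduced rather
than guessed.

## The synthetic-data generator

`simulate_subject_run()` plants a trapezoid (default: amplitude 1% of a
baseline level of 1000, `t_peak` 6 s, `t_return` 28 s — physiologically
plausible values chosen once, well inside the identifiable range, and not
claimed to be any study's observed values) in an active voxel subset,
adds independent Gaussian noise per voxel-timepoint and a single slow
cosine drift per run (the component a 48 s high-pass would remove). The
default active fraction (0.2) matches the ROI fraction so that a
noiseless analysis selects exactly the planted set. All generators are
pure functions of (spec, seed): the same seed reproduces runs
bit-for-bit, and the caller's RNG state is restored afterwards.

`simulate_cohort()` produces the tabular side: three groups with sizes
18/21/20; ages ~46/37/52 ± 9–11 y; education ~17 y (truncated normal,
≥ 8); CAG repeats ~42/43 for gene carriers only; per-region cortical
thickness for eight visual regions drawn from group-specific means and
SDs, with a shared subject-level factor (loading √0.5) correlating a
subject's deviations across regions; and cognitive raw scores driven by a
latent ability `group_shift + slope * (thickness_ref − control mean) +
age_slope * (age − 45) + residual`, mapped to each test's raw scale with
timed tests reversed. Gender is Bernoulli with group-specific male
proportions.

One identity is worth stating because it is not obvious: compound
Z-scores are standardized against the control group, so when cognition is
tightly coupled to thickness, one compound-Z unit corresponds to one
control-group SD of thickness — the mm-per-Z association coefficient then
equals that SD regardless of the latent slope's magnitude. The
parameter-recovery test plants a 0.13 mm-per-Z association through that
SD.

**What the generator does not emulate**: head motion, temporally
autocorrelated (AR) noise, spatially smooth noise, physiological
confounds, registration error, or realistic scanner drift spectra.
Passing recovery tests therefore demonstrate the correctness of the
algorithmic chain, not robustness to real-data artifacts; an AR(1) noise
option is the natural first extension.

## Cohort statistics

- **Compound Z-scores** (`compound_zscore()`): per test,
  `Z = direction * (x − mean_ref)/sd_ref` with the control group as
  reference (configurable to whole-sample standardization); timed tests
  are sign-flipped so higher always means better; a domain score is the
  mean of its tests' Z. The reference choice is a genuine open point —
  control-referenced standardization makes control means exactly 0, which
  published cohort tables only approximately show; both conventions are
  supported and the control reference is the default.
- **ANCOVA contrasts** (`ancova_contrast()`): `outcome ~ group +
  covariates` with controls as reference; each non-reference coefficient
  is the adjusted group difference with its t-based 95% CI. Covariate
  sets are arguments, not hard-coded, because different analyses in a
  study may adjust for different sets (age + gender, or age + gender +
  education).
- **Association regressions** (`association_regression()`): thickness on
  a domain Z-score in gene carriers only, covariates entered in one
  block; partial eta squared is computed from the drop-one (Type-III) sum
  of squares, `SS_pred / (SS_pred + SS_res)`, which for a 1-df predictor
  equals the squared partial correlation `t² / (t² + df)` — both
  identities are tested against an independent Type-III oracle.
- **Multiplicity**: `bonferroni_alpha(alpha, m) = alpha / m`; the family
  size `m` is always explicit at the call site (0.05/12 ≈ 0.0042, which
  prints as .004).

## Validation design and problem sizes

The suite validates each stage against independent oracles: a scalar
piecewise implementation of the trapezoid; normal-equation OLS for the
GLM; brute-force sorts for the ROI (exhaustively for all mask sizes up to
50); direct recomputation for percent change and averaging; and the
exhaustive fine-grid fitter oracle. End-to-end checks use noiseless
planted subjects (recovery to within half the fit grid resolution), a
pure-noise GLM calibration on ~10,600 voxels (|Z| > 1.96 rate 5% ± 1%),
and CI coverage of planted group differences and regression slopes over
2,000 simulated cohorts at n = 20/group (95% ± 2%). These sizes were
chosen so the whole suite runs in a few minutes on one CPU while keeping
Monte-Carlo error well inside each tolerance.

The coverage experiment draws all three groups with a **common** residual
SD (0.15 mm). That is intentional: the pooled-variance ANCOVA CI is
calibrated under homoscedastic errors, which is the property being
verified. With group-specific SDs as unequal as 0.10 vs 0.19 the same
interval under-covers (~92–94% at n = 20/group) — the classic
Behrens–Fisher effect. This is a known limitation of pooled-variance
contrasts at small unequal-variance samples, not an implementation
defect; heteroscedasticity-robust intervals are a possible extension.

## Known limitations

- No prewhitening or temporal-derivative regressor in the GLM; adequate
  for white synthetic noise, an approximation for real data.
- The trapezoid's rise is anchored at block onset; a delayed-onset
  response would bias time-to-peak upward.
- Percent-change normalisation keeps the pre-rejection grand mean by
  design; a gross artifact block therefore shifts all retained blocks'
  percent values slightly.
- The cohort generator draws thickness and cognition from Gaussian
  models; skewed clinical scales (e.g. capped functional scores) are not
  emulated.
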