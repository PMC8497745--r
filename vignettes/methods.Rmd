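---
title: "Methods and conventions of the gaitwork pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and conventions of the gaitwork pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitwork)
```

This vignette documents the modeling decisions, numerical conventions and
known limitations of the pipeline. It is the reference for *why* the code
does what it does; the function reference documents *what* each function
does.

## The problem

Fatigue changes how runners load their joints. The pipeline quantifies this
with three linked analyses on paired (pre/post-fatigue) stance-phase data:

1. **Joint energetics** — sagittal joint power `P = M * omega` (moment times
   angular velocity, mass-normalized) and its trapezoidal time integrals over
   stance: positive work (generation), negative work (absorption), and total
   work (their sum).
2. **Partial least squares regression (PLSR)** — relating a small set of
   discrete kinematic predictors (ankle/knee initial-contact angles and
   ranges of motion) to the six joint-work responses, with leave-one-out
   cross-validity selection of the number of latent components.
3. **Paired statistics** — per-variable paired t-tests and a whole-curve
   permutation test over the 101 stance nodes.

Because no participant-level dataset ships with the package, analyses run on
a synthetic cohort calibrated to published group summaries (means and SDs of
joint angles, moments, powers and works in each condition). The generator is
itself part of the deliverable: it provides ground truth against which every
downstream stage is validated.

## Synthetic cohort model

### Per-subject targets

Each subject draws a vector of discrete targets (initial-contact angles,
angle extrema, peak moments, positive works, stance duration, body mass) per
condition from the calibrated population table
(`default_population_table()`). Pre and post values of the same variable are
sampled as a bivariate Gaussian pair with correlation `rho` (default 0.7),
reflecting that paired designs owe their power to within-subject
correlation. The published summaries do not report this correlation, so 0.7
is a *chosen* parameter: large enough to give the paired tests realistic
power, small enough to keep between-condition scatter. Sign-constrained
variables (e.g. positive works must be non-negative) are redrawn per
variable until the constraint holds, which truncates the implied Gaussian.
For most variables the truncation is negligible; for the small hip positive
work (mean 0.19, SD 0.33 J/kg) it biases the realized mean upward by about
0.011 J/kg. This is documented rather than corrected, and Monte-Carlo
consistency tests only assert unbiasedness for variables whose construction
is truncation-free.

Two further quantities are not published and had to be chosen: the stance
duration (0.24 s +/- 0.02, typical of recreational running) and the knee
minimum angle (means 16.90/16.76, SD 3.50), which the source tables omit but
the waveform templates require.

### Waveform templates

Angles are piecewise-cosine curves through control points (initial contact,
an interior extremum, toe-off), with zero slope at the nodes and the
interior node snapped to the sampling grid. Snapping makes the *sampled*
extrema equal the control values exactly, so ground truth is exact by
construction: maximum, minimum and ROM (= max - min over the control points,
including initial contact) round-trip through the extraction stage to
machine precision when filtering is disabled.

Moments are sums of raised-cosine bumps with the calibrated peak values
(e.g. a dorsiflexor bump early and a plantarflexor bump through mid/late
stance for the ankle). The positive-work target is then enforced in closed
form: scaling the moment over the positive-power runs by a gain `c` changes
the achieved positive work *linearly* in `c` (the angle, and hence the
angular velocity, is fixed), so the required gain is solved exactly rather
than iterated. The gain is blended to 1 at run edges with a cosine taper to
keep the moment continuous; if a tiny target would force a negative core
gain, the taper is shrunk (ultimately to a hard uniform rescale), which is
always feasible for non-negative targets.

Vertical GRF is a half-sine from 30 N at contact to 2.5 body weights at
midstance and back, padded with 50 ms of zeros, so the 30 N threshold
recovers the designed stance window exactly.

### Calibrated versus emergent quantities

Only initial-contact angles, angle extrema (hence ROM), peak moments,
positive works, stance duration and mass are *calibrated* (enforced per
subject). Negative/total works, peak powers and the post-filtering values
are *emergent* from the templates; they come out in realistic ranges but are
not forced to the published summaries. Acceptance-style checks therefore
target calibrated quantities only.

### Determinism

All randomness flows from the population seed through a per-subject seed
(`(seed * 1000003 + i * 7919) mod (2^31 - 1)`), evaluated inside
`with_local_seed()` so the caller's RNG stream is untouched. Cohorts are
bit-reproducible for a given spec.

## Signal conditioning conventions

- **Zero-phase Butterworth**: the conventional biomechanics reading of an
  "n-th order low-pass" is a forward-backward pass of a half-order filter.
  Edges are padded by odd (point-symmetric) reflection and each pass starts
  from the filter's steady state for the edge value, so constants pass
  through exactly and startup transients are suppressed.
- **Stance detection before filtering**: the 30 N threshold is applied to
  the raw GRF (the synthetic GRF is clean by construction and the filter
  would smear the exact threshold crossings). The stance window is the
  *longest* contiguous supra-threshold run; ties are an error, not a guess.
- **Indices are 1-based** (R convention) throughout; durations use
  `(end - start) / rate`.
- **Time normalization** linearly interpolates the stance segment onto 101
  points (percent stance 0 to 100), preserving endpoints exactly.
- Kinematics and kinetics are sampled at different rates (200 Hz motion
  capture, 1000 Hz force platform); the stance window found on the GRF grid
  is mapped to the kinematic grid by nearest-sample matching.

## PLSR conventions

The NIPALS PLS2 implementation is from scratch (that primitive is the point
of the module); `mixOmics::pls` is used in the test suite only, as an
independent oracle.

- Both `X` and `Y` are globally standardized (z-scored, `N - 1`
  denominator) once; leave-one-out refits during PRESS computation reuse the
  global standardization rather than re-centering per fold. This is the
  simplest convention, matches the usual presentation of
  `Q2 = 1 - PRESS(H)/SS(H-1)` with `SS(0)` the total standardized sum of
  squares, and is applied consistently in code, oracles and tests.
- **Component selection**: components are accepted while
  `Q2_H >= 0.0975` (`= 1 - 0.95^2`); selection stops at the first failure
  and keeps at least one component. Note the rule is *greedy*, not global:
  on a training subset it can legitimately stop before the true rank.
- **Coefficients**: `B = W (P'W)^{-1} Q'` on the standardized scale;
  `coef()` converts to original-unit slopes and an intercept. With all
  components retained, predictions coincide with ordinary least squares,
  which the tests assert to 1e-8.
- **Accuracy metric**: the train/test evaluation reports
  `100 * (1 - RMSE / range)` per response, averaged over responses, where
  `range` is the *training* response range. This normalized-RMSE accuracy is
  a project definition (chosen to make 100% mean exact prediction), not a
  standard statistic; compare values only within this package.
- The 80/20 split is seeded and subject-agnostic (rows are trials).

## Perturbation sensitivity

The grid varies one predictor at a time over
`X_min + k * X_dif`, `k in {-0.1, 0, 0.1, ..., 1, 2}`, holding the others
at their averages, and tabulates the model predictions. Two grid modes
exist because the published boundary rows are inconsistent with the
formula: `"formula"` (default) uses the formula everywhere; `
"printed-compat"` reproduces the published boundary rows (`0.9 * X_min` and
`2 * X_max`) while interior rows are identical in both modes. The direction
summary records the sign of the top-minus-bottom prediction per
predictor/response pair; for a linear model it is invariant to the level
choice.

## Paired statistics

Discrete variables use the paired t-test on within-subject differences,
with a Shapiro-Wilk normality p-value reported alongside (not gating). No
multiplicity correction is applied across variables, matching common
practice in this literature; interpret the table accordingly.

The whole-curve test is a permutation stand-in for one-dimensional
statistical parametric mapping: the pointwise paired-t trajectory over the
101 nodes is compared with the permutation distribution of the *maximum*
absolute t under random sign flips of the subject difference curves. Sign
flips are exact under exchangeability of the condition labels within
subject; including the identity flip keeps the test valid at level alpha.
Supra-threshold clusters are maximal runs above the family-wise threshold.
This controls the family-wise error without random-field assumptions; the
trade-off is a discrete threshold resolution of `1 / n_perm`.

## Problem sizes and costs

The intended scale is desk-sized: cohorts of roughly 10-100 subjects
(2 trials each), 101-node curves, 4 predictors and 6 responses. The full
pipeline (`run_all()`) on the default 50-subject cohort runs in seconds on
one CPU; the dominant costs are trial synthesis and the nine permutation
waveform tests.

## Limitations

- Waveform shapes are stylized (cosine segments and bumps); they calibrate
  discrete summaries, not the fine structure of real gait curves, so
  waveform-level statistics on synthetic cohorts describe the generator,
  not human running.
- The pre/post correlation, stance duration, knee minimum angle and GRF
  amplitude are chosen, not published; sensitivity of downstream results to
  these choices has not been mapped.
- The hip positive-work mean carries the small truncation bias noted above.
- PLSR evaluation splits by trial, not by subject; with both conditions of
  a subject available, train and test sets are not strictly independent at
  the subject level.
- The greedy Q-squared rule can under-select components on small training
  subsets; this is a property of the rule, faithfully implemented.
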