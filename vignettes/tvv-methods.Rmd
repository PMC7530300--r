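---
title: "TVV effect profiles: models, conventions and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TVV effect profiles: models, conventions and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tvv)
```

## The measurement model

During ventricular repolarization the body-surface heart vector traces a
3-D loop between the J point (end of depolarization) and the end of the T
wave. The speed of that motion — the T vector velocity — summarises the
temporal progression of the myocardial action-potential distribution. We
quantify it by trajectory time quantiles: `Tr(p)` is the time in
milliseconds at which the cumulative chord length of the loop first
reaches `p` percent of its total, `p = 1..100`. Drugs that block inward
(late Na+, L-type Ca2+) currents accelerate early repolarization
(`ddTr(p)c < 0` at small p); hERG/IKr block delays late repolarization
(`ddTr(p)c > 0` at large p). The percentage `p_zero` where a drug's effect
profile turns from negative to positive measures the balance of the two,
and a threshold of 43% separates hERG-predominant from balanced
multichannel blockers.

### Assumptions

* The trajectory is measured on the filtered signal at the native 500 Hz
  sampling rate; arc length is the chord-length sum, with no spline
  re-parameterization or re-sampling of the loop.
* The trajectory starts at J + 20 ms (excludes late depolarization); the
  20 ms offset is a constant and cancels in every placebo-corrected
  change-from-baseline quantity.
* Tr(p) is averaged over normal beats with acceptable annotations within
  an ECG; annotations are inputs, not estimated here.
* Heart-rate dependence is a per-quantile power law; "drug-free" data for
  exponent estimation are all placebo-period ECGs plus all pre-dose ECGs
  of active periods.
* Drug effects are linear in plasma concentration (designs A and C); an
  intercept profile (the model prediction at zero concentration) that is
  clearly non-zero flags a violation.

## Parameters that matter

| Parameter | Unit | Default | Why |
|---|---|---|---|
| Low-pass cutoff | Hz | 36 | Removes muscle noise while preserving the T-loop morphology; applied forward+backward (zero phase), 4 poles |
| PQ window | ms before Q | [−40, −10] | Isoelectric PR segment; robust when the P-offset annotation is absent |
| Trajectory start | ms after J | 20 | Excludes late depolarization effects |
| p grid | % | integers 1..100 | Fixed evaluation grid of all profiles |
| Spline breakpoints | count | A 8, B 16, C 12 | Smoothing/complexity trade-off per design; counts include both boundaries p = 1 and p = 100, so the basis dimension is `(k − 2) + 4` |
| Bootstrap N | replicates | 200 (desk) / 4000, 4000, 1000 (full) | Two-sided 90% band needs stable 5/95% quantiles |
| p_zero threshold | % | 43 | Classification boundary between hERG-predominant and multichannel profiles |

## Numerical conventions

* **Quantile interpolation.** `Tr(p)` uses the first sample interval in
  which the cumulative length reaches the target, with linear
  interpolation inside it; flat (zero-length) segments are skipped in
  favour of the earliest crossing time. `Tr(100)` is exactly the sampled
  trajectory duration.
* **Baseline spline extrapolation.** The isoelectric baseline is a natural
  cubic spline through one node per beat (median PQ amplitude at the
  window midpoint) and uses the natural spline's *linear* extrapolation
  beyond the first/last node. Constant extrapolation — an obvious
  alternative — leaks an edge residual into the outermost PQ windows on a
  second pass and thereby breaks idempotence for drifting signals; linear
  extrapolation is exact (and exactly idempotent) for constant and linear
  drifts.
* **Bessel design.** No filter-design library is assumed: the 4-pole
  low-pass Bessel filter is derived from the roots of the degree-4
  reversed Bessel polynomial, magnitude-normalised to −3 dB at the cutoff
  (found by root bracketing), bilinear-transformed with frequency
  prewarping, and applied forward–backward with odd-reflection padding.
  DC gain is exactly 1 per pass.
* **Mixed-model fallbacks.** All pointwise fits use REML with correlated
  random effects. A singular fit falls back to a random intercept, then to
  OLS; a fit whose residual variance collapses to (numerical) zero is
  treated as degenerate and also falls back — lme4's optimizer can
  otherwise stop at a non-converged point on such data (e.g. small
  perfectly balanced inputs, where the correct answer is the grand mean).
  The fallback actually used is recorded on every fit object.
* **p_zero tie-break.** Exact zeros count as non-negative. A profile with
  mixed signs but no negative-to-positive transition (positive early,
  negative at the end) is assigned 100, like the all-negative case,
  because it ends in acceleration.
* **Bootstrap reproducibility.** Replicates consume pre-assigned seed
  substreams drawn once from the master seed, so results are independent
  of execution order; empirical quantiles use linear interpolation
  (type 7).

## The functional model and its inference

Stacking the records over p and expanding every scalar covariate into
`covariate × B_j(p)` columns turns the 100 pointwise models into one linear
mixed model whose coefficients are spline coefficient vectors. Subject
random effects are spline-expanded the same way with a **diagonal**
covariance across spline coefficients — the unstructured alternative makes
the largest (two-drug, 12-breakpoint) configuration unfittable at desk
scale. Residuals are treated as independent and homoscedastic across p
within an ECG. Both simplifications mean the single fit's standard errors
are not trustworthy, so the package never reports them: **all interval
estimates come from the two-step bootstrap** (subjects resampled with
replacement and relabelled, then replicate ECGs resampled within each
subject × timepoint cell before replicate averaging).

Within a bootstrap replicate the default fitting engine is ordinary least
squares on the fixed-effect columns (`method = "ols"`). Subject-level
variation is exactly what the primary resampling step propagates, OLS fixed
effects are consistent under the generating models, and this is what makes
paper-scale replicate counts feasible on one CPU (a REML refit per
replicate is available with `method = "reml"`). The structural parameter
count reported on a fit (`n_params`) counts fixed coefficients, one
variance per diagonal random-effect column and the residual variance; the
two-drug parallel-design configuration with 12 breakpoints and 21 nominal
timepoints comes out at 407, matching the complexity reported for such
models.

Two conventions were genuinely open:

* *Breakpoint counting.* "k knots" is read as k equidistant breakpoints
  including both boundaries (`m = k + 2` basis functions). The alternative
  (k interior knots) remains available by passing a different `n_knots`.
  The chosen convention reproduces the published ~406-parameter count of
  the most complex configuration; the alternative does not.
* *Secondary bootstrap unit.* Replicate ECGs are resampled per
  subject × timepoint cell (not jointly across a subject's whole day).
  This is the finest "ECG" unit in triplicate designs; resampling jointly
  would preserve within-day correlation that the models do not use.

## The synthetic world

The generator exists at two levels.

**Quantile level** (`simulate_drugfree_quantiles`,
`simulate_study_quantiles`) draws Tr(p) tables directly from the
generating equations: a base duration curve
`q(p) = 300 (p/100)^0.585` ms (chosen so that half the trajectory length
takes two-thirds of the duration — 200 vs 300 ms — as observed under
placebo), exponents `alpha(p)` ramping linearly from 1.06 (p ≤ 6) to 0.44
(p = 100) (the shape and printed extremes of the published exponent
curve), subject random effects on log-intercept (SD 0.05) and log-RR slope
(SD 0.1), residual SD 0.02 on the log scale, log RR SD 0.12 (resting RR
roughly 0.78–1.28 s), one-compartment PK (ka 1.5/h, ke 0.35/h, 25%
between-subject CV on Cmax), a subject effect-slope SD of 0.15, an
ECG-level log-duration SD of 0.015 and 1 ms per-p additive noise. Where no
value was externally stated these were fixed once as typical of
thorough-QT-style resting ECG studies and not revisited.

**Waveform level** (`simulate_beat`, `simulate_ecg`, `simulate_study`)
builds a 3-D dipole — Gaussian wavelets for P/QRS, an asymmetric rotating
T loop — and imposes the time course explicitly: the time to reach arc
fraction p/100 equals `q(p) rr^alpha(p) + g(p) C / C_ref`. Drug effects
enter as this time-warp, never as additive waveform change, which makes
the ground-truth `ddTr(p)c` equal `g(p) C/C_ref` *by construction*;
default annotation jitter is 2 ms (truncated to preserve ordering) and
amplitude noise 4 µV. Because the effect is a time-advance, an effect
profile cannot demand more advance at small p than the undrugged
trajectory needs to get there; `piecewise_effect` therefore tapers its
flat acceleration in linearly below p = 10, and `simulate_beat` rejects
any warp that is non-monotone.

What the synthetic world does **not** emulate: P-wave or conduction
pathology, ectopy, T-wave alternans or any beat-to-beat variability,
respiration/electrode artifacts, annotation error correlated with drug or
heart rate, and PK hysteresis. A green test therefore establishes that the
pipeline recovers known effects under idealised morphology and honest
noise — not that it is robust to adjudication problems of real clinical
recordings, which are handled upstream of this package.

## File formats

WFDB support is a documented subset (format 16, 16-bit little-endian,
gain 1000 adu/mV, plain-text annotation sidecar in milliseconds); HL7 aECG
support is a subset of the aECG XML structure (per-lead digit sequences in
µV with scale/origin, beat annotations in ms). Round-trip fidelity of the
package's own writer/reader pairs is tested; both quantize amplitudes at
1 µV. All loaders normalise records to 500 Hz by linear resampling with
index rescaling.

## Known limitations

* Sensitivity/specificity of the p_zero threshold pools bootstrap samples
  across the conditions of a class (per-drug averaging would weight drugs
  equally; pooling weights samples equally).
* The functional model's residual independence across p is a working
  assumption; within-ECG correlation across p would widen honest bands
  somewhat. The bootstrap partially absorbs this because whole subjects
  (with their full p-profiles) are resampled.
* No claim is made that a lower p_zero means a higher proarrhythmic risk —
  the threshold separates two mechanistic classes on the drugs studied.
* Study C's treatment effect and concentration slope are weakly separated
  in small parallel arms; expect wider intercept bands there.
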