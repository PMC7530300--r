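# tvv — Continuous T Vector Velocity Effect Profiles from 12-Lead ECGs

`tvv` quantifies drug effects on ventricular repolarization from annotated
10-second resting 12-lead ECGs. It is aimed at cardiac-safety
pharmacologists and ECG methodologists who want to look beyond QTc
prolongation: the package measures *where along the repolarization process*
a drug accelerates or delays the heart vector, which separates predominant
hERG/IKr potassium-channel blockers (higher torsade-de-pointes risk) from
balanced multichannel blockers (low risk despite QT prolongation).

## The method

1. **T vector trajectory.** The eight independent leads (I, II, V1–V6) are
   baseline-corrected (median PQ amplitude, natural cubic spline between
   beats), low-pass filtered (bidirectional 4-pole Bessel, 36 Hz) and mapped
   through the inverse Dower transformation to the 3-D heart vector. For
   each normal beat the trajectory runs from J-point + 20 ms to T end.
2. **Trajectory time quantiles.** `Tr(p)` is the time (ms) needed to cover
   `p` percent of the trajectory's total arc length, `p = 1..100`; per-ECG
   values are beat averages. `Tr(100)` is the (J–Tend-like) trajectory
   duration.
3. **Heart-rate correction.** On drug-free data each quantile follows a
   power law `Tr(p) ~ beta_p RR^alpha_p`; `alpha_p` is estimated per p by a
   linear mixed model `log Tr(p) = log beta_p + alpha_p log RR + eps` with
   correlated random intercept/slope per subject, and
   `Tr(p)c = Tr(p) / RR^alpha_p`.
4. **Effect models.** Placebo-corrected changes from baseline `ddTr(p)c`
   are modelled per study design: exposure–response with random
   intercept/slope (crossover, design A), phase means (multiple daily
   doses, design B), or a covariate-adjusted parallel-design model with
   treatment indicator, per-drug concentration slopes, nominal-timepoint
   factor and centered baseline (design C).
5. **Functional model.** The 100 pointwise models are joined into one
   mixed model whose p-dependent coefficients are cubic B-splines
   (8/16/12 equidistant breakpoints on [1, 100] for designs A/B/C),
   giving a continuous effect profile `ddTr(p)c`.
6. **Bootstrap and p_zero.** A two-step nonparametric bootstrap (subjects,
   then replicate ECGs within subject × timepoint) yields the median
   profile and its 90% band. `p_zero` — the largest p where the profile
   turns from negative (acceleration) to positive (delay) — classifies a
   drug as hERG-predominant when `p_zero < 43`.

A full synthetic-study generator (dipole-model waveforms with exact
ground-truth annotations, one-compartment pharmacokinetics,
concentration-proportional p-dependent repolarization time-warps) makes
every stage testable without clinical data.

## Worked example

Simulate a reduced 12-subject crossover study of a quinidine-like
multichannel blocker (designed effect: sign change at p = 40, +50 ms at
p = 100 at the reference concentration 1754 ng/mL), then run the full
statistical pipeline:

```r
library(tvv)

sim <- simulate_study_quantiles(
  "A", n_subjects = 12, timepoints = c(0, 1, 2, 4, 8), n_replicates = 3,
  drugs = list(quinidine = list(cmax = 1754, g = transition_effect(40, 50))),
  seed = 5)

alpha_hat <- fit_alpha_profile(sim$table[sim$table$treatment == "placebo", ])
alpha_hat
#> <alpha_profile> p in [1, 100]; alpha range [0.4177, 1.0679]
#>   fitted on: 180 rows, 12 subjects, RR [0.851, 1.314] s
#>   fallbacks: 16 of 100 fits

tabc <- apply_hr_correction(sim$table, alpha_hat)
bs <- bootstrap_profiles(tabc, "A", sim$pk, conc = 1754, N = 200, seed = 1)
bs
#> <bootstrap_result> 200 replicates (0 failed), seed 1
#>   ddTr(100)c median 52.1 [46.5, 57.2] ms; p_zero median 37%
```

Reading: at the reference concentration the drug delays the end of
repolarization by ~52 ms (designed: 50), the 90% bootstrap band is
[46.5, 57.2] ms, and the acceleration-to-delay transition is recovered at
p ≈ 37 (designed: 40) — correctly below the 43% classification threshold
only for drugs whose early acceleration is strong relative to the terminal
delay. The estimated exponent profile declines from ~1.07 at small p to
~0.42 at p = 100, the imposed ramp.

Waveform-level simulation, file I/O (WFDB subset, HL7 aECG subset, CSV) and
extraction are exercised the same way; see `?simulate_study`,
`?load_annotated_ecg`, `?quantile_table`, and the command-line front end
`inst/cli/tvv.R` (subcommands `simulate`, `extract`, `alpha`, `correct`,
`profile`, `classify`).

## Vignette

`vignettes/tvv-methods.Rmd` documents the model assumptions, the synthetic
world and its limitations, numerical conventions (tie-breaks, fallbacks,
tolerances) and the design decisions taken where the method description
left room.
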