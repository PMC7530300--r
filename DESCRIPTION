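Package: tvv
Title: Continuous T Vector Velocity Effect Profiles from 12-Lead ECGs
Version: 0.1.0
Authors@R:
    person("TVV", "Maintainers", email = "tvv@example.org", role = c("aut", "cre"))
Description: Quantifies drug effects on ventricular repolarization from
    annotated 12-lead resting ECGs using T vector velocity (TVV) analysis.
    Reconstructs the 3-D T vector via the inverse Dower transformation,
    measures trajectory time quantiles Tr(p) (the time to traverse p percent
    of the T vector trajectory arc length), applies per-quantile power-law
    heart-rate correction, fits pointwise and spline-based functional
    mixed-effects exposure-response models for crossover and parallel study
    designs, approximates effect-profile uncertainty with a hierarchical
    two-step bootstrap, and extracts the p_zero biomarker separating
    predominant hERG-channel blockers from balanced multichannel blockers.
    Includes a fully synthetic study generator (dipole-model ECG waveforms,
    one-compartment pharmacokinetics, known ground-truth effect profiles) so
    that every pipeline stage is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    splines,
    stats,
    utils,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
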