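test_that("noise-free beats reproduce the designed quantile curve", {
  b <- simulate_beat(rr_s = 1.0, jitter_sd_ms = 0, noise_mv = 0)
  sig <- b$leads; colnames(sig) <- tvv_lead_order()
  e <- annotated_ecg(sig, 500, b$beat)
  tr <- trajectory_quantiles(beat_trajectory(e, e$beats[1, ]))
  expect_lt(max(abs(tr - b$truth)), 2)  # sampling discretization only
})

test_that("the drug time-warp makes ddTr(p) equal g(p) by construction", {
  g <- transition_effect(40, 30)
  extract <- function(conc) {
    b <- simulate_beat(rr_s = 1.0, g = g, conc = conc, c_ref = 1000,
                       jitter_sd_ms = 0, noise_mv = 0)
    sig <- b$leads; colnames(sig) <- tvv_lead_order()
    e <- annotated_ecg(sig, 500, b$beat)
    trajectory_quantiles(beat_trajectory(e, e$beats[1, ]))
  }
  dd <- extract(1000) - extract(0)
  expect_lt(max(abs(dd - g(1:100))), 0.5)
  # non-monotone warp is rejected
  expect_error(simulate_beat(rr_s = 1.0, g = function(p) -3 * p, conc = 1,
                             c_ref = 1),
               "invalid effect profile")
})

test_that("the imposed RR power law shows up in the beat durations", {
  tr_at <- function(rr) {
    b <- simulate_beat(rr_s = rr, jitter_sd_ms = 0, noise_mv = 0)
    sig <- b$leads; colnames(sig) <- tvv_lead_order()
    e <- annotated_ecg(sig, 500, b$beat)
    trajectory_quantiles(beat_trajectory(e, e$beats[1, ]))[["Tr_100"]]
  }
  ratio <- tr_at(0.8) / tr_at(1.2)
  expect_lt(abs(ratio / (0.8 / 1.2)^alpha_ramp(100) - 1), 0.02)
})

test_that("study simulation is reproducible and has the stated dimensions", {
  s1 <- simulate_study(synthetic_design(seed = 7))
  s2 <- simulate_study(synthetic_design(seed = 7))
  expect_identical(s1$pk, s2$pk)
  expect_identical(s1$truth, s2$truth)
  # 22 subjects x 16 timepoints x 3 replicates x 5 treatments
  expect_equal(nrow(s1$schedule), 22 * 16 * 3 * 5)
  # waveform path: byte-identical signals for the same seed
  spec_small <- synthetic_design(n_subjects = 2, timepoints = c(0, 1),
                                 n_replicates = 1,
                                 drugs = list(d = list(cmax = 100,
                                                       g = transition_effect(50, 10))),
                                 seed = 3)
  w1 <- simulate_study(spec_small, waveforms = TRUE)
  w2 <- simulate_study(spec_small, waveforms = TRUE)
  expect_identical(w1$ecgs[[1]]$signal, w2$ecgs[[1]]$signal)
  expect_identical(w1$pk, w2$pk)
})

test_that("a written study round-trips through the loaders", {
  spec_small <- synthetic_design(n_subjects = 2, timepoints = c(0, 1),
                                 n_replicates = 1,
                                 drugs = list(d = list(cmax = 100,
                                                       g = transition_effect(50, 10))),
                                 seed = 3)
  out <- withr::local_tempdir()
  w <- simulate_study(spec_small, waveforms = TRUE, out_dir = out)
  expect_true(file.exists(file.path(out, "pk.csv")))
  expect_true(file.exists(file.path(out, "ground_truth.json")))
  back <- load_annotated_ecg(w$files[1], "wfdb")
  orig <- simulate_study(spec_small, waveforms = TRUE)$ecgs[[basename(w$files[1])]]
  expect_lt(max(abs(back$signal - orig$signal)), 5.01e-4)
  expect_equal(back$beats[, 1:4], orig$beats[, 1:4])
})

test_that("zero-noise quantile study yields ddTrc exactly g(p) C/cref", {
  g <- transition_effect(55, 25)
  sim <- simulate_study_quantiles("A", n_subjects = 4,
    timepoints = c(0, 2, 6), n_replicates = 2,
    drugs = list(drug = list(cmax = 1000, g = g)),
    sd_subj_intercept = 0, sd_effect = 0, sd_ecg = 0, sd_ms = 0,
    seed = 23, p_grid = c(10, 55, 100))
  tabc <- apply_hr_correction(sim$table, true_alpha_profile(p_grid = c(10, 55, 100)))
  rec <- build_analysis_dataset(tabc, "A", sim$pk, p_grid = c(10, 55, 100))
  conc <- rowSums(rec$conc)
  for (k in seq_along(c(10, 55, 100))) {
    p <- c(10, 55, 100)[k]
    expect_equal(unname(rec$y[, paste0("p", p)]), g(p) * conc / 1000,
                 tolerance = 1e-8)
  }
})

test_that("full waveform pipeline recovers the generating effect profile", {
  g <- piecewise_effect(accel = -10, delay = 25, p_flat = 40)
  spec <- synthetic_design(n_subjects = 5, timepoints = c(0, 1, 2, 4),
                           n_replicates = 2,
                           drugs = list(drug = list(cmax = 1000, g = g)),
                           seed = 31)
  w <- simulate_study(spec, waveforms = TRUE)
  qt <- quantile_table(w$ecgs)
  tabc <- apply_hr_correction(qt, true_alpha_profile())
  rec <- build_analysis_dataset(tabc, "A", w$pk)
  fit <- fit_functional(rec, method = "ols")
  prof <- predict_effect_profile(fit, 1000)
  # generating transition (g crosses zero at p = 57) recovered within 5 points
  expect_lte(abs(prof$p_zero - compute_pzero(g(1:100))), 5)
  # terminal effect within a few ms of truth
  expect_lt(abs(prof$ddTrc[100] - 25), 6)
})
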