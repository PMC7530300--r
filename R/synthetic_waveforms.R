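## Waveform-level synthetic ECG generator.
##
## The heart vector is a 3-D dipole: Gaussian wavelets for the P wave and the
## QRS complex, and a T loop traced along a rotating-direction curve whose
## time course is imposed explicitly. The repolarization time axis is built
## from the ground-truth quantile curve, so the time to reach arc-length
## fraction p/100 of the T trajectory equals
##   q(p) * rr^alpha(p) + g(p) * conc / c_ref   (ms)
## by construction; drug effects enter as this time-warp, never as an
## additive waveform change, which makes the generated ddTrc(p) exactly
## g(p) * conc / c_ref. Projection to the eight leads uses the forward Dower
## matrix.

# T-loop geometry parameterised by arc-length fraction s in [0, 1]:
# asymmetric loop built from rotating Gaussian-enveloped components.
t_loop_geometry <- function(amplitude = 0.55, wobble = 0.12, phi0 = 0.45,
                            dphi = 1.15, n_fine = 800) {
  u <- seq(0, 1, length.out = n_fine)
  env <- sin(pi * u)^1.3
  phi <- phi0 + dphi * u
  pts <- cbind(amplitude * env * cos(phi),
               amplitude * env * sin(phi),
               wobble * amplitude * sin(2 * pi * u) * env + 0.25 * amplitude * env)
  seg <- sqrt(rowSums((pts[-1, ] - pts[-n_fine, ])^2))
  s <- c(0, cumsum(seg)) / sum(seg)
  list(s = s, pts = pts)
}

# evaluate the loop at arbitrary arc-length fractions
loop_at <- function(geom, s) {
  cbind(stats::approx(geom$s, geom$pts[, 1], xout = s)$y,
        stats::approx(geom$s, geom$pts[, 2], xout = s)$y,
        stats::approx(geom$s, geom$pts[, 3], xout = s)$y)
}

gauss_wave <- function(t, center, width, amp3) {
  outer(exp(-((t - center) / width)^2), amp3)
}

#' Simulate a single annotated beat
#'
#' Builds one beat (P wave, QRS, T loop) as an 8-lead segment with exact
#' fiducial annotations. The repolarization time axis encodes the power-law
#' RR dependence `rr^alpha(p)` and the additive drug warp
#' `g(p) conc / c_ref` (ms), so the extracted Tr(p) of the beat equals the
#' designed curve up to sampling discretization.
#'
#' @param rr_s Beat interval in seconds (0.4 to 2.0).
#' @param fs Sampling frequency, Hz.
#' @param alpha True exponent profile, function of p.
#' @param g Drug effect profile in ms at the reference concentration
#'   (function of p), or NULL.
#' @param conc,c_ref Concentration and reference concentration.
#' @param tr100 Base trajectory duration at RR = 1 s, ms.
#' @param subject_scale Multiplicative subject factor on the base duration
#'   curve (morphology random effect).
#' @param geom T-loop geometry from `t_loop_geometry()` (subject-specific
#'   morphology); default geometry when NULL.
#' @param jitter_sd_ms Gaussian annotation jitter SD on J and T end
#'   (truncated to preserve ordering), default 0 here; study-level default 2.
#' @param noise_mv Additive white amplitude noise SD per lead, mV.
#' @return List: `leads` (`n x 8` matrix), `beat` (annotation row, 0-based
#'   indices relative to segment start), `n_samples`, `truth` (designed
#'   Tr(p) in ms).
#' @export
simulate_beat <- function(rr_s, fs = 500, alpha = alpha_ramp, g = NULL,
                          conc = 0, c_ref = 1, tr100 = 300,
                          subject_scale = 1, geom = NULL,
                          jitter_sd_ms = 0, noise_mv = 0) {
  stopifnot(rr_s >= 0.4, rr_s <= 2.0)
  if (is.null(geom)) geom <- t_loop_geometry()
  # designed time (ms from trajectory start) to reach arc fraction s = p/100
  p_fine <- seq(0.5, 100, by = 0.5)
  t_p <- base_trajectory_curve(p_fine, tr100 = tr100) * subject_scale *
    rr_s^alpha(p_fine)
  if (!is.null(g) && conc > 0) t_p <- t_p + g(p_fine) * conc / c_ref
  if (any(diff(c(0, t_p)) <= 0)) stop("invalid effect profile: non-monotone time warp")

  p_on_s <- 0.02; q_on_s <- 0.08; j_s <- 0.17
  t_start_s <- j_s + 0.020
  dur_s <- t_p[length(t_p)] / 1000
  n <- round(rr_s * fs)
  t <- (seq_len(n) - 1) / fs
  xyz <- gauss_wave(t, p_on_s + 0.025, 0.014, c(0.04, 0.05, 0.015)) +       # P
    gauss_wave(t, q_on_s + 0.035, 0.008, c(0.9, 1.1, 0.35)) +               # R
    gauss_wave(t, q_on_s + 0.055, 0.006, c(-0.35, -0.45, -0.1)) +          # S
    gauss_wave(t, q_on_s + 0.018, 0.006, c(-0.12, -0.15, -0.05))           # Q
  # T segment: invert the time warp to arc fraction, evaluate the loop
  in_t <- t >= t_start_s & t <= t_start_s + dur_s
  tau_ms <- (t[in_t] - t_start_s) * 1000
  s_tau <- stats::approx(c(0, t_p), c(0, p_fine / 100), xout = tau_ms, rule = 2)$y
  xyz[in_t, ] <- xyz[in_t, ] + loop_at(geom, s_tau)
  leads <- forward_dower(xyz)
  if (noise_mv > 0) leads <- leads + matrix(stats::rnorm(length(leads), 0, noise_mv),
                                            nrow(leads))
  j_idx <- round(j_s * fs)
  t_end_idx <- round((t_start_s + dur_s) * fs)
  if (jitter_sd_ms > 0) {
    jit <- function(idx, lower) {
      max(lower + 1, idx + round(stats::rnorm(1, 0, jitter_sd_ms) * fs / 1000))
    }
    t_end_idx <- min(n - 1, jit(t_end_idx, j_idx + 0.020 * fs + 2))
  }
  beat <- data.frame(p_on = round(p_on_s * fs), q_on = round(q_on_s * fs),
                     j_point = j_idx, t_end = t_end_idx)
  list(leads = leads, beat = beat, n_samples = n,
       truth = stats::setNames(stats::approx(p_fine, t_p, xout = 1:100)$y,
                               tr_cols(1:100)))
}

#' Simulate a full 10-s annotated ECG record
#'
#' Concatenates beats from [simulate_beat()] into a 10-s record (constant
#' beat interval `rr_s` within the record), optionally adds low-frequency
#' baseline wander, and returns an [annotated_ecg()].
#'
#' @inheritParams simulate_beat
#' @param duration_s Record length, seconds.
#' @param wander_mv Amplitude of a slow sinusoidal baseline drift, mV.
#' @param meta Study metadata list.
#' @return An `annotated_ecg`.
#' @export
simulate_ecg <- function(rr_s, fs = 500, duration_s = 10, alpha = alpha_ramp,
                         g = NULL, conc = 0, c_ref = 1, tr100 = 300,
                         subject_scale = 1, geom = NULL, jitter_sd_ms = 2,
                         noise_mv = 0.004, wander_mv = 0, meta = list()) {
  n_total <- round(duration_s * fs)
  sig <- matrix(0, n_total, 8, dimnames = list(NULL, tvv_lead_order()))
  beats <- list()
  offset <- 0L
  while (offset + round(rr_s * fs) <= n_total) {
    b <- simulate_beat(rr_s, fs, alpha, g, conc, c_ref, tr100, subject_scale,
                       geom, jitter_sd_ms, noise_mv)
    idx <- offset + seq_len(b$n_samples)
    sig[idx, ] <- b$leads
    ann <- b$beat + offset
    beats[[length(beats) + 1L]] <- ann
    offset <- offset + b$n_samples
  }
  if (wander_mv > 0) {
    t <- (seq_len(n_total) - 1) / fs
    drift <- wander_mv * sin(2 * pi * 0.25 * t + stats::runif(1, 0, 2 * pi))
    sig <- sig + drift  # common-mode drift on every lead
  }
  annotated_ecg(sig, fs, do.call(rbind, beats), meta)
}

#' Synthetic study design specification
#'
#' The stated world of the generator. Defaults describe the single-dose
#' five-period crossover design: 22 subjects, 16 nominal timepoints
#' (pre-dose plus 0.5--24 h), triplicate ECGs, placebo plus four active
#' treatments.
#'
#' @param design `"A"`, `"B"` or `"C"`.
#' @param n_subjects,timepoints,n_replicates Schedule dimensions.
#' @param drugs Named list of drug specs (`cmax`, `g`, optional `ka`, `ke`).
#' @param alpha True exponent profile.
#' @param jitter_sd_ms Annotation jitter SD (ms) on J/T end.
#' @param noise_mv Amplitude noise SD (mV).
#' @param seed Master seed.
#' @return A `synthetic_design` list.
#' @export
synthetic_design <- function(design = "A", n_subjects = 22,
                             timepoints = c(0, 0.5, 1, 1.5, 2, 2.5, 3, 3.5, 4,
                                            5, 6, 7, 8, 12, 14, 24),
                             n_replicates = 3,
                             drugs = list(
                               dofetilide = list(cmax = 2.5, g = transition_effect(20, 20)),
                               quinidine = list(cmax = 1754, g = transition_effect(35, 55)),
                               ranolazine = list(cmax = 2043, g = transition_effect(52, 8)),
                               verapamil = list(cmax = 114, g = transition_effect(55, 2))),
                             alpha = alpha_ramp, jitter_sd_ms = 2,
                             noise_mv = 0.004, seed = 7) {
  structure(list(design = design, n_subjects = n_subjects,
                 timepoints = timepoints, n_replicates = n_replicates,
                 drugs = drugs, alpha = alpha, jitter_sd_ms = jitter_sd_ms,
                 noise_mv = noise_mv, seed = seed),
            class = "synthetic_design")
}

#' Simulate a complete annotated-ECG study
#'
#' Builds the full schedule (crossover: every subject under every treatment;
#' design C: parallel assignment with a placebo arm), one-compartment PK
#' curves with log-normal between-subject Cmax variability, subject random
#' effects on baseline morphology, heart rate and effect slope, and -- when
#' `waveforms = TRUE` -- a synthetic [annotated_ecg()] per schedule row,
#' optionally written to disk in any supported format. Ground truth
#' (generating curves and per-record concentrations) is always returned,
#' and written as JSON beside the records when files are written.
#'
#' @param spec A [synthetic_design()].
#' @param waveforms Generate waveform records (FALSE returns schedule, PK
#'   and ground truth only; the default full-size schedule has 5280 rows,
#'   so waveform generation is meant for scaled-down specs).
#' @param out_dir When non-NULL, write records there (plus `pk.csv` and
#'   `ground_truth.json`).
#' @param format On-disk record format (see [write_annotated_ecg()]).
#' @return List: `schedule`, `pk`, `truth`, and with waveforms `ecgs`
#'   (named list of `annotated_ecg`) or `files` (paths, when writing).
#' @export
simulate_study <- function(spec = synthetic_design(), waveforms = FALSE,
                           out_dir = NULL, format = "wfdb") {
  set.seed(spec$seed)
  subjects <- sprintf("S%02d", seq_len(spec$n_subjects))
  treatments <- c("placebo", names(spec$drugs))
  assign_trt <- if (spec$design == "C") {
    split(subjects, rep_len(treatments, spec$n_subjects))
  } else {
    stats::setNames(rep(list(subjects), length(treatments)), treatments)
  }
  schedule <- do.call(rbind, lapply(treatments, function(trt) {
    expand.grid(subject = assign_trt[[trt]], treatment = trt,
                timepoint = spec$timepoints,
                replicate = seq_len(spec$n_replicates),
                stringsAsFactors = FALSE)
  }))
  schedule <- schedule[order(schedule$subject, schedule$treatment,
                             schedule$timepoint, schedule$replicate), ]
  rownames(schedule) <- NULL

  b0 <- stats::setNames(stats::rnorm(spec$n_subjects, 0, 0.05), subjects)
  bg <- stats::setNames(stats::rnorm(spec$n_subjects, 0, 0.15), subjects)
  rr_subj <- stats::setNames(exp(stats::rnorm(spec$n_subjects, 0, 0.08)), subjects)
  geoms <- stats::setNames(lapply(seq_len(spec$n_subjects), function(i) {
    t_loop_geometry(amplitude = 0.55 * exp(stats::rnorm(1, 0, 0.1)),
                    phi0 = 0.45 + stats::rnorm(1, 0, 0.15))
  }), subjects)
  cmax_subj <- lapply(names(spec$drugs), function(d) {
    stats::setNames(spec$drugs[[d]]$cmax * exp(stats::rnorm(spec$n_subjects, 0, 0.25)),
                    subjects)
  })
  names(cmax_subj) <- names(spec$drugs)

  pk <- do.call(rbind, lapply(names(spec$drugs), function(d) {
    g <- schedule[schedule$treatment == d & schedule$timepoint > 0 &
                    schedule$replicate == 1, c("subject", "treatment", "timepoint")]
    if (nrow(g) == 0L) return(NULL)
    g$drug <- d
    g$conc_ng_ml <- pk_concentration(g$timepoint, cmax_subj[[d]][g$subject],
                                     ka = spec$drugs[[d]]$ka %||% 1.5,
                                     ke = spec$drugs[[d]]$ke %||% 0.35)
    g
  }))
  cmax_geomean <- vapply(names(spec$drugs), function(d) {
    exp(mean(log(tapply(pk$conc_ng_ml[pk$drug == d], pk$subject[pk$drug == d], max))))
  }, numeric(1))

  truth <- list(design = spec$design,
                alpha = spec$alpha(1:100),
                base = base_trajectory_curve(1:100),
                g = lapply(spec$drugs, function(d) d$g(1:100)),
                cmax_ref = vapply(spec$drugs, `[[`, numeric(1), "cmax"),
                cmax_geomean = cmax_geomean,
                b0 = b0, bg = bg, seed = spec$seed)

  out <- list(schedule = schedule, pk = pk, truth = truth)
  if (!waveforms) return(out)

  pk_key <- paste(pk$subject, pk$treatment, pk$timepoint)
  ecgs <- vector("list", nrow(schedule))
  for (r in seq_len(nrow(schedule))) {
    row <- schedule[r, ]
    conc <- 0
    if (row$treatment != "placebo" && row$timepoint > 0) {
      conc <- pk$conc_ng_ml[match(paste(row$subject, row$treatment, row$timepoint),
                                  pk_key)]
    }
    d <- spec$drugs[[row$treatment]]
    g_subj <- if (!is.null(d)) {
      scl <- 1 + bg[row$subject]  # subject random effect on the effect slope
      local({ g0 <- d$g; s <- scl; function(p) g0(p) * s })
    } else NULL
    rr <- rr_subj[row$subject] * exp(stats::rnorm(1, 0, 0.06))
    rr <- min(2.0, max(0.5, rr))
    ecgs[[r]] <- simulate_ecg(
      rr_s = rr, g = g_subj, conc = conc,
      c_ref = if (!is.null(d)) d$cmax else 1,
      subject_scale = exp(b0[row$subject]), geom = geoms[[row$subject]],
      jitter_sd_ms = spec$jitter_sd_ms, noise_mv = spec$noise_mv,
      meta = as.list(row))
  }
  names(ecgs) <- sprintf("%s_%s_t%g_r%d", schedule$subject, schedule$treatment,
                         schedule$timepoint, schedule$replicate)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- character(nrow(schedule))
    for (r in seq_len(nrow(schedule))) {
      path <- file.path(out_dir, names(ecgs)[r])
      if (format != "wfdb") path <- paste0(path, if (format == "aecg") ".xml" else ".csv")
      write_annotated_ecg(ecgs[[r]], path, format)
      files[r] <- path
    }
    utils::write.csv(pk, file.path(out_dir, "pk.csv"), row.names = FALSE)
    jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    out$files <- files
  } else {
    out$ecgs <- ecgs
  }
  out
}
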