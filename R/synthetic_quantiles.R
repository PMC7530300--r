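#' Ground-truth ingredient functions for the synthetic world
#'
#' `alpha_ramp()` is the default true heart-rate-correction exponent
#' profile: 1.06 for p <= 6, declining linearly to 0.44 at p = 100 (the
#' shape of the published exponent curve, anchored at its printed extremes).
#' `base_trajectory_curve()` is the drug-free heart-rate-corrected duration
#' curve `q(p) = tr100 (p/100)^gamma`; the default exponent makes
#' `q(50)/q(100) = 2/3` (200 vs 300 ms), matching the observed placebo
#' curve. `transition_effect()` builds a monotone effect profile g(p) in ms
#' per reference concentration with its sign change exactly at `p_zero`;
#' `piecewise_effect()` builds the flat-then-ramp profile (constant
#' acceleration below `p_flat`, linear to `delay` at p = 100).
#'
#' @param p Integer percentages.
#' @return `alpha_ramp`, `base_trajectory_curve`: numeric vector over `p`;
#'   the effect constructors return a `function(p)`.
#' @export
alpha_ramp <- function(p) {
  ifelse(p <= 6, 1.06, 1.06 + (0.44 - 1.06) * (p - 6) / (100 - 6))
}

#' @rdname alpha_ramp
#' @param tr100 Trajectory duration at RR = 1 s, ms.
#' @param gamma Power-law exponent of the duration curve.
#' @export
base_trajectory_curve <- function(p, tr100 = 300, gamma = log(1.5) / log(2)) {
  tr100 * (p / 100)^gamma
}

#' @rdname alpha_ramp
#' @param p_zero Percentage where the effect changes sign.
#' @param delay100 Effect at p = 100 (ms at the reference concentration).
#' @export
transition_effect <- function(p_zero, delay100 = 30, gamma = 2) {
  sz <- (p_zero / 100)^gamma
  function(p) delay100 * ((p / 100)^gamma - sz) / (1 - sz)
}

#' @rdname alpha_ramp
#' @param accel Acceleration (negative, ms) over the flat early segment.
#' @param delay Delay at p = 100 (ms).
#' @param p_flat Percentage up to which the acceleration stays flat.
#' @details `piecewise_effect` tapers the acceleration in over `p < 10`:
#'   a drug cannot advance the time-to-reach-p by more than the time the
#'   undrugged trajectory needs to get there, so a flat offset down to
#'   p = 0 would produce a physically impossible (non-monotone) time warp
#'   in the waveform generator.
#' @export
piecewise_effect <- function(accel = -10, delay = 25, p_flat = 40) {
  function(p) {
    flat <- ifelse(p < p_flat, accel,
                   accel + (delay - accel) * (p - p_flat) / (100 - p_flat))
    flat * pmin(1, p / 10)
  }
}

#' Synthetic drug-free quantile corpus
#'
#' Generates a replicate-free drug-free quantile table directly at the
#' Tr(p) level under the generating model
#' `log Tr(p) = log q(p) + (alpha(p) + b1_i) log RR + b0_i + eps`,
#' with subject random intercept/slope drawn once per subject (shared
#' across p) and independent residual noise per ECG and p. Used to test the
#' heart-rate-correction stage against known exponents.
#'
#' @param n_subjects,n_ecgs Corpus size (default 30 x 40).
#' @param alpha Function of p giving the true exponents.
#' @param sd_subj_intercept,sd_subj_slope,sd_resid Log-scale SDs of the
#'   subject intercept, subject slope and residual (defaults 0.05, 0.1,
#'   0.02).
#' @param rr_log_sd Within-corpus SD of log RR (default 0.12, i.e. resting
#'   RR roughly 0.78--1.28 s).
#' @param seed Integer seed.
#' @param p_grid Integer percentages; default `1:100`.
#' @return List with `table` (quantile table: subject, RR_s, Tr_p) and
#'   `truth` (alpha values, base curve, subject effects).
#' @export
simulate_drugfree_quantiles <- function(n_subjects = 30, n_ecgs = 40,
                                        alpha = alpha_ramp,
                                        sd_subj_intercept = 0.05,
                                        sd_subj_slope = 0.1, sd_resid = 0.02,
                                        rr_log_sd = 0.12, seed = 1,
                                        p_grid = 1:100) {
  set.seed(seed)
  a <- alpha(p_grid)
  q <- base_trajectory_curve(p_grid)
  b0 <- stats::rnorm(n_subjects, 0, sd_subj_intercept)
  b1 <- stats::rnorm(n_subjects, 0, sd_subj_slope)
  rows <- vector("list", n_subjects * n_ecgs)
  k <- 0L
  for (i in seq_len(n_subjects)) {
    lrr <- stats::rnorm(n_ecgs, 0, rr_log_sd)
    for (e in seq_len(n_ecgs)) {
      eps <- stats::rnorm(length(p_grid), 0, sd_resid)
      tr <- exp(log(q) + (a + b1[i]) * lrr[e] + b0[i] + eps)
      k <- k + 1L
      rows[[k]] <- c(list(subject = sprintf("S%02d", i), treatment = "placebo",
                          timepoint = 0, replicate = e, RR_s = exp(lrr[e])),
                     stats::setNames(as.list(tr), tr_cols(p_grid)))
    }
  }
  table <- do.call(rbind, lapply(rows, as.data.frame))
  list(table = table,
       truth = list(alpha = a, base = q, b0 = b0, b1 = b1, p_grid = p_grid))
}

#' One-compartment PK concentration curve
#'
#' First-order absorption/elimination profile normalised to a target Cmax:
#' `C(t) = cmax f(t) / max f` with `f(t) = exp(-ke t) - exp(-ka t)`.
#'
#' @param t Hours post dose (concentration 0 for `t <= 0`).
#' @param cmax Peak concentration, ng/mL.
#' @param ka,ke Absorption and elimination rate constants, 1/h.
#' @return Concentrations in ng/mL.
#' @export
pk_concentration <- function(t, cmax, ka = 1.5, ke = 0.35) {
  f <- function(tt) exp(-ke * tt) - exp(-ka * tt)
  tmax <- log(ka / ke) / (ka - ke)
  ifelse(t <= 0, 0, cmax * f(t) / f(tmax))
}

#' Synthetic study at the quantile level
#'
#' Simulates a complete study (crossover for designs A/B, parallel assignment
#' for design C part 1) directly at the Tr(p) level: subject-specific
#' baseline morphology and RR, triplicate ECGs per timepoint, one-compartment
#' PK with log-normal between-subject variability on Cmax, and a
#' concentration-proportional p-dependent drug effect. On the corrected
#' scale the generating model is
#' `Trc(p) = q(p) e^{b0_i} + g(p) (C / cmax_ref) (1 + b_g_i)`,
#' mapped to the observed scale via `Tr(p) = Trc(p) RR^alpha(p)` plus an
#' ECG-level log-normal factor and small per-p additive noise. The true
#' placebo-corrected change from baseline at the reference concentration is
#' therefore `g(p)` by construction.
#'
#' @param design `"A"`, `"B"` or `"C"` (assignment structure: crossover vs
#'   parallel with a placebo arm).
#' @param n_subjects Default 22 (the crossover study size).
#' @param timepoints Hours post dose; `<= 0` rows are pre-dose baselines.
#'   Default: the 16 nominal timepoints of the single-dose crossover design.
#' @param n_replicates ECGs per subject x timepoint (default triplicate).
#' @param drugs Named list; each element
#'   `list(cmax = <ng/mL>, g = function(p), ka =, ke =)`. Default: one
#'   hERG-like and one balanced compound.
#' @param alpha True exponent function of p.
#' @param sd_subj_intercept,sd_effect,sd_ecg,sd_ms Noise levels: subject
#'   log-intercept SD, subject relative effect-slope SD, ECG-level
#'   log-duration SD, per-p additive noise in ms.
#' @param rr_log_sd_subject,rr_log_sd_ecg Between/within subject SD of
#'   log RR.
#' @param seed Integer seed.
#' @param p_grid Integer percentages; default `1:100`.
#' @return List: `table` (replicate-level quantile rows), `pk`
#'   (subject,treatment,timepoint,drug,conc_ng_ml), `truth` (generating
#'   functions, subject effects, cmax_ref per drug).
#' @export
simulate_study_quantiles <- function(design = c("A", "B", "C"), n_subjects = 22,
                                     timepoints = c(0, 0.5, 1, 1.5, 2, 2.5, 3,
                                                    3.5, 4, 5, 6, 7, 8, 12, 14, 24),
                                     n_replicates = 3,
                                     drugs = list(
                                       herg = list(cmax = 1000, g = transition_effect(20, 40)),
                                       balanced = list(cmax = 1000, g = transition_effect(55, 25))),
                                     alpha = alpha_ramp,
                                     sd_subj_intercept = 0.05, sd_effect = 0.15,
                                     sd_ecg = 0.015, sd_ms = 1,
                                     rr_log_sd_subject = 0.08, rr_log_sd_ecg = 0.06,
                                     seed = 1, p_grid = 1:100) {
  design <- match.arg(design)
  set.seed(seed)
  a <- alpha(p_grid)
  q <- base_trajectory_curve(p_grid)
  treatments <- c("placebo", names(drugs))
  subjects <- sprintf("S%02d", seq_len(n_subjects))
  b0 <- stats::setNames(stats::rnorm(n_subjects, 0, sd_subj_intercept), subjects)
  bg <- stats::setNames(stats::rnorm(n_subjects, 0, sd_effect), subjects)
  rr_subj <- stats::setNames(stats::rnorm(n_subjects, 0, rr_log_sd_subject), subjects)
  cmax_subj <- lapply(names(drugs), function(d) {
    stats::setNames(drugs[[d]]$cmax * exp(stats::rnorm(n_subjects, 0, 0.25)), subjects)
  })
  names(cmax_subj) <- names(drugs)

  assign_trt <- if (design == "C") {
    # parallel: subjects split evenly over placebo + drugs
    split(subjects, rep_len(treatments, n_subjects))
  } else {
    stats::setNames(rep(list(subjects), length(treatments)), treatments)
  }

  g_vals <- lapply(drugs, function(d) d$g(p_grid))
  rows <- list(); pk_rows <- list()
  for (trt in treatments) {
    for (s in assign_trt[[trt]]) {
      for (tp in timepoints) {
        conc <- 0
        if (trt != "placebo" && tp > 0) {
          d <- drugs[[trt]]
          conc <- pk_concentration(tp, cmax_subj[[trt]][s],
                                   ka = d$ka %||% 1.5, ke = d$ke %||% 0.35)
          pk_rows[[length(pk_rows) + 1L]] <-
            data.frame(subject = s, treatment = trt, timepoint = tp,
                       drug = trt, conc_ng_ml = conc)
        }
        for (r in seq_len(n_replicates)) {
          rr <- exp(rr_subj[s] + stats::rnorm(1, 0, rr_log_sd_ecg))
          trc <- q * exp(b0[s])
          if (conc > 0) {
            trc <- trc + g_vals[[trt]] * (conc / drugs[[trt]]$cmax) * (1 + bg[s])
          }
          tr <- trc * rr^a * exp(stats::rnorm(1, 0, sd_ecg)) +
            stats::rnorm(length(p_grid), 0, sd_ms)
          rows[[length(rows) + 1L]] <-
            c(list(subject = s, treatment = trt, timepoint = tp, replicate = r,
                   RR_s = rr),
              stats::setNames(as.list(tr), tr_cols(p_grid)))
        }
      }
    }
  }
  table <- do.call(rbind, lapply(rows, as.data.frame))
  pk <- if (length(pk_rows)) do.call(rbind, pk_rows) else NULL
  truth <- list(alpha = a, base = q, g = g_vals,
                cmax_ref = vapply(drugs, `[[`, numeric(1), "cmax"),
                b0 = b0, bg = bg, p_grid = p_grid, design = design)
  list(table = table, pk = pk, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
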