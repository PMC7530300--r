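#' Annotated 12-lead ECG record
#'
#' Container for one 10-s resting ECG: the eight independent lead signals,
#' sampling frequency, per-beat fiducial annotations and study metadata.
#' Amplitudes are in millivolts; all annotation positions are 0-based sample
#' indices in `[0, n_samples)`.
#'
#' Beats are usable when all four fiducials (P onset, Q onset, J point,
#' T end) are present, strictly ordered, and the T-vector trajectory window
#' `[j_point + 20 ms, t_end]` spans at least 2 samples.
#'
#' @param signal Numeric matrix `n_samples x n_leads`, mV. Columns must carry
#'   the lead names; the eight independent leads I, II, V1--V6 are required
#'   (III/aVR/aVL/aVF, if present, are dropped — they are linear combinations).
#' @param fs Sampling frequency in Hz (> 0).
#' @param beats Data frame with columns `p_on, q_on, j_point, t_end`
#'   (0-based sample indices; NA allowed and marks the beat unusable) and
#'   optionally `is_usable`.
#' @param meta Named list identifying the record within a study
#'   (`subject`, `treatment`, `timepoint`, `replicate`, ...).
#' @return An object of class `annotated_ecg`.
#' @export
annotated_ecg <- function(signal, fs, beats, meta = list()) {
  stopifnot(is.matrix(signal), is.numeric(signal), fs > 0)
  ln <- colnames(signal)
  if (is.null(ln)) stop("signal matrix must have lead names as colnames")
  missing_leads <- setdiff(tvv_lead_order(), ln)
  if (length(missing_leads) > 0L) {
    stop("required lead(s) missing: ", paste(missing_leads, collapse = ", "))
  }
  signal <- signal[, tvv_lead_order(), drop = FALSE]
  beats <- as.data.frame(beats)
  for (col in c("p_on", "q_on", "j_point", "t_end")) {
    if (is.null(beats[[col]])) beats[[col]] <- NA_real_
  }
  n <- nrow(signal)
  idx <- as.matrix(beats[, c("p_on", "q_on", "j_point", "t_end")])
  if (any(idx < 0 | idx >= n, na.rm = TRUE)) {
    stop("annotation sample indices outside [0, n_samples)")
  }
  if (is.null(beats$is_usable)) beats$is_usable <- TRUE
  beats$is_usable <- beats$is_usable & beat_is_usable(beats, fs)
  o <- order(beats$q_on)
  beats <- beats[o, , drop = FALSE]
  rownames(beats) <- NULL
  structure(
    list(signal = signal, lead_names = tvv_lead_order(), fs = fs,
         beats = beats, meta = meta),
    class = "annotated_ecg"
  )
}

# Usability: fiducials present, strictly ordered, trajectory window >= 2 samples.
beat_is_usable <- function(beats, fs) {
  with(beats, {
    ok <- !is.na(p_on) & !is.na(q_on) & !is.na(j_point) & !is.na(t_end)
    ord <- ok & (p_on < q_on) & (q_on < j_point) & (j_point < t_end)
    span <- ord & (t_end - (j_point + 0.020 * fs) >= 2)
    span & !is.na(span)
  })
}

#' @export
print.annotated_ecg <- function(x, ...) {
  cat(sprintf("<annotated_ecg> %d samples x %d leads @ %g Hz (%.1f s), %d beats (%d usable)\n",
              nrow(x$signal), ncol(x$signal), x$fs, nrow(x$signal) / x$fs,
              nrow(x$beats), sum(x$beats$is_usable)))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' Derive the four dependent limb leads
#'
#' III, aVR, aVL and aVF are fixed linear combinations of I and II and are
#' not stored; this computes them on demand.
#'
#' @param ecg An `annotated_ecg`.
#' @return Numeric matrix `n_samples x 4` with columns III, aVR, aVL, aVF (mV).
#' @export
derived_limb_leads <- function(ecg) {
  I <- ecg$signal[, "I"]; II <- ecg$signal[, "II"]
  cbind(III = II - I, aVR = -(I + II) / 2, aVL = I - II / 2, aVF = II - I / 2)
}

#' Resample an ECG record to a target sampling frequency
#'
#' Linear interpolation of each lead with rescaling of all annotation indices.
#' Used by the loaders to normalise every record to 500 Hz.
#'
#' @param ecg An `annotated_ecg`.
#' @param fs_out Target sampling frequency in Hz.
#' @return An `annotated_ecg` at `fs_out`.
#' @export
resample_ecg <- function(ecg, fs_out = 500) {
  if (ecg$fs == fs_out) return(ecg)
  n_in <- nrow(ecg$signal)
  t_in <- (seq_len(n_in) - 1) / ecg$fs
  n_out <- floor((n_in - 1) * fs_out / ecg$fs) + 1L
  t_out <- (seq_len(n_out) - 1) / fs_out
  sig <- apply(ecg$signal, 2, function(y) stats::approx(t_in, y, xout = t_out)$y)
  colnames(sig) <- colnames(ecg$signal)
  beats <- ecg$beats
  for (col in c("p_on", "q_on", "j_point", "t_end")) {
    beats[[col]] <- round(beats[[col]] * fs_out / ecg$fs)
  }
  beats$is_usable <- NULL
  annotated_ecg(sig, fs_out, beats, ecg$meta)
}
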