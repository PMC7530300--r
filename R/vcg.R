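#' Per-beat T vector trajectory
#'
#' Reconstructs the 3-D heart vector over the repolarization window of one
#' beat. The trajectory spans `[j_point + 20 ms, t_end]` (the 20 ms offset
#' excludes late depolarization); samples are taken at the record's native
#' sampling frequency and mapped through the inverse Dower transformation.
#'
#' @param ecg An `annotated_ecg`.
#' @param beat One row of `ecg$beats` (or a list with `j_point`, `t_end`).
#' @return A list of class `t_trajectory` with `points` (`n x 3` matrix,
#'   mV), `t0_ms` (absolute time of the first point) and `fs`; or `NULL`
#'   with a warning when the span is degenerate (< 2 samples).
#' @export
beat_trajectory <- function(ecg, beat) {
  start <- round(beat$j_point + 0.020 * ecg$fs)
  end <- beat$t_end
  if (end - start < 1) {
    warning(sprintf("beat at q_on=%s excluded: trajectory span < 2 samples", beat$q_on))
    return(NULL)
  }
  idx <- seq(start, end)  # 0-based sample indices
  xyz <- inverse_dower(ecg$signal[idx + 1, , drop = FALSE])
  structure(list(points = xyz, t0_ms = start * 1000 / ecg$fs, fs = ecg$fs),
            class = "t_trajectory")
}

#' Trajectory time quantiles Tr(p)
#'
#' Computes the time (ms, measured from the trajectory's first point) at
#' which the cumulative chord length of the 3-D trajectory first reaches
#' p percent of its total length, with linear interpolation inside the
#' bracketing sample interval. Tr(100) equals the trajectory duration.
#'
#' @param traj A `t_trajectory` (or plain `n x 3` matrix, in which case `fs`
#'   must be supplied).
#' @param p_grid Integer percentages; default `1:100`.
#' @param fs Sampling frequency when `traj` is a bare matrix.
#' @return Named numeric vector `Tr_p` in ms, nondecreasing in p.
#' @export
trajectory_quantiles <- function(traj, p_grid = 1:100, fs = NULL) {
  if (inherits(traj, "t_trajectory")) {
    pts <- traj$points; fs <- traj$fs
  } else {
    pts <- traj
    if (is.null(fs)) stop("fs required for a bare trajectory matrix")
  }
  n <- nrow(pts)
  if (n < 2L) stop("degenerate trajectory")
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-n, , drop = FALSE])^2))
  cs <- c(0, cumsum(seg))
  L <- cs[n]
  if (L <= 0) stop("degenerate trajectory")
  targets <- p_grid / 100 * L
  # first index where the cumulative length reaches the target
  i <- findInterval(targets, cs, left.open = TRUE) + 1L
  i <- pmin(i, n)
  frac <- (targets - cs[i - 1L]) / seg[i - 1L]
  tr <- ((i - 2L) + frac) * 1000 / fs
  tr[targets <= 0] <- 0
  names(tr) <- paste0("Tr_", p_grid)
  tr
}

#' Per-ECG trajectory quantiles
#'
#' Computes Tr(p) for every usable beat and averages them, per p, into the
#' ECG-level quantile row; RR is the mean Q-to-Q interval of the usable
#' beats in seconds. Beats whose trajectory is degenerate (zero length or
#' span below 2 samples) are excluded with a warning.
#'
#' @param ecg An `annotated_ecg` (baseline-corrected and filtered).
#' @param p_grid Integer percentages; default `1:100`.
#' @return One-row data frame with the study-key columns of `ecg$meta`,
#'   `RR_s`, and `Tr_1 .. Tr_100`; or `NULL` (with a warning) when no beat
#'   is usable.
#' @export
ecg_quantiles <- function(ecg, p_grid = 1:100) {
  beats <- ecg$beats[ecg$beats$is_usable, , drop = FALSE]
  trs <- list()
  for (b in seq_len(nrow(beats))) {
    traj <- beat_trajectory(ecg, beats[b, ])
    if (is.null(traj)) next
    tq <- tryCatch(trajectory_quantiles(traj, p_grid), error = function(e) NULL)
    if (!is.null(tq)) trs[[length(trs) + 1L]] <- tq
  }
  if (length(trs) == 0L) {
    warning("ECG excluded: no usable beat with non-degenerate trajectory")
    return(NULL)
  }
  tr_mean <- colMeans(do.call(rbind, trs))
  rr <- if (nrow(beats) >= 2L) mean(diff(beats$q_on)) / ecg$fs else NA_real_
  meta <- ecg$meta[intersect(c("subject", "treatment", "timepoint", "replicate", "phase"),
                             names(ecg$meta))]
  out <- c(meta, list(RR_s = rr), as.list(tr_mean))
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Assemble a quantile table from many records
#'
#' Convenience wrapper running [baseline_correct()], [bessel_lowpass()] and
#' [ecg_quantiles()] over a list of records and row-binding the results.
#'
#' @param ecgs List of `annotated_ecg` records.
#' @param preprocess Apply baseline correction and 36 Hz Bessel filtering
#'   first (default TRUE).
#' @param p_grid Integer percentages; default `1:100`.
#' @return Data frame, one row per non-excluded ECG.
#' @export
quantile_table <- function(ecgs, preprocess = TRUE, p_grid = 1:100) {
  rows <- lapply(ecgs, function(e) {
    if (preprocess) e <- bessel_lowpass(baseline_correct(e))
    ecg_quantiles(e, p_grid)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

tr_cols <- function(p_grid = 1:100) paste0("Tr_", p_grid)
trc_cols <- function(p_grid = 1:100) paste0("Trc_", p_grid)
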