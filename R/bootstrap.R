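#' Two-step hierarchical resampling
#'
#' The paper's nonparametric bootstrap scheme: subjects are the primary
#' resampling unit (drawn with replacement and relabelled so duplicated
#' subjects stay distinct for the random effects), then within each drawn
#' subject the replicate 10-s ECGs of every treatment x timepoint cell are
#' drawn with replacement (the secondary unit) before any replicate
#' averaging downstream.
#'
#' @param table Replicate-level quantile table (one row per ECG) with a
#'   `subject` column.
#' @param seed Optional integer; when given, the draw is deterministic.
#' @return The resampled table; fresh subject ids in `subject`, the original
#'   id in `.orig_subject`.
#' @export
two_step_resample <- function(table, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  subjects <- unique(table$subject)
  if (length(subjects) < 2L) {
    draw <- subjects  # degenerate single-subject case: primary step is fixed
  } else {
    draw <- sample(subjects, length(subjects), replace = TRUE)
  }
  by_subject <- split(seq_len(nrow(table)), table$subject)
  cell_all <- paste(table$treatment, table$timepoint, sep = "\r")
  idx_all <- integer(0); new_id <- character(0)
  for (k in seq_along(draw)) {
    rows <- by_subject[[as.character(draw[k])]]
    idx <- unlist(lapply(split(rows, cell_all[rows]), function(ii) {
      if (length(ii) == 1L) ii else sample(ii, length(ii), replace = TRUE)
    }), use.names = FALSE)
    idx_all <- c(idx_all, idx)
    new_id <- c(new_id, rep(sprintf("bs%03d", k), length(idx)))
  }
  out <- table[idx_all, , drop = FALSE]
  out$.orig_subject <- out$subject
  out$subject <- new_id
  rownames(out) <- NULL
  out
}

#' Bootstrap distribution of continuous effect profiles
#'
#' Runs `N` independent two-step resamples; each resample is pushed through
#' [build_analysis_dataset()], [fit_functional()] and
#' [predict_effect_profile()]. The summary profile is the per-p median with
#' the two-sided 90% confidence band as the 5 and 95% empirical quantiles
#' (linear interpolation); every bootstrap profile also yields one `p_zero`
#' sample. Replicates are driven by pre-assigned seed substreams, so results
#' do not depend on execution order; non-converged replicates are dropped
#' and counted, and more than 20% failures is an error.
#'
#' The default fitting engine is `"ols"`: subject-level variability is
#' captured by the primary resampling step, the single-fit covariances are
#' never used for inference, and this keeps paper-scale replicate counts
#' (4000/4000/1000 for designs A/B/C) tractable. REML refits per replicate
#' are available with `method = "reml"`.
#'
#' @param table Replicate-level corrected quantile table.
#' @param design `"A"`, `"B"` or `"C"`.
#' @param pk Concentration table (see [build_analysis_dataset()]).
#' @param conc Concentration(s) at which profiles are predicted.
#' @param N Number of bootstrap replicates (desk-scale default 200).
#' @param seed Master seed.
#' @param n_knots,treatment,phase,method Passed to [fit_functional()].
#' @param placebo Placebo treatment label.
#' @return A `bootstrap_result`: `profiles` (kept replicates x 100),
#'   `pzero_samples`, `summary` ([effect_profile()] with bands), `N`,
#'   `n_failed`, `seed`.
#' @export
bootstrap_profiles <- function(table, design, pk = NULL, conc = 0, N = 200,
                               seed = 1, n_knots = NULL, treatment = NULL,
                               phase = NULL, method = c("ols", "reml"),
                               placebo = "placebo") {
  method <- match.arg(method)
  stopifnot(N >= 1)
  set.seed(seed)
  substreams <- sample.int(.Machine$integer.max - 1L, N)
  profiles <- vector("list", N)
  for (i in seq_len(N)) {
    profiles[[i]] <- tryCatch({
      rs <- two_step_resample(table, seed = substreams[i])
      pk_rs <- remap_pk(pk, rs)
      records <- suppressWarnings(
        build_analysis_dataset(rs, design, pk_rs, placebo = placebo))
      fit <- fit_functional(records, n_knots = n_knots, treatment = treatment,
                            phase = phase, method = method)
      predict_effect_profile(fit, conc)$ddTrc
    }, error = function(e) NULL)
  }
  failed <- vapply(profiles, is.null, logical(1))
  if (mean(failed) > 0.2) stop("unstable model under resampling: ",
                               sum(failed), " of ", N, " replicates failed")
  P <- do.call(rbind, profiles[!failed])
  med <- apply(P, 2, stats::median)
  lo <- apply(P, 2, stats::quantile, probs = 0.05, names = FALSE)
  hi <- apply(P, 2, stats::quantile, probs = 0.95, names = FALSE)
  pz <- apply(P, 1, compute_pzero)
  structure(list(profiles = P, N = N, n_failed = sum(failed), seed = seed,
                 summary = effect_profile(1:100, med, lo, hi, conc = conc),
                 pzero_samples = pz),
            class = "bootstrap_result")
}

# duplicate the PK rows of resampled subjects under their fresh ids
remap_pk <- function(pk, resampled_table) {
  if (is.null(pk)) return(NULL)
  map <- unique(resampled_table[, c("subject", ".orig_subject")])
  pieces <- lapply(seq_len(nrow(map)), function(k) {
    rows <- pk[pk$subject == map$.orig_subject[k], , drop = FALSE]
    if (nrow(rows)) rows$subject <- map$subject[k]
    rows
  })
  do.call(rbind, pieces)
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> %d replicates (%d failed), seed %d\n",
              x$N, x$n_failed, x$seed))
  cat(sprintf("  ddTr(100)c median %.1f [%.1f, %.1f] ms; p_zero median %d%%\n",
              x$summary$ddTrc[100], x$summary$lower90[100], x$summary$upper90[100],
              as.integer(stats::median(x$pzero_samples))))
  invisible(x)
}
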