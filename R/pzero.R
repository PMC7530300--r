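#' Zero-transition percentage of an effect profile
#'
#' `p_zero` is the largest trajectory length percentage p at which the
#' effect profile changes sign from negative (accelerated repolarization)
#' to non-negative (delayed repolarization). Profiles that are negative
#' everywhere get 100; profiles that are non-negative everywhere get 1
#' (exact zeros count as non-negative). A profile with mixed signs but no
#' negative-to-positive transition (i.e. ending negative) is treated like
#' the all-negative case and gets 100.
#'
#' @param ddTrc Numeric effect profile over the integer grid `p = 1..100`
#'   (or an `effect_profile`).
#' @return Integer p_zero in `1..100`.
#' @export
compute_pzero <- function(ddTrc) {
  if (inherits(ddTrc, "effect_profile")) ddTrc <- ddTrc$ddTrc
  if (anyNA(ddTrc)) stop("NaN/NA in effect profile")
  neg <- ddTrc < 0
  n <- length(neg)
  if (all(neg)) return(n)
  if (!any(neg)) return(1L)
  trans <- which(neg[-n] & !neg[-1])
  if (length(trans)) max(trans) else if (neg[n]) n else 1L
}

#' Classify drug conditions by p_zero threshold
#'
#' Each bootstrap p_zero sample is one classification instance: a sample is
#' predicted `hERG_predominant` iff `p_zero < threshold`. Sensitivity is the
#' fraction of samples from `hERG_predominant` conditions predicted as such;
#' specificity the fraction of `multichannel_low_risk` samples predicted as
#' such. Samples are pooled across the conditions of a class. Conditions
#' labelled `excluded` are ignored. A sweep over all integer thresholds is
#' returned alongside.
#'
#' @param conditions Data frame with columns `drug`, `risk_class` (one of
#'   `hERG_predominant`, `multichannel_low_risk`, `excluded`) and `pzero`
#'   (one row per bootstrap sample).
#' @param threshold Classification threshold in percent (default 43).
#' @return A `classification_report`: `threshold`, `sensitivity`,
#'   `specificity`, per-condition counts, and the `sweep` table over
#'   thresholds 1..100.
#' @export
classify <- function(conditions, threshold = 43) {
  stopifnot(all(c("drug", "risk_class", "pzero") %in% names(conditions)))
  conditions <- conditions[conditions$risk_class != "excluded", , drop = FALSE]
  pos <- conditions$pzero[conditions$risk_class == "hERG_predominant"]
  negc <- conditions$pzero[conditions$risk_class == "multichannel_low_risk"]
  if (length(pos) == 0L || length(negc) == 0L) {
    stop("both risk classes must have at least one p_zero sample")
  }
  sens_at <- function(thr) mean(pos < thr)
  spec_at <- function(thr) mean(negc >= thr)
  sweep <- data.frame(threshold = 1:100,
                      sensitivity = vapply(1:100, sens_at, numeric(1)),
                      specificity = vapply(1:100, spec_at, numeric(1)))
  counts <- stats::aggregate(pzero ~ drug + risk_class, conditions, length)
  names(counts)[3] <- "n_samples"
  structure(list(threshold = threshold, sensitivity = sens_at(threshold),
                 specificity = spec_at(threshold), counts = counts,
                 sweep = sweep),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> threshold %g%%: sensitivity %.3f, specificity %.3f\n",
              x$threshold, x$sensitivity, x$specificity))
  print(x$counts, row.names = FALSE)
  invisible(x)
}
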