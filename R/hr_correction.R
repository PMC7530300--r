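#' Fit per-quantile heart-rate correction exponents
#'
#' For each trajectory length percentage p the dependence of Tr(p) on heart
#' rate is modelled as a power law `Tr(p) ~ beta_p * RR^alpha_p`, i.e. on the
#' log scale `log Tr(p) = log beta_p + alpha_p log RR + eps`, fitted to
#' drug-free data by a linear mixed model (REML) with correlated random
#' intercept and slope per subject. The 100 fits are independent (no
#' smoothing across p). Singular or non-converged fits fall back to a random
#' intercept model, then to OLS; the fallback used is recorded.
#'
#' RR is in seconds, so `log RR = 0` at 60 bpm and `beta_p` is Tr(p) at a
#' 1-second beat interval. Natural logarithms throughout.
#'
#' @param drug_free Quantile table rows (placebo periods plus pre-dose
#'   baselines): columns `subject`, `RR_s`, `Tr_1..Tr_100`.
#' @param p_grid Integer percentages; default `1:100`.
#' @return An `alpha_profile`: data frame with `p`, `alpha`, `se`,
#'   `log_beta`, `fallback`, plus attributes `n_obs` and `fingerprint`.
#' @export
fit_alpha_profile <- function(drug_free, p_grid = 1:100) {
  if (length(unique(drug_free$subject)) < 2L) stop("need >= 2 subjects")
  lrr <- log(drug_free$RR_s)
  if (stats::var(lrr) <= 0) stop("alpha unidentifiable: RR constant in drug-free data")
  subject <- factor(drug_free$subject)
  out <- data.frame(p = p_grid, alpha = NA_real_, se = NA_real_,
                    log_beta = NA_real_, fallback = "none",
                    stringsAsFactors = FALSE)
  for (k in seq_along(p_grid)) {
    y <- log(drug_free[[paste0("Tr_", p_grid[k])]])
    d <- data.frame(y = y, lrr = lrr, subject = subject)
    fit <- fit_lmm_slope(d)
    out$alpha[k] <- fit$slope
    out$se[k] <- fit$se
    out$log_beta[k] <- fit$intercept
    out$fallback[k] <- fit$fallback
  }
  attr(out, "n_obs") <- nrow(drug_free)
  attr(out, "fingerprint") <- sprintf("%d rows, %d subjects, RR [%0.3f, %0.3f] s",
                                      nrow(drug_free), nlevels(subject),
                                      min(drug_free$RR_s), max(drug_free$RR_s))
  class(out) <- c("alpha_profile", "data.frame")
  out
}

# REML random-intercept+slope fit with the documented fallback chain.
fit_lmm_slope <- function(d) {
  quiet_lmer <- function(formula) {
    suppressMessages(suppressWarnings(
      tryCatch(lme4::lmer(formula, data = d, REML = TRUE,
                          control = lme4::lmerControl(calc.derivs = FALSE)),
               error = function(e) NULL)
    ))
  }
  m <- quiet_lmer(y ~ lrr + (1 + lrr | subject))
  fallback <- "none"
  if (is.null(m) || lme4::isSingular(m, tol = 1e-5)) {
    m2 <- quiet_lmer(y ~ lrr + (1 | subject))
    if (!is.null(m2)) { m <- m2; fallback <- "random_intercept" }
  }
  if (is.null(m)) {
    m <- stats::lm(y ~ lrr, data = d)
    fallback <- "ols"
    co <- suppressWarnings(stats::coef(summary(m)))
    return(list(intercept = co[1, 1], slope = co[2, 1], se = co[2, 2],
                fallback = fallback))
  }
  fe <- lme4::fixef(m)
  se <- sqrt(diag(as.matrix(stats::vcov(m))))
  list(intercept = fe[[1]], slope = fe[[2]], se = se[[2]], fallback = fallback)
}

#' @export
print.alpha_profile <- function(x, ...) {
  cat(sprintf("<alpha_profile> p in [%d, %d]; alpha range [%.4f, %.4f]\n",
              min(x$p), max(x$p), min(x$alpha), max(x$alpha)))
  cat("  fitted on:", attr(x, "fingerprint"), "\n")
  if (any(x$fallback != "none")) {
    cat("  fallbacks:", sum(x$fallback != "none"), "of", nrow(x), "fits\n")
  }
  invisible(x)
}

#' Apply heart-rate correction to a quantile table
#'
#' Adds `Trc_p = Tr_p / RR^alpha_p` columns; the uncorrected `Tr_p` columns
#' are retained.
#'
#' @param table Quantile table with `RR_s` and `Tr_p` columns.
#' @param alphas An `alpha_profile` covering every p present in `table`.
#' @return The table with appended `Trc_p` columns.
#' @export
apply_hr_correction <- function(table, alphas) {
  stopifnot(all(table$RR_s > 0))
  p_grid <- as.integer(sub("^Tr_", "", grep("^Tr_\\d+$", names(table), value = TRUE)))
  missing_p <- setdiff(p_grid, alphas$p)
  if (length(missing_p)) {
    stop("alpha profile lacks p = ", paste(missing_p, collapse = ", "))
  }
  a <- alphas$alpha[match(p_grid, alphas$p)]
  for (k in seq_along(p_grid)) {
    table[[paste0("Trc_", p_grid[k])]] <-
      table[[paste0("Tr_", p_grid[k])]] / table$RR_s^a[k]
  }
  table
}
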