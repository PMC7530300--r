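#' Build the analysis dataset for a study design
#'
#' Turns a heart-rate-corrected quantile table into the per-design modelling
#' records: replicate ECGs are averaged per subject x treatment x timepoint,
#' the change from baseline is formed against the subject's own pre-dose
#' (timepoint <= 0) mean within the period, and, for the crossover designs A
#' and B, the placebo change at the matching nominal timepoint of the same
#' subject is subtracted (records without a matched placebo timepoint are
#' dropped with a warning). For the (partly) parallel design C only the
#' change from baseline is formed; placebo correction happens inside the
#' model, which additionally carries the treatment indicator, nominal
#' timepoint and the centered subject baseline as covariates.
#'
#' @param table Quantile table with `subject`, `treatment`, `timepoint`,
#'   `replicate`, `Trc_p` columns.
#' @param design `"A"`, `"B"` or `"C"`.
#' @param pk Concentration table `subject,treatment,timepoint,drug,conc_ng_ml`
#'   (active treatments; absent combinations count as concentration 0).
#' @param placebo Treatment label of the placebo arm/period.
#' @param phase_breaks Design B only: hours post first dose starting the
#'   afternoon and evening phases (default `c(4, 9.5)`, the dosing schema).
#' @param p_grid Integer percentages; default `1:100`.
#' @return A `tvv_records` object: `design`, `data` (subject, treatment,
#'   timepoint, phase), `conc` (matrix, one column per drug, ng/mL), `y`
#'   (matrix over p: ddTrc for A/B, dTrc for C), and for C `baseline`
#'   (subject baseline Trc, centered inside the fits) and `trt` (0/1).
#' @export
build_analysis_dataset <- function(table, design = c("A", "B", "C"), pk = NULL,
                                   placebo = "placebo", phase_breaks = c(4, 9.5),
                                   p_grid = 1:100) {
  design <- match.arg(design)
  trc <- trc_cols(p_grid)
  stopifnot(all(trc %in% names(table)))
  Y <- as.matrix(table[, trc, drop = FALSE])

  # replicate averaging (matrix rowsum; key order = factor level order)
  key <- factor(paste(table$subject, table$treatment, table$timepoint, sep = "\r"))
  Yagg <- rowsum(Y, key) / as.vector(table(key))
  first <- !duplicated(key)
  meta0 <- table[first, c("subject", "treatment", "timepoint"), drop = FALSE]
  meta0 <- meta0[match(levels(key), key[first]), , drop = FALSE]

  # change from baseline within subject x treatment period
  pkey <- factor(paste(meta0$subject, meta0$treatment, sep = "\r"))
  pre <- meta0$timepoint <= 0
  has_bl <- tapply(pre, pkey, any)
  if (!all(has_bl)) {
    warning("dropped period(s) without pre-dose baseline: ",
            paste(gsub("\r", "/", names(has_bl)[!has_bl]), collapse = ", "))
  }
  Bl <- rowsum(Yagg[pre, , drop = FALSE], pkey[pre]) /
    as.vector(table(droplevels(pkey[pre])))
  keep <- !pre & as.character(pkey) %in% rownames(Bl)
  bl_mat <- Bl[as.character(pkey)[keep], , drop = FALSE]
  delta <- Yagg[keep, , drop = FALSE] - bl_mat
  meta <- meta0[keep, , drop = FALSE]
  colnames(delta) <- colnames(bl_mat) <- paste0("p", p_grid)
  rownames(delta) <- rownames(bl_mat) <- NULL

  if (design %in% c("A", "B")) {
    is_pla <- meta$treatment == placebo
    pla_key <- paste(meta$subject, meta$timepoint)[is_pla]
    pla_delta <- delta[is_pla, , drop = FALSE]
    act <- which(!is_pla)
    m <- match(paste(meta$subject, meta$timepoint)[act], pla_key)
    if (anyNA(m)) {
      miss <- act[is.na(m)]
      warning("dropped ", length(miss), " record(s) without matched placebo timepoint: ",
              paste(utils::head(paste(meta$subject[miss], meta$timepoint[miss], sep = "@"), 5),
                    collapse = ", "))
      act <- act[!is.na(m)]; m <- m[!is.na(m)]
    }
    y <- delta[act, , drop = FALSE] - pla_delta[m, , drop = FALSE]
    meta <- meta[act, , drop = FALSE]
    baseline <- NULL; trt <- NULL
  } else {
    y <- delta
    baseline <- bl_mat
    trt <- as.numeric(meta$treatment != placebo)
  }

  meta$phase <- if (design == "B") {
    cut(meta$timepoint, breaks = c(-Inf, phase_breaks, Inf),
        labels = c("morning", "afternoon", "evening"), right = FALSE)
  } else NA

  drugs <- if (!is.null(pk)) sort(unique(pk$drug)) else character(0)
  conc <- matrix(0, nrow(meta), length(drugs), dimnames = list(NULL, drugs))
  if (length(drugs)) {
    pk_key <- paste(pk$subject, pk$treatment, pk$timepoint, pk$drug)
    for (d in drugs) {
      mi <- match(paste(meta$subject, meta$treatment, meta$timepoint, d), pk_key)
      conc[, d] <- ifelse(is.na(mi), 0, pk$conc_ng_ml[mi])
    }
  }
  rownames(meta) <- NULL
  structure(list(design = design, data = meta, conc = conc, y = y,
                 baseline = baseline, trt = trt, p_grid = p_grid,
                 placebo = placebo),
            class = "tvv_records")
}

#' @export
print.tvv_records <- function(x, ...) {
  cat(sprintf("<tvv_records> design %s: %d records, %d subjects, treatments: %s\n",
              x$design, nrow(x$data), length(unique(x$data$subject)),
              paste(unique(x$data$treatment), collapse = ", ")))
  invisible(x)
}

# subset helper keeping all parallel components aligned
records_subset <- function(records, keep) {
  records$data <- records$data[keep, , drop = FALSE]
  records$conc <- records$conc[keep, , drop = FALSE]
  records$y <- records$y[keep, , drop = FALSE]
  if (!is.null(records$baseline)) records$baseline <- records$baseline[keep, , drop = FALSE]
  if (!is.null(records$trt)) records$trt <- records$trt[keep]
  records
}

quiet_fit_lmer <- function(formula, data) {
  suppressMessages(suppressWarnings(
    tryCatch(lme4::lmer(formula, data = data, REML = TRUE,
                        control = lme4::lmerControl(calc.derivs = FALSE)),
             error = function(e) NULL)))
}

# A REML fit with (numerically) zero residual variance is degenerate: the
# optimizer sits at a boundary and the fixed effects are unreliable (e.g. the
# balanced two-subject case lands at 6.857 instead of the grand mean 7).
lmer_degenerate <- function(m, y) {
  stats::sigma(m) <= max(1e-8, 1e-6 * stats::sd(y))
}

# Generic mixed/OLS fit for one p. `fixed` is the RHS of the fixed part,
# `ran` the random-effects term (NULL for intercept-free designs).
fit_one_p <- function(d, fixed, ran, method) {
  if (method == "ols") {
    m <- stats::lm(stats::as.formula(paste("y ~", fixed)), data = d)
    co <- stats::coef(m)
    if (anyNA(co)) stop("collinear fixed-effect design (check NT/treatment coding)")
    # suppress the "essentially perfect fit" note on noise-free inputs
    se <- suppressWarnings(sqrt(diag(stats::vcov(m))))
    return(list(fixef = co, se = se, ranef_var = NULL, engine = "ols"))
  }
  m <- quiet_fit_lmer(stats::as.formula(paste("y ~", fixed, "+", ran)), d)
  engine <- "reml"
  if (is.null(m) || lme4::isSingular(m, tol = 1e-5)) {
    m2 <- quiet_fit_lmer(stats::as.formula(paste("y ~", fixed, "+ (1 | subject)")), d)
    if (!is.null(m2)) { m <- m2; engine <- "reml_intercept_only" } else m <- NULL
  }
  if (!is.null(m) && lmer_degenerate(m, d$y)) m <- NULL
  if (is.null(m)) return(fit_one_p(d, fixed, ran, "ols"))
  fe <- lme4::fixef(m)
  if (anyNA(fe)) stop("collinear fixed-effect design (check NT/treatment coding)")
  list(fixef = fe, se = sqrt(diag(as.matrix(stats::vcov(m)))),
       ranef_var = as.data.frame(lme4::VarCorr(m)), engine = engine)
}

#' Pointwise mixed model, design A (crossover exposure-response)
#'
#' Models the placebo-corrected change from baseline at one p as linear in
#' the drug concentration with correlated random intercept and slope per
#' subject: `ddTrc = (t0 + b0_i) + (t1 + b1_i) C`.
#'
#' @param records `tvv_records` built with `design = "A"`.
#' @param p Trajectory length percentage.
#' @param treatment Optional treatment label to subset to (its drug's
#'   concentration column is used).
#' @param method `"reml"` (default) or `"ols"` (fixed effects only; used by
#'   the bootstrap where subject-level uncertainty comes from resampling).
#' @return A `pointwise_fit` with elements `theta0`, `theta1`, `se`, ...
#' @export
fit_pointwise_A <- function(records, p, treatment = NULL, method = c("reml", "ols")) {
  method <- match.arg(method)
  if (!is.null(treatment)) records <- records_subset(records, records$data$treatment == treatment)
  conc <- rowSums(records$conc[, active_drugs(records), drop = FALSE])
  if (all(conc == 0)) stop("slope unidentifiable: all concentrations zero")
  if (length(unique(records$data$subject)) < 2L) stop("need >= 2 subjects")
  d <- data.frame(y = records$y[, paste0("p", p)], conc = conc,
                  subject = factor(records$data$subject))
  f <- fit_one_p(d, "conc", "(1 + conc | subject)", method)
  structure(list(design = "A", p = p, theta0 = f$fixef[["(Intercept)"]],
                 theta1 = f$fixef[["conc"]], se = f$se, ranef_var = f$ranef_var,
                 engine = f$engine),
            class = "pointwise_fit")
}

#' Pointwise mixed model, design B (phase means)
#'
#' Intercept-only mixed model per dosing phase:
#' `ddTrc = theta + eta_i`; `theta` is the population mean effect.
#'
#' @inheritParams fit_pointwise_A
#' @param phase `"morning"`, `"afternoon"` or `"evening"`.
#' @export
fit_pointwise_B <- function(records, p, phase, treatment = NULL,
                            method = c("reml", "ols")) {
  method <- match.arg(method)
  keep <- records$data$phase == phase
  if (!is.null(treatment)) keep <- keep & records$data$treatment == treatment
  if (!any(keep)) stop("no records in phase '", phase, "'")
  records <- records_subset(records, keep)
  if (length(unique(records$data$subject)) < 2L) stop("need >= 2 subjects in phase")
  d <- data.frame(y = records$y[, paste0("p", p)],
                  subject = factor(records$data$subject))
  f <- fit_one_p(d, "1", "(1 | subject)", method)
  structure(list(design = "B", p = p, phase = phase,
                 theta = f$fixef[["(Intercept)"]], se = f$se,
                 ranef_var = f$ranef_var, engine = f$engine),
            class = "pointwise_fit")
}

#' Pointwise mixed model, design C (parallel/crossover with covariates)
#'
#' Models the change from baseline at one p with treatment indicator,
#' per-drug concentration slopes (fixed + random), nominal-timepoint factor
#' (sum-to-zero contrasts so the treatment main effect stays interpretable)
#' and the centered subject baseline:
#' `dTrc = (t0 + b0_i) + t1 TRT + sum_l (t2_l + b2_il) C_l + t3_k NT_k + t4 (BL - mean BL)`.
#' The placebo-corrected drug effect at concentrations `C` is
#' `ddTrc = t1 + sum_l t2_l C_l`.
#'
#' @inheritParams fit_pointwise_A
#' @param treatment Active treatment label; the fit uses its records plus
#'   the placebo arm.
#' @export
fit_pointwise_C <- function(records, p, treatment, method = c("reml", "ols")) {
  method <- match.arg(method)
  keep <- records$data$treatment %in% c(treatment, records$placebo)
  records <- records_subset(records, keep)
  if (!any(records$trt == 0)) stop("no placebo arm present for design C fit")
  drugs <- active_drugs(records)
  if (length(drugs) == 0L) stop("no drug with non-zero concentrations")
  pcol <- paste0("p", p)
  d <- data.frame(y = records$y[, pcol], trt = records$trt,
                  bl_c = records$baseline[, pcol] - mean(records$baseline[, pcol]),
                  nt = factor(records$data$timepoint),
                  subject = factor(records$data$subject))
  ccols <- paste0("conc_", seq_along(drugs))
  for (i in seq_along(drugs)) d[[ccols[i]]] <- records$conc[, drugs[i]]
  stats::contrasts(d$nt) <- stats::contr.sum(nlevels(d$nt))
  fixed <- paste(c("trt", ccols, if (nlevels(d$nt) > 1) "nt", "bl_c"), collapse = " + ")
  ran <- paste0("(1 + ", paste(ccols, collapse = " + "), " | subject)")
  f <- fit_one_p(d, fixed, ran, method)
  structure(list(design = "C", p = p, drugs = drugs,
                 theta0 = f$fixef[["(Intercept)"]], theta1 = f$fixef[["trt"]],
                 theta2 = stats::setNames(f$fixef[ccols], drugs),
                 se = f$se, ranef_var = f$ranef_var, engine = f$engine),
            class = "pointwise_fit")
}

# drugs with any non-zero concentration in the current record subset
active_drugs <- function(records) {
  colnames(records$conc)[colSums(abs(records$conc)) > 0]
}

#' Drug-effect prediction from a pointwise fit
#'
#' Design A: `theta0 + theta1 C`; design B: `theta`; design C:
#' `theta1 + sum_l theta2_l C_l` (the model prediction at `C = 0` is the
#' intercept profile).
#'
#' @param fit A `pointwise_fit`.
#' @param conc Concentration (scalar for A; named or ordered vector over the
#'   fit's drugs for C; ignored for B).
#' @return Predicted ddTrc in ms.
#' @export
predict_pointwise <- function(fit, conc = 0) {
  if (any(conc < 0)) stop("negative concentration")
  switch(fit$design,
    A = fit$theta0 + fit$theta1 * conc,
    B = fit$theta,
    C = fit$theta1 + sum(fit$theta2 * rep_len(conc, length(fit$theta2))))
}
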