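#' Cubic B-spline basis on the trajectory-percentage grid
#'
#' Builds the basis used to parametrize p-dependent model coefficients:
#' cubic B-splines over `n_knots` equidistant breakpoints spanning
#' `[1, 100]` (boundaries included in the count), evaluated on the integer
#' grid `p = 1..100`. The basis dimension is `m = (n_knots - 2) + 4`; with
#' `n_knots = 2` (boundaries only) it is the global cubic polynomial space.
#' The basis is a partition of unity.
#'
#' @param n_knots Number of equidistant breakpoints including both
#'   boundaries; at least 2 (the defaults per study design are 8, 16, 12).
#' @param p_grid Integer evaluation grid; default `1:100`.
#' @return A `spline_basis`: list with `degree`, `breaks`, `m` and the
#'   evaluation matrix `B` (`length(p_grid) x m`).
#' @export
build_spline_basis <- function(n_knots, p_grid = 1:100) {
  if (n_knots < 2) stop("need n_knots >= 2 breakpoints")
  breaks <- seq(1, 100, length.out = n_knots)
  interior <- if (n_knots > 2) breaks[-c(1, n_knots)] else numeric(0)
  B <- splines::bs(p_grid, knots = interior, degree = 3, intercept = TRUE,
                   Boundary.knots = c(1, 100))
  B <- unclass(B); attributes(B)[c("knots", "Boundary.knots", "degree", "intercept")] <- NULL
  colnames(B) <- paste0("b", seq_len(ncol(B)))
  structure(list(degree = 3L, breaks = breaks, m = ncol(B), B = B,
                 p_grid = p_grid),
            class = "spline_basis")
}

#' @export
print.spline_basis <- function(x, ...) {
  cat(sprintf("<spline_basis> degree 3, %d breakpoints on [1, 100], m = %d\n",
              length(x$breaks), x$m))
  invisible(x)
}

default_knots <- function(design) c(A = 8L, B = 16L, C = 12L)[[design]]

# Expand a scalar covariate into m columns (covariate x basis value at the
# row's p) for the stacked-over-p data set.
expand_cols <- function(basis, p_index, covariate, prefix) {
  M <- basis$B[p_index, , drop = FALSE] * covariate
  colnames(M) <- paste0(prefix, seq_len(basis$m))
  M
}

#' Fit the functional (spline) mixed-effects model
#'
#' Joins the 100 pointwise models of a design into one linear mixed model
#' over the stacked `p = 1..100` records: every scalar covariate of the
#' pointwise model is expanded into `m` columns (covariate times basis value
#' at the row's p), so each fixed effect becomes a spline coefficient vector
#' and the fitted coefficient functions are continuous in p. Subject random
#' effects are spline-expanded likewise with a diagonal covariance.
#' Residuals are treated as independent and homoscedastic across p within an
#' ECG; single-fit standard errors are therefore not reported — inference
#' comes from [bootstrap_profiles()].
#'
#' @param records `tvv_records` from [build_analysis_dataset()].
#' @param n_knots Breakpoint count for [build_spline_basis()]; defaults to
#'   8/16/12 for designs A/B/C.
#' @param treatment,phase Optional condition subset (phase: design B).
#' @param method `"reml"` (lme4, with ML and OLS fallbacks, logged) or
#'   `"ols"` (fixed effects only; the bootstrap engine).
#' @return A `functional_model_fit`: basis, spline coefficients per effect,
#'   coefficient functions evaluated on the p grid (`theta`), `n_params`,
#'   `engine`, `converged`.
#' @export
fit_functional <- function(records, n_knots = NULL, treatment = NULL, phase = NULL,
                           method = c("reml", "ols")) {
  method <- match.arg(method)
  design <- records$design
  if (!is.null(treatment)) {
    keep <- if (design == "C") records$data$treatment %in% c(treatment, records$placebo)
            else records$data$treatment == treatment
    records <- records_subset(records, keep)
  }
  if (design == "B" && !is.null(phase)) {
    records <- records_subset(records, records$data$phase == phase)
  }
  if (nrow(records$data) == 0L) stop("no records left after subsetting")
  if (is.null(n_knots)) n_knots <- default_knots(design)
  basis <- build_spline_basis(n_knots, records$p_grid)
  m <- basis$m
  n_obs <- nrow(records$data)
  p_index <- rep(seq_along(records$p_grid), each = n_obs)
  y <- as.vector(records$y)  # column-major: all obs at p1, then p2, ...
  subject <- factor(rep(records$data$subject, times = length(records$p_grid)))

  blocks <- list()   # named list of fixed-effect column blocks
  ran_prefixes <- character(0)
  if (design == "A") {
    conc <- rep(rowSums(records$conc[, active_drugs(records), drop = FALSE]),
                times = length(records$p_grid))
    if (all(conc == 0)) stop("slope unidentifiable: all concentrations zero")
    blocks$theta0 <- expand_cols(basis, p_index, 1, "i")
    blocks$theta1 <- expand_cols(basis, p_index, conc, "c")
    ran_prefixes <- c("i", "c")
  } else if (design == "B") {
    blocks$theta <- expand_cols(basis, p_index, 1, "i")
    ran_prefixes <- "i"
  } else {
    if (!any(records$trt == 0)) stop("no placebo arm present for design C fit")
    drugs <- active_drugs(records)
    if (length(drugs) == 0L) stop("no drug with non-zero concentrations")
    trt <- rep(records$trt, times = length(records$p_grid))
    blocks$theta0 <- expand_cols(basis, p_index, 1, "i")
    blocks$theta1 <- expand_cols(basis, p_index, trt, "t")
    for (l in seq_along(drugs)) {
      cl <- rep(records$conc[, drugs[l]], times = length(records$p_grid))
      blocks[[paste0("theta2_", drugs[l])]] <- expand_cols(basis, p_index, cl,
                                                           paste0("c", l, "_"))
      ran_prefixes <- c(ran_prefixes, paste0("c", l, "_"))
    }
    nt <- factor(rep(records$data$timepoint, times = length(records$p_grid)))
    if (nlevels(nt) > 1) {
      NT <- stats::model.matrix(~nt, contrasts.arg = list(nt = "contr.sum"))[, -1, drop = FALSE]
      for (k in seq_len(ncol(NT))) {
        blocks[[paste0("theta3_", k)]] <- expand_cols(basis, p_index, NT[, k],
                                                      paste0("nt", k, "_"))
      }
    }
    bl <- as.vector(records$baseline)
    blocks$theta4 <- expand_cols(basis, p_index, bl - mean(bl), "g")
    ran_prefixes <- c("i", ran_prefixes)
  }

  X <- do.call(cbind, blocks)
  fit <- fit_functional_engine(y, X, subject, blocks, ran_prefixes, method)

  coefs <- split_block_coefs(fit$beta, blocks)
  theta <- lapply(coefs, function(cf) drop(basis$B %*% cf))
  # structural parameter count: fixed coefficients + one variance per
  # (diagonal) random-effect column + the residual variance, independent of
  # the engine actually used
  n_params <- ncol(X) + length(ran_prefixes) * m + 1L
  structure(list(design = design, basis = basis, coef = coefs, theta = theta,
                 drugs = if (design == "C") active_drugs(records) else
                         colnames(records$conc),
                 n_params = n_params, n_records = length(y),
                 engine = fit$engine, converged = fit$converged,
                 deviance = fit$deviance),
            class = "functional_model_fit")
}

fit_functional_engine <- function(y, X, subject, blocks, ran_prefixes, method) {
  if (method == "ols") {
    qf <- stats::lm.fit(X, y)
    if (any(is.na(qf$coefficients))) stop("collinear fixed-effect design")
    return(list(beta = qf$coefficients, engine = "ols", converged = TRUE,
                n_var_params = 0L, deviance = sum(qf$residuals^2)))
  }
  d <- as.data.frame(X)
  d$y <- y; d$subject <- subject
  ran_terms <- vapply(ran_prefixes, function(pref) {
    cols <- grep(paste0("^", pref, "[0-9]+$"), colnames(X), value = TRUE)
    paste0("(0 + ", paste(cols, collapse = " + "), " || subject)")
  }, character(1))
  f <- stats::as.formula(paste("y ~ 0 +", paste(colnames(X), collapse = " + "),
                               "+", paste(ran_terms, collapse = " + ")))
  m <- quiet_fit_lmer(f, d)
  engine <- "reml"
  if (is.null(m)) {
    m <- suppressMessages(suppressWarnings(
      tryCatch(lme4::lmer(f, data = d, REML = FALSE,
                          control = lme4::lmerControl(calc.derivs = FALSE)),
               error = function(e) NULL)))
    engine <- "ml"
  }
  if (is.null(m)) {
    qf <- stats::lm.fit(X, y)
    return(list(beta = qf$coefficients, engine = "ols_fallback", converged = TRUE,
                n_var_params = 0L, deviance = sum(qf$residuals^2)))
  }
  beta <- lme4::fixef(m)[colnames(X)]
  list(beta = beta, engine = engine,
       converged = length(m@optinfo$conv$lme4) == 0,
       n_var_params = length(m@theta) + 1L,
       deviance = as.numeric(stats::deviance(m, REML = FALSE)))
}

split_block_coefs <- function(beta, blocks) {
  out <- list(); k <- 0L
  for (nm in names(blocks)) {
    w <- ncol(blocks[[nm]])
    out[[nm]] <- unname(beta[(k + 1):(k + w)])
    k <- k + w
  }
  out
}

#' @export
print.functional_model_fit <- function(x, ...) {
  cat(sprintf("<functional_model_fit> design %s, m = %d, %d parameters, %d records, engine %s\n",
              x$design, x$basis$m, x$n_params, x$n_records, x$engine))
  invisible(x)
}

#' Continuous drug-effect profile from a functional fit
#'
#' Evaluates the fitted coefficient functions at the requested drug
#' concentration(s) on the p grid. Design A: `theta0(p) + theta1(p) C`;
#' design B: `theta(p)`; design C: `theta1(p) + sum_l theta2_l(p) C_l`.
#' `conc = 0` gives the zero-concentration (intercept) profile.
#'
#' @param fit A `functional_model_fit`.
#' @param conc Concentration in ng/mL (scalar; for two-drug design C
#'   conditions a vector ordered as `fit$drugs`).
#' @return An `effect_profile`: `p`, `ddTrc` (ms), empty band slots, `conc`,
#'   and the derived `p_zero`.
#' @export
predict_effect_profile <- function(fit, conc = 0) {
  if (any(conc < 0)) stop("negative concentration")
  dd <- switch(fit$design,
    A = fit$theta$theta0 + fit$theta$theta1 * conc[1],
    B = fit$theta$theta,
    C = {
      drugs <- fit$drugs
      conc <- rep_len(conc, length(drugs))
      prof <- fit$theta$theta1
      for (l in seq_along(drugs)) {
        prof <- prof + fit$theta[[paste0("theta2_", drugs[l])]] * conc[l]
      }
      prof
    })
  effect_profile(fit$basis$p_grid, dd, conc = conc)
}

#' Construct an effect profile object
#'
#' @param p Integer percentage grid.
#' @param ddTrc Effect values in ms over `p`.
#' @param lower90,upper90 Optional 90% band bounds.
#' @param conc Concentration context.
#' @return An `effect_profile` list; `p_zero` is computed on `ddTrc`.
#' @export
effect_profile <- function(p, ddTrc, lower90 = NULL, upper90 = NULL, conc = NULL) {
  structure(list(p = p, ddTrc = ddTrc, lower90 = lower90, upper90 = upper90,
                 conc = conc, p_zero = compute_pzero(ddTrc)),
            class = "effect_profile")
}

#' @export
print.effect_profile <- function(x, ...) {
  cat(sprintf("<effect_profile> ddTr(100)c = %.1f ms, p_zero = %d%%%s\n",
              x$ddTrc[length(x$ddTrc)], x$p_zero,
              if (!is.null(x$lower90)) " (with 90% band)" else ""))
  invisible(x)
}
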