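# hand-built single-p table for dataset-assembly arithmetic
tiny_table <- function() {
  data.frame(
    subject = rep(c("s1", "s2"), each = 4),
    treatment = rep(c("placebo", "placebo", "drug", "drug"), 2),
    timepoint = rep(c(0, 2), 4),
    replicate = 1,
    RR_s = 1,
    Trc_100 = c(298, 303, 300, 320,   # s1: placebo 298->303, active 300->320
                300, 300, 300, 300)   # s2: no change anywhere
  )
}

test_that("dataset assembly: replicate averaging, baselines, placebo matching", {
  rec <- build_analysis_dataset(tiny_table(), "A", p_grid = 100)
  # ddTrc = (320-300) - (303-298) = 15 for s1; 0 for s2
  expect_equal(sort(rec$y[, "p100"]), c(0, 15))
  expect_equal(rec$data$treatment, rep("drug", 2))

  # replicate averaging happens before differencing
  tab <- tiny_table()
  tab2 <- tab; tab2$replicate <- 2; tab2$Trc_100 <- tab2$Trc_100 + 4
  rec2 <- build_analysis_dataset(rbind(tab, tab2), "A", p_grid = 100)
  expect_equal(sort(rec2$y[, "p100"]), c(0, 15))  # +4 cancels in differencing

  # identical active and placebo changes give ddTrc = 0
  tab3 <- tiny_table()
  tab3$Trc_100[4] <- 305  # active change now equals placebo change (5)
  rec3 <- build_analysis_dataset(tab3, "A", p_grid = 100)
  expect_equal(unname(rec3$y[rec3$data$subject == "s1", "p100"]), 0)

  # missing matched placebo timepoint drops the active record with a warning
  tab4 <- rbind(tiny_table(),
                data.frame(subject = "s1", treatment = "drug", timepoint = 2.5,
                           replicate = 1, RR_s = 1, Trc_100 = 330))
  expect_warning(rec4 <- build_analysis_dataset(tab4, "A", p_grid = 100),
                 "s1@2.5")
  expect_equal(nrow(rec4$data), 2)

  # missing baseline drops the whole subject-period (and, in cascade, the
  # subject's now-unmatched active records), each with a warning
  tab5 <- tiny_table()[-1, ]  # s1 placebo baseline gone
  w <- capture_warnings(rec5 <- build_analysis_dataset(tab5, "A", p_grid = 100))
  expect_match(w, "baseline", all = FALSE)
  expect_match(w, "matched placebo", all = FALSE)
  expect_equal(rec5$data$subject, "s2")
})

test_that("design A pointwise fit recovers exact linear data and is linear in C", {
  set.seed(31)
  n_sub <- 6
  conc <- rep(c(100, 400, 900), times = n_sub)
  dd <- 0 + 0.03 * conc  # theta0 = 0, theta1 = 0.03, no noise
  rec <- list(design = "A",
              data = data.frame(subject = rep(letters[1:n_sub], each = 3),
                                treatment = "drug", timepoint = rep(1:3, n_sub)),
              conc = matrix(conc, dimnames = list(NULL, "drug")),
              y = matrix(dd, dimnames = list(NULL, "p100")), p_grid = 100,
              placebo = "placebo")
  class(rec) <- "tvv_records"
  fit <- fit_pointwise_A(rec, 100)
  expect_lt(abs(fit$theta0 - 0), 1e-6)
  expect_lt(abs(fit$theta1 - 0.03), 1e-6)
  # predictions are exactly linear in C
  expect_equal(predict_pointwise(fit, 200) - predict_pointwise(fit, 0),
               2 * (predict_pointwise(fit, 100) - predict_pointwise(fit, 0)))
  expect_error(predict_pointwise(fit, -5), "negative")
  rec0 <- rec; rec0$conc[] <- 0
  expect_error(fit_pointwise_A(rec0, 100), "unidentifiable")
})

test_that("design B fit is the (balanced) population mean", {
  mk <- function(y) {
    rec <- list(design = "B",
                data = data.frame(subject = rep(c("a", "b"), each = 2),
                                  treatment = "drug", timepoint = c(1, 2),
                                  phase = "morning"),
                conc = matrix(numeric(4), dimnames = list(NULL, "drug")),
                y = matrix(y, dimnames = list(NULL, "p50")), p_grid = 50,
                placebo = "placebo")
    class(rec) <- "tvv_records"
    rec
  }
  expect_equal(fit_pointwise_B(mk(rep(7, 4)), 50, "morning")$theta, 7,
               tolerance = 1e-8)
  expect_equal(fit_pointwise_B(mk(c(5, 5, 9, 9)), 50, "morning")$theta, 7,
               tolerance = 1e-6)
  expect_error(fit_pointwise_B(mk(rep(7, 4)), 50, "evening"), "phase")
})

test_that("design C fit separates treatment effect and concentration slope", {
  set.seed(41)
  sim <- simulate_study_quantiles("C", n_subjects = 20,
    timepoints = c(0, 1, 2, 4, 8), n_replicates = 3,
    drugs = list(drug = list(cmax = 1000, g = function(p) rep(5, length(p)))),
    seed = 41, p_grid = c(50, 100))
  tabc <- apply_hr_correction(sim$table, true_alpha_profile(p_grid = c(50, 100)))
  rec <- build_analysis_dataset(tabc, "C", sim$pk, p_grid = c(50, 100))
  fit <- fit_pointwise_C(rec, 100, "drug")
  # truth: theta1 = 0, theta2 = 5 / 1000 per ng/mL -> dd at cref = 5 ms
  dd <- predict_pointwise(fit, 1000)
  se_dd <- sqrt(sum(fit$se[c("trt", "conc_1")]^2 * c(1, 1000^2)))
  expect_lt(abs(dd - 5), 2 * se_dd + 1)
  # prediction at C = 0 equals the treatment intercept theta1
  expect_equal(predict_pointwise(fit, 0), fit$theta1)
  # no placebo arm is an error
  rec_nopla <- tvv:::records_subset(rec, rec$data$treatment != "placebo")
  expect_error(fit_pointwise_C(rec_nopla, 100, "drug"), "placebo")
})

test_that("design A 90% CIs achieve nominal coverage over replicates", {
  # simulate straight from the design-A generating equation at one p
  theta0 <- 1; theta1 <- 0.02
  n_sub <- 8; n_tp <- 6
  conc0 <- rep(seq(100, 1000, length.out = n_tp), n_sub)
  subj <- rep(letters[1:n_sub], each = n_tp)
  set.seed(99)
  cover <- logical(200)
  for (r in seq_len(200)) {
    eta0 <- rnorm(n_sub, 0, 1.5)[match(subj, letters[1:n_sub])]
    eta1 <- rnorm(n_sub, 0, 0.005)[match(subj, letters[1:n_sub])]
    dd <- (theta0 + eta0) + (theta1 + eta1) * conc0 + rnorm(length(conc0), 0, 1)
    rec <- list(design = "A",
                data = data.frame(subject = subj, treatment = "drug",
                                  timepoint = rep(1:n_tp, n_sub)),
                conc = matrix(conc0, dimnames = list(NULL, "drug")),
                y = matrix(dd, dimnames = list(NULL, "p100")), p_grid = 100,
                placebo = "placebo")
    class(rec) <- "tvv_records"
    fit <- fit_pointwise_A(rec, 100)
    # t-based interval with subject-level degrees of freedom (standard for
    # these small crossover studies; the Wald z interval undercovers)
    ci <- fit$theta1 + c(-1, 1) * qt(0.95, n_sub - 1) * fit$se[["conc"]]
    cover[r] <- ci[1] <= theta1 && theta1 <= ci[2]
  }
  expect_gte(mean(cover), 0.85)
  expect_lte(mean(cover), 0.95)
})
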