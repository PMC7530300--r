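test_that("spline basis: partition of unity, dimension, degenerate cases", {
  for (k in c(2, 8, 12, 16)) {
    b <- build_spline_basis(k)
    expect_equal(b$m, (k - 2) + 4)
    expect_equal(rowSums(b$B), rep(1, 100), tolerance = 1e-12)
    expect_true(all(b$B >= 0))
  }
  expect_equal(build_spline_basis(8)$m, 10)
  expect_equal(build_spline_basis(2)$m, 4)  # global cubic polynomial space
  expect_error(build_spline_basis(1), "n_knots")
})

# small design-A records object generated directly from the model equation,
# with theta0(p), theta1(p) supplied as functions
make_A_records <- function(theta0, theta1, n_sub = 8, sd_eta0 = 0, sd_eta1 = 0,
                           sd_eps = 0, seed = 1, p_grid = 1:100) {
  set.seed(seed)
  conc0 <- rep(c(0.2, 0.5, 1, 0.7) * 1000, n_sub)
  subj <- rep(sprintf("s%02d", 1:n_sub), each = 4)
  n <- length(conc0)
  e0 <- rnorm(n_sub, 0, sd_eta0)[rep(1:n_sub, each = 4)]
  e1 <- rnorm(n_sub, 0, sd_eta1)[rep(1:n_sub, each = 4)]
  y <- sapply(p_grid, function(p) {
    (theta0(p) + e0) + (theta1(p) + e1) * conc0 + rnorm(n, 0, sd_eps)
  })
  colnames(y) <- paste0("p", p_grid)
  rec <- list(design = "A",
              data = data.frame(subject = subj, treatment = "drug",
                                timepoint = rep(1:4, n_sub)),
              conc = matrix(conc0, dimnames = list(NULL, "drug")),
              y = y, p_grid = p_grid, placebo = "placebo")
  class(rec) <- "tvv_records"
  rec
}

test_that("constant-in-p truth is reproduced (constants lie in every spline space)", {
  rec <- make_A_records(function(p) 3, function(p) 0.01)
  for (m in c("reml", "ols")) {
    fit <- fit_functional(rec, method = m)
    prof <- predict_effect_profile(fit, 1000)
    expect_lt(max(abs(prof$ddTrc - 13)), 0.1)
  }
})

test_that("a spline-representable coefficient function is recovered", {
  basis <- build_spline_basis(8)
  set.seed(13)
  cf <- rnorm(basis$m, 0.02, 0.01)
  theta1_true <- drop(basis$B %*% cf)
  rec <- make_A_records(function(p) 0, function(p) theta1_true[p],
                        sd_eps = 0.5, seed = 3)
  fit <- fit_functional(rec, n_knots = 8, method = "ols")
  est <- (predict_effect_profile(fit, 1000)$ddTrc -
            predict_effect_profile(fit, 0)$ddTrc) / 1000
  expect_lt(max(abs(est - theta1_true)), 0.5 / 1000 * 50)  # well under noise scale
})

test_that("functional and pointwise fits agree on design-A data", {
  rec <- make_A_records(function(p) 0, function(p) transition_effect(45, 30)(p) / 1000,
                        sd_eta0 = 1, sd_eta1 = 0.002, sd_eps = 1, seed = 8)
  fit <- fit_functional(rec, method = "reml")
  prof <- predict_effect_profile(fit, 1000)$ddTrc
  pw <- vapply(1:100, function(p) {
    predict_pointwise(fit_pointwise_A(rec, p), 1000)
  }, numeric(1))
  expect_lt(max(abs(prof - pw)), 2)
})

test_that("profiles are smooth: third differences bounded by the basis", {
  rec <- make_A_records(function(p) 0, function(p) transition_effect(45, 30)(p) / 1000,
                        sd_eps = 2, seed = 5)
  fit <- fit_functional(rec, method = "ols")
  prof <- predict_effect_profile(fit, 1000)$ddTrc
  # bound: |d3 profile| <= sum_j |coef_j| * max|d3 B_j| (triangle inequality)
  cf_total <- fit$coef$theta0 + fit$coef$theta1 * 1000
  d3B <- apply(fit$basis$B, 2, function(col) max(abs(diff(col, differences = 3))))
  expect_lte(max(abs(diff(prof, differences = 3))),
             sum(abs(cf_total) * d3B) + 1e-9)
})

test_that("design C parameter count reconstructs the published complexity", {
  # two drugs, 12 knots, 21 nominal timepoints: fixed 14*(1+1+2+1) + 20*14,
  # diagonal random effects (1 + 2 drugs) * 14, residual 1 -> 407
  set.seed(17)
  n_sub <- 24
  tps <- seq_len(21)
  subj <- rep(sprintf("s%02d", 1:n_sub), each = length(tps))
  trt <- rep(rep(c("placebo", "combo"), n_sub / 2), each = length(tps))
  n <- length(subj)
  # per-subject PK noise keeps the two concentration columns and the
  # timepoint factor from being exactly collinear
  conc <- cbind(d1 = ifelse(trt == "combo",
                            (500 + 100 * rep(tps, n_sub)) * exp(rnorm(n, 0, 0.2)), 0),
                d2 = ifelse(trt == "combo",
                            (200 + 50 * rep(tps, n_sub)) * exp(rnorm(n, 0, 0.2)), 0))
  p_grid <- 1:100
  y <- matrix(rnorm(n * 100), n, 100, dimnames = list(NULL, paste0("p", p_grid)))
  rec <- list(design = "C",
              data = data.frame(subject = subj, treatment = trt,
                                timepoint = rep(tps, n_sub)),
              conc = conc, y = y,
              baseline = matrix(300 + rnorm(n), n, 100,
                                dimnames = list(NULL, paste0("p", p_grid))),
              trt = as.numeric(trt != "placebo"), p_grid = p_grid,
              placebo = "placebo")
  class(rec) <- "tvv_records"
  fit <- fit_functional(rec, n_knots = 12, treatment = "combo", method = "ols")
  expect_lt(abs(fit$n_params - 406) / 406, 0.15)
})

test_that("prediction is linear in concentration and rejects negative C", {
  rec <- make_A_records(function(p) 1, function(p) 0.01, sd_eps = 0.5, seed = 2)
  fit <- fit_functional(rec, method = "ols")
  p0 <- predict_effect_profile(fit, 0)$ddTrc
  p1 <- predict_effect_profile(fit, 500)$ddTrc
  p2 <- predict_effect_profile(fit, 1000)$ddTrc
  expect_equal(p2 - p0, 2 * (p1 - p0), tolerance = 1e-9)
  expect_error(predict_effect_profile(fit, -1), "negative")
})
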