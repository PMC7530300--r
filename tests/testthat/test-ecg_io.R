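sample_record <- function(seed = 1, jitter = 0, noise = 0) {
  set.seed(seed)
  simulate_ecg(rr_s = 0.9, duration_s = 5, jitter_sd_ms = jitter,
               noise_mv = noise, meta = list(subject = "S01"))
}

test_that("write/read round trip preserves all three formats", {
  ecg <- sample_record()
  tmp <- withr::local_tempdir()
  for (fmt in c("wfdb", "aecg", "csv")) {
    path <- switch(fmt, wfdb = file.path(tmp, "rec"),
                   aecg = file.path(tmp, "rec.xml"),
                   csv = file.path(tmp, "rec.csv"))
    write_annotated_ecg(ecg, path, fmt)
    back <- load_annotated_ecg(path, fmt)
    tol <- if (fmt == "csv") 1e-12 else 5.01e-4  # wfdb/aecg quantize at 1 uV
    expect_lt(max(abs(back$signal - ecg$signal)), tol)
    expect_equal(back$beats[, 1:4], ecg$beats[, 1:4])
    expect_equal(back$fs, 500)
    # second round trip is exact (values already on the amplitude grid)
    path2 <- switch(fmt, wfdb = file.path(tmp, "rec2"),
                    aecg = file.path(tmp, "rec2.xml"),
                    csv = file.path(tmp, "rec2.csv"))
    write_annotated_ecg(back, path2, fmt)
    back2 <- load_annotated_ecg(path2, fmt)
    expect_equal(back2$signal, back$signal, tolerance = 1e-12)
  }
})

test_that("annotation times in ms convert to sample indices at fs", {
  ecg <- sample_record()
  ecg$beats$t_end[1] <- 201  # 402 ms at 500 Hz
  tmp <- file.path(withr::local_tempdir(), "rec.xml")
  write_annotated_ecg(ecg, tmp, "aecg")
  doc <- xml2::read_xml(tmp)
  tend <- xml2::xml_find_first(
    doc, ".//h:beat[@index='1']/h:annotation[@code='MDC_ECG_WAVC_TWAVE_END']",
    c(h = "urn:hl7-org:v3"))
  expect_equal(as.numeric(xml2::xml_attr(tend, "value")), 402)
  back <- load_annotated_ecg(tmp, "aecg")
  expect_equal(back$beats$t_end[1], 201)
})

test_that("records at other sampling frequencies are normalised to 500 Hz", {
  ecg <- sample_record()
  # fabricate a 250 Hz version by decimation
  half <- ecg$signal[seq(1, nrow(ecg$signal), by = 2), ]
  b <- ecg$beats[, 1:4]
  b[] <- round(as.matrix(b) / 2)
  low <- annotated_ecg(half, 250, b)
  tmp <- file.path(withr::local_tempdir(), "rec")
  write_annotated_ecg(low, tmp, "wfdb")
  back <- load_annotated_ecg(tmp, "wfdb")
  expect_equal(back$fs, 500)
  expect_equal(nrow(back$signal), 2 * nrow(half) - 1)
  expect_equal(back$beats$q_on, low$beats$q_on * 2)
})

test_that("missing leads are fatal and missing annotations mark beats unusable", {
  ecg <- sample_record()
  expect_error(annotated_ecg(ecg$signal[, setdiff(tvv_lead_order(), "V3")],
                             500, ecg$beats),
               "V3")
  b <- ecg$beats[, 1:4]
  b$t_end[2] <- NA
  e2 <- annotated_ecg(ecg$signal, 500, b)
  expect_false(e2$beats$is_usable[2])
  expect_true(all(e2$beats$is_usable[-2]))
  expect_error(load_annotated_ecg(file.path(tempdir(), "nope"), "wfdb"), "missing")
})

test_that("baseline correction removes offsets, drifts, and is idempotent", {
  # signal zero in every PQ window, arbitrary elsewhere: spline is zero
  spike <- function(t, l) ifelse(t %% 1 > 0.3 & t %% 1 < 0.6, 0.8, 0)
  e0 <- make_test_ecg(spike)
  expect_equal(baseline_correct(e0)$signal, e0$signal, tolerance = 1e-12)

  # constant offset removed exactly
  ec <- make_test_ecg(function(t, l) rep(if (l == "II") 0.3 else 0.1, length(t)))
  cor <- baseline_correct(ec)
  expect_lt(max(abs(cor$signal)), 1e-9)

  # linear drift 0 -> 1 mV over 10 s: residual PQ medians below 0.02 mV,
  # and agreement with an explicit spline-through-nodes oracle
  ed <- make_test_ecg(function(t, l) t / 10)
  cord <- baseline_correct(ed)
  fs <- ed$fs
  for (b in seq_len(nrow(ed$beats))) {
    w <- seq(round(ed$beats$q_on[b] - 0.040 * fs), round(ed$beats$q_on[b] - 0.010 * fs))
    expect_lt(abs(median(cord$signal[w + 1, "V2"])), 0.02)
  }
  w_lo <- round(ed$beats$q_on - 0.040 * fs); w_hi <- round(ed$beats$q_on - 0.010 * fs)
  nx <- (w_lo + w_hi) / 2
  ny <- mapply(function(lo, hi) median(ed$signal[(lo + 1):(hi + 1), "V5"]), w_lo, w_hi)
  base <- spline(nx, ny, xout = seq_len(nrow(ed$signal)) - 1, method = "natural")$y
  expect_equal(cord$signal[, "V5"], ed$signal[, "V5"] - base, tolerance = 1e-12)

  # idempotence
  twice <- baseline_correct(cord)
  expect_lt(max(abs(twice$signal - cord$signal)), 1e-6)

  one_beat <- ed
  one_beat$beats <- one_beat$beats[1, ]
  expect_error(baseline_correct(one_beat), "insufficient beats")
})

test_that("bessel low-pass has unit DC gain, flat passband, strong stopband", {
  const <- make_test_ecg(function(t, l) rep(1, length(t)))
  out <- bessel_lowpass(const)
  expect_lt(max(abs(out$signal - 1)), 1e-6)

  fs <- 500
  amp_after <- function(freq) {
    e <- make_test_ecg(function(t, l) sin(2 * pi * freq * t))
    y <- bessel_lowpass(e)$signal[, 1]
    max(abs(y[1000:4000]))  # steady-state section
  }
  expect_gt(amp_after(5), 0.98)   # passband within 2%
  a100 <- amp_after(100)
  expect_lt(a100, 0.15)
  # oracle: squared single-pass analog response at 100/36 normalized frequency
  expect_lt(a100, bessel4_analog_mag(100 / 36)^2 * 1.10)
  expect_error(bessel_lowpass(const, cutoff_hz = 250), "Nyquist")
})

test_that("bidirectional filtering has zero phase lag", {
  e <- make_test_ecg(function(t, l) sin(2 * pi * 7 * t) + 0.5 * cos(2 * pi * 13 * t))
  y <- bessel_lowpass(e)$signal[, 1]
  x <- e$signal[, 1]
  cc <- ccf(y, x, lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})
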