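# Shared fixtures and independent oracles. Everything is generated in code;
# no stored data.

# Brute-force trajectory-quantile oracle: explicit loop over cumulative chord
# length with linear interpolation. Kept deliberately independent of
# trajectory_quantiles() (no shared helpers).
oracle_quantiles <- function(pts, fs, p_grid = 1:100) {
  n <- nrow(pts)
  cl <- numeric(n)
  for (i in 2:n) cl[i] <- cl[i - 1] + sqrt(sum((pts[i, ] - pts[i - 1, ])^2))
  L <- cl[n]
  out <- numeric(length(p_grid))
  for (k in seq_along(p_grid)) {
    target <- p_grid[k] / 100 * L
    i <- 1L
    while (cl[i] < target && i < n) i <- i + 1L
    if (i == 1L) {
      out[k] <- 0
    } else {
      f <- (target - cl[i - 1]) / (cl[i] - cl[i - 1])
      out[k] <- ((i - 2) + f) * 1000 / fs
    }
  }
  out
}

# Analog magnitude response of the -3dB-normalised 4-pole Bessel low-pass,
# evaluated straight from the reversed Bessel polynomial (independent of the
# package's pole-based design path).
bessel4_analog_mag <- function(w_rel) {
  bessel_poly <- function(s) s^4 + 10 * s^3 + 45 * s^2 + 105 * s + 105
  mag <- function(w) Mod(105 / bessel_poly(complex(real = 0, imaginary = w)))
  # -3 dB frequency of the delay-normalised prototype
  w3 <- uniroot(function(w) mag(w)^2 - 0.5, c(0.5, 5), tol = 1e-12)$root
  vapply(w_rel, function(w) mag(w * w3), numeric(1))
}

# Independent p_zero oracle: dumb full scan over all sign transitions.
oracle_pzero <- function(dd) {
  if (all(dd < 0)) return(length(dd))
  if (all(dd >= 0)) return(1L)
  best <- NA_integer_
  for (p in seq_len(length(dd) - 1)) {
    if (dd[p] < 0 && dd[p + 1] >= 0) best <- p
  }
  if (is.na(best)) { if (dd[length(dd)] < 0) length(dd) else 1L } else best
}

# Minimal annotated ECG built from an explicit signal function of time (s).
make_test_ecg <- function(f, fs = 500, duration_s = 10,
                          beat_starts = seq(0, duration_s - 1, by = 1),
                          meta = list()) {
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  sig <- sapply(tvv_lead_order(), function(l) f(t, l))
  colnames(sig) <- tvv_lead_order()
  beats <- data.frame(p_on = round((beat_starts + 0.02) * fs),
                      q_on = round((beat_starts + 0.15) * fs),
                      j_point = round((beat_starts + 0.30) * fs),
                      t_end = round((beat_starts + 0.60) * fs))
  annotated_ecg(sig, fs, beats, meta)
}

# alpha_profile carrying the generating exponents (bypasses estimation where
# a test targets a downstream stage only)
true_alpha_profile <- function(alpha_fun = alpha_ramp, p_grid = 1:100) {
  out <- data.frame(p = p_grid, alpha = alpha_fun(p_grid), se = 0,
                    log_beta = log(base_trajectory_curve(p_grid)),
                    fallback = "none")
  class(out) <- c("alpha_profile", "data.frame")
  out
}
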