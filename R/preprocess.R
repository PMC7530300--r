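#' Isoelectric baseline correction
#'
#' Adjusts every lead to its isoelectric line. For each usable beat the
#' baseline node is the median amplitude over the PQ window
#' `[q_on - 40 ms, q_on - 10 ms]` (the isoelectric PR segment), placed at the
#' window midpoint. A natural cubic spline through the nodes is evaluated at
#' every sample and subtracted; beyond the first/last node the natural
#' spline's linear extrapolation is used (this keeps the correction exact --
#' and idempotent -- for linear drifts; constant extrapolation would leak an
#' edge residual into the first and last PQ windows). Fitted per lead. With
#' 2 or 3 nodes the natural spline degrades gracefully to lower-order
#' interpolation.
#'
#' @param ecg An `annotated_ecg` with at least 2 usable beats.
#' @return The corrected `annotated_ecg`.
#' @export
baseline_correct <- function(ecg) {
  beats <- ecg$beats[ecg$beats$is_usable, , drop = FALSE]
  if (nrow(beats) < 2L) stop("insufficient beats for baseline")
  fs <- ecg$fs
  n <- nrow(ecg$signal)
  w_lo <- pmax(0, round(beats$q_on - 0.040 * fs))
  w_hi <- pmax(w_lo + 1, round(beats$q_on - 0.010 * fs))
  node_x <- (w_lo + w_hi) / 2
  x_all <- seq_len(n) - 1L
  sig <- ecg$signal
  for (lead in colnames(sig)) {
    node_y <- mapply(function(lo, hi) stats::median(sig[(lo + 1):(hi + 1), lead]),
                     w_lo, w_hi)
    base <- stats::spline(node_x, node_y, xout = x_all, method = "natural")$y
    sig[, lead] <- sig[, lead] - base
  }
  ecg$signal <- sig
  ecg
}

## ---- 4-pole Bessel low-pass -------------------------------------------------

# Analog prototype: poles of the degree-4 reversed Bessel polynomial
# s^4 + 10 s^3 + 45 s^2 + 105 s + 105, rescaled so the magnitude response is
# -3 dB at omega = 1. No filter-design package ships with the image, so the
# design is done here from first principles and checked in the tests against
# magnitude oracles evaluated directly on the polynomial.
bessel4_analog_poles <- function() {
  poles <- polyroot(c(105, 105, 45, 10, 1))  # ascending coefficients
  gain <- 105
  mag2 <- function(w) {
    h <- gain / prod(complex(real = 0, imaginary = w) - poles)
    Mod(h)^2
  }
  w3db <- stats::uniroot(function(w) mag2(w) - 0.5, c(0.5, 5), tol = 1e-12)$root
  list(poles = poles / w3db, gain = gain / w3db^4)
}

# Digital coefficients (b, a) for a single forward pass via bilinear transform
# with prewarping of the cutoff frequency.
bessel4_coefficients <- function(cutoff_hz, fs) {
  proto <- bessel4_analog_poles()
  warped <- 2 * fs * tan(pi * cutoff_hz / fs)
  pa <- proto$poles * warped
  pz <- (2 * fs + pa) / (2 * fs - pa)
  a <- Re(poly_from_roots(pz))
  b <- Re(poly_from_roots(rep(-1 + 0i, 4)))
  # normalise DC gain (z = 1) to unity
  b <- b * sum(a) / sum(b)
  list(b = b, a = a)
}

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

# Direct-form IIR filtering with zero initial state (vectorised MA part,
# C-level recursion for the AR part).
iir_filter <- function(b, a, x) {
  n <- length(x)
  u <- b[1] * x
  for (k in 2:length(b)) u <- u + b[k] * c(rep(0, k - 1), x[seq_len(n - k + 1)])
  as.numeric(stats::filter(u, -a[-1], method = "recursive"))
}

#' Zero-phase low-pass Bessel filter
#'
#' Applies a 4-pole low-pass Bessel filter forward and then backward
#' (zero phase lag, squared magnitude response) to every lead. Edge
#' transients are controlled by odd-reflection padding. DC gain is exactly 1
#' per pass.
#'
#' @param ecg An `annotated_ecg`.
#' @param cutoff_hz Cutoff (-3 dB per pass) in Hz; must be below Nyquist.
#' @return The filtered `annotated_ecg`.
#' @export
bessel_lowpass <- function(ecg, cutoff_hz = 36) {
  if (ecg$fs <= 2 * cutoff_hz) stop("cutoff at or above Nyquist frequency")
  co <- bessel4_coefficients(cutoff_hz, ecg$fs)
  ecg$signal <- apply(ecg$signal, 2, function(x) filtfilt_pad(co$b, co$a, x))
  colnames(ecg$signal) <- tvv_lead_order()
  ecg
}

filtfilt_pad <- function(b, a, x) {
  n <- length(x)
  np <- min(n - 1L, 250L)
  # odd reflection about the end points suppresses edge transients
  pre <- 2 * x[1] - x[seq(np + 1, 2)]
  post <- 2 * x[n] - x[seq(n - 1, n - np)]
  y <- iir_filter(b, a, c(pre, x, post))
  y <- rev(iir_filter(b, a, rev(y)))
  y[(np + 1):(np + n)]
}
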