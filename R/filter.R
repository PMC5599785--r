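# IIR band-pass filtering.
#
# No DSP package is assumed: the Butterworth design (analog prototype ->
# lowpass-to-bandpass transform -> bilinear transform) and the zero-phase
# forward-backward pass are implemented here as second-order sections.
# Recursion is delegated to stats::filter(), which runs in C.

#' Design a Butterworth band-pass filter as second-order sections
#'
#' Prototype order `order` yields a band-pass of order `2*order`; the default
#' order 4 gives an asymptotic roll-off of about 24 dB per octave on each
#' side for a single pass. Corner frequencies are the -3 dB (half-power)
#' points. Second-order-section form keeps narrow low-frequency bands (e.g.
#' 0.5-4 Hz at 512 Hz sampling) numerically stable where a single
#' transfer-function polynomial would not be.
#'
#' @param low,high Corner frequencies in Hz, `0 < low < high < fs/2`.
#' @param fs Sampling rate in Hz.
#' @param order Prototype (per-edge) order; default 4.
#' @return Numeric matrix with one row per biquad section, columns
#'   `b0,b1,b2,a0,a1,a2` (a0 = 1).
#' @export
butter_bandpass <- function(low, high, fs, order = 4) {
  if (low <= 0 || high <= low) stop("need 0 < low < high")
  if (high >= fs / 2) {
    stop("upper band edge (", high, " Hz) must lie below Nyquist (",
         fs / 2, " Hz)")
  }
  stopifnot(order >= 1)
  fs2 <- 2 * fs
  # pre-warped analog edge frequencies
  wl <- fs2 * tan(pi * low / fs)
  wh <- fs2 * tan(pi * high / fs)
  w0 <- sqrt(wl * wh)
  bw <- wh - wl
  # Butterworth lowpass prototype poles (unit circle, left half-plane)
  theta <- pi * (2 * seq_len(order) - 1) / (2 * order)
  p_lp <- complex(real = -sin(theta), imaginary = cos(theta))
  # lowpass -> bandpass: each prototype pole maps to a pair
  pb <- unlist(lapply(p_lp, function(p) {
    b2 <- p * bw / 2
    disc <- sqrt(b2^2 - w0^2)
    c(b2 + disc, b2 - disc)
  }))
  # bilinear transform; analog zeros (order of them, at s = 0) map to z = 1,
  # degree balancing adds `order` zeros at z = -1
  pd <- (fs2 + pb) / (fs2 - pb)
  gain <- Re(bw^order * fs2^order / prod(fs2 - pb))
  # pair poles into real-coefficient biquads
  cpx <- pd[Im(pd) > 1e-10]
  re <- sort(Re(pd[abs(Im(pd)) <= 1e-10]))
  dens <- lapply(cpx, function(p) c(1, -2 * Re(p), Mod(p)^2))
  if (length(re) > 0) {
    if (length(re) %% 2 != 0) stop("internal: unpaired real pole")
    for (m in seq(1, length(re), by = 2)) {
      dens[[length(dens) + 1]] <- c(1, -(re[m] + re[m + 1]), re[m] * re[m + 1])
    }
  }
  sos <- t(vapply(seq_along(dens), function(m) {
    g <- if (m == 1) gain else 1
    c(g * c(1, 0, -1), dens[[m]])  # one zero at +1, one at -1 per section
  }, numeric(6)))
  if (any(Mod(pd) >= 1)) stop("internal: unstable filter design")
  sos
}

#' Complex frequency response of a second-order-section filter
#'
#' @param sos Section matrix from [butter_bandpass()].
#' @param f Frequencies in Hz at which to evaluate.
#' @param fs Sampling rate in Hz.
#' @return Complex vector `H(f)` for a single (one-directional) pass.
#' @export
sos_freq_response <- function(sos, f, fs) {
  z <- exp(-2i * pi * f / fs)
  H <- rep(1 + 0i, length(z))
  for (m in seq_len(nrow(sos))) {
    H <- H * (sos[m, 1] + sos[m, 2] * z + sos[m, 3] * z^2) /
      (sos[m, 4] + sos[m, 5] * z + sos[m, 6] * z^2)
  }
  H
}

# single forward pass of one biquad over a vector, zero initial conditions
biquad_pass <- function(b, a, x) {
  nb <- length(b)
  v <- stats::filter(c(rep(0, nb - 1), x), b, method = "convolution",
                     sides = 1)
  v <- as.numeric(v)[nb:(nb + length(x) - 1)]
  as.numeric(stats::filter(v, -a[-1], method = "recursive"))
}

#' Zero-phase (forward-backward) filtering with a section cascade
#'
#' Applies every section forward then backward, squaring the magnitude
#' response and cancelling phase. Edges are handled by odd-symmetric
#' extension of length `padlen` before filtering (mirroring about the first
#' and last sample), which suppresses start-up transients.
#'
#' @param sos Section matrix from [butter_bandpass()].
#' @param x Numeric vector (one channel).
#' @param padlen Extension length in samples; capped at `length(x) - 1`.
#' @return Filtered vector, same length as `x`.
#' @export
sos_filtfilt <- function(sos, x, padlen = 3 * 2 * (nrow(sos) + 1)) {
  n <- length(x)
  padlen <- min(padlen, n - 1)
  if (padlen > 0) {
    pre <- 2 * x[1] - x[(padlen + 1):2]
    post <- 2 * x[n] - x[(n - 1):(n - padlen)]
    y <- c(pre, x, post)
  } else {
    y <- x
  }
  for (m in seq_len(nrow(sos))) y <- biquad_pass(sos[m, 1:3], sos[m, 4:6], y)
  y <- rev(y)
  for (m in seq_len(nrow(sos))) y <- biquad_pass(sos[m, 1:3], sos[m, 4:6], y)
  y <- rev(y)
  if (padlen > 0) y <- y[(padlen + 1):(padlen + n)]
  y
}
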