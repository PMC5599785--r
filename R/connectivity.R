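# Phase lag index connectivity from Hilbert-transform instantaneous phases.

# analytic signal of one real vector via the FFT one-sided spectrum
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase of every channel of an epoch
#'
#' Phase of the analytic signal (Hilbert transform) per channel per sample,
#' wrapped to (-pi, pi]. Constant channels have no defined phase and are
#' rejected.
#'
#' @param epoch Numeric channels x samples matrix.
#' @param fs Sampling rate in Hz (carried along for provenance).
#' @param trim Samples dropped from each end of the phase matrix, where the
#'   finite-length analytic signal is least reliable. Default 0: on
#'   4096-sample epochs end effects are negligible at band frequencies.
#' @return A `phase_epoch`: list with `phases` (channels x samples matrix of
#'   radians) and `fs`.
#' @export
instantaneous_phase <- function(epoch, fs, trim = 0) {
  stopifnot(is.matrix(epoch), is.numeric(epoch))
  if (ncol(epoch) < 64) {
    stop("epoch too short for phase estimation (", ncol(epoch),
         " samples; need >= 64)")
  }
  constant <- apply(epoch, 1, function(ch) diff(range(ch)) == 0)
  if (any(constant)) {
    stop("constant channel(s) have undefined phase: row ",
         paste(which(constant), collapse = ", "))
  }
  ph <- t(apply(epoch, 1, function(ch) Arg(analytic_signal(ch))))
  if (trim > 0) {
    if (2 * trim >= ncol(ph)) stop("trim removes every sample")
    ph <- ph[, (trim + 1):(ncol(ph) - trim), drop = FALSE]
  }
  rownames(ph) <- rownames(epoch)
  structure(list(phases = ph, fs = fs), class = "phase_epoch")
}

#' Phase lag index of two phase series
#'
#' `PLI = |mean(sign(sin(phi_a - phi_b)))|`: the absolute mean sign of the
#' instantaneous phase difference's sine. 0 means no consistent nonzero lag
#' (including exact zero-lag coupling, which volume conduction produces);
#' 1 means a perfectly consistent lead or lag. `sign(0)` contributes 0.
#'
#' @param phase_a,phase_b Numeric vectors of phases in radians, equal length.
#' @return Scalar in \[0, 1\], symmetric in its arguments.
#' @export
pli_pair <- function(phase_a, phase_b) {
  if (length(phase_a) != length(phase_b)) {
    stop("phase series differ in length (", length(phase_a), " vs ",
         length(phase_b), ")")
  }
  if (length(phase_a) == 0) stop("empty phase series")
  abs(mean(sign(sin(phase_a - phase_b))))
}

#' Phase-lag-index matrix of an epoch
#'
#' Applies [pli_pair()] to every unordered channel pair. Uses the identity
#' sin(a - b) = sin(a)cos(b) - cos(a)sin(b) so the trigonometric transforms
#' are computed once per channel.
#'
#' @param pe A `phase_epoch` from [instantaneous_phase()].
#' @return Symmetric numeric matrix with zero diagonal, entries in \[0, 1\],
#'   dimnames set to the channel labels.
#' @export
pli_matrix <- function(pe) {
  stopifnot(inherits(pe, "phase_epoch"))
  ph <- pe$phases
  n <- nrow(ph)
  if (n < 2) stop("need at least 2 channels")
  S <- sin(ph)
  C <- cos(ph)
  W <- matrix(0, n, n, dimnames = list(rownames(ph), rownames(ph)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      w <- abs(mean(sign(S[i, ] * C[j, ] - C[i, ] * S[j, ])))
      W[i, j] <- w
      W[j, i] <- w
    }
  }
  W
}

#' Element-wise mean of connectivity matrices
#'
#' Aggregates per-epoch PLI matrices into one subject-level matrix.
#'
#' @param mats Non-empty list of same-dimension matrices with identical
#'   dimnames.
#' @return Matrix of the same shape.
#' @export
average_pli <- function(mats) {
  if (!is.list(mats) || length(mats) == 0) stop("need a non-empty list")
  ref <- rownames(mats[[1]])
  for (m in mats) {
    if (!identical(dim(m), dim(mats[[1]])) || !identical(rownames(m), ref)) {
      stop("connectivity matrices differ in shape or channel labels")
    }
  }
  Reduce(`+`, mats) / length(mats)
}

#' Mean connectivity over all channel pairs
#'
#' Arithmetic mean of the strictly-upper-triangle entries; the global
#' connectivity summary reported alongside the tree metrics.
#'
#' @param m Symmetric connectivity matrix, n >= 2.
#' @return Scalar in \[0, 1\].
#' @export
mean_pli <- function(m) {
  stopifnot(is.matrix(m))
  if (nrow(m) < 2) stop("need at least 2 channels")
  mean(m[upper.tri(m)])
}

#' Write / read a connectivity matrix as labelled TSV
#'
#' Dense tab-separated text with a header row of channel labels.
#'
#' @param m Connectivity matrix with dimnames.
#' @param path File path.
#' @return `path` (write) or the matrix (read).
#' @export
write_connectivity <- function(m, path) {
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' @rdname write_connectivity
#' @export
read_connectivity <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(d)
  dimnames(m) <- list(colnames(m), colnames(m))
  m
}
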