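# Preprocessing chain: re-reference -> band-pass -> epoch -> artifact screen.

#' Re-reference a recording to the mean of chosen channels
#'
#' Subtracts the mean of the named reference channels (classically the
#' bilateral mastoids TP9/TP10) from every channel and drops the reference
#' channels from the output.
#'
#' @param rec An [eeg_recording()].
#' @param ref_labels Character vector of reference channel labels.
#' @return Re-referenced [eeg_recording()] without the reference channels.
#' @export
rereference <- function(rec, ref_labels) {
  stopifnot(inherits(rec, "eeg_recording"))
  absent <- setdiff(ref_labels, rec$channel_labels)
  if (length(absent) > 0) {
    stop("reference channel(s) not present in recording: ",
         paste(absent, collapse = ", "))
  }
  ref_idx <- match(ref_labels, rec$channel_labels)
  ref <- colMeans(rec$data[ref_idx, , drop = FALSE])
  keep <- setdiff(seq_len(nrow(rec$data)), ref_idx)
  if (length(keep) == 0) stop("re-referencing would drop every channel")
  out <- rec$data[keep, , drop = FALSE] -
    matrix(ref, nrow = length(keep), ncol = ncol(rec$data), byrow = TRUE)
  eeg_recording(out, rec$channel_labels[keep], rec$fs,
                reference_note = paste0("mean(",
                                        paste(ref_labels, collapse = ","),
                                        ")"))
}

#' Band-pass filter a recording (zero phase)
#'
#' Butterworth band-pass ([butter_bandpass()]) applied forward and backward
#' ([sos_filtfilt()]) channel by channel, so that no phase shift is
#' introduced: nonzero filter phase would bias the instantaneous-phase
#' estimates downstream. The extension length scales with the period of the
#' low band edge so that slow bands settle.
#'
#' @param rec An [eeg_recording()].
#' @param band A [band_definition()].
#' @param order Prototype filter order (default 4, about 24 dB/octave per
#'   pass).
#' @return Filtered [eeg_recording()] of identical shape.
#' @export
bandpass <- function(rec, band, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(band, "band_definition"))
  check_band_vs_fs(band, rec$fs)
  sos <- butter_bandpass(band$low, band$high, rec$fs, order = order)
  padlen <- min(ncol(rec$data) - 1, max(24, round(3 * rec$fs / band$low)))
  out <- t(apply(rec$data, 1, function(x) sos_filtfilt(sos, x, padlen)))
  eeg_recording(out, rec$channel_labels, rec$fs,
                reference_note = paste0(rec$reference_note, "; ", band$name,
                                        " ", band$low, "-", band$high, " Hz"))
}

#' Cut a recording into fixed-length non-overlapping epochs
#'
#' Consecutive epochs from the start of the recording; a trailing partial
#' epoch is discarded. The canonical configuration (8 s at 512 Hz) yields
#' 4096-sample epochs.
#'
#' @param rec An [eeg_recording()].
#' @param epoch_seconds Epoch length in seconds (default 8).
#' @return An `epoch_set`: list with `epochs` (list of channels x samples
#'   matrices), `band` (NULL here; set by the pipeline), `fs`,
#'   `epoch_length`, `channel_labels`.
#' @export
epoch_recording <- function(rec, epoch_seconds = 8) {
  stopifnot(inherits(rec, "eeg_recording"))
  epoch_length <- round(rec$fs * epoch_seconds)
  n <- ncol(rec$data)
  if (epoch_length < 1 || n < epoch_length) {
    stop("recording (", n, " samples) is shorter than one epoch (",
         epoch_length, " samples)")
  }
  n_epochs <- n %/% epoch_length
  epochs <- lapply(seq_len(n_epochs), function(k) {
    rec$data[, ((k - 1) * epoch_length + 1):(k * epoch_length), drop = FALSE]
  })
  structure(list(epochs = epochs, fs = rec$fs, epoch_length = epoch_length,
                 channel_labels = rec$channel_labels, band = NULL),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set: %d epochs x %d channels x %d samples @ %g Hz>\n",
              length(x$epochs), length(x$channel_labels), x$epoch_length,
              x$fs))
  invisible(x)
}

#' Screen epochs by a peak-to-peak amplitude threshold
#'
#' A surrogate for visual artifact inspection: an epoch is clean iff every
#' channel's peak-to-peak amplitude is at most `ptp_threshold`. The first
#' `n_keep` clean epochs in temporal order are retained; if fewer exist, all
#' clean epochs are returned with a warning.
#'
#' @param es An `epoch_set` from [epoch_recording()].
#' @param ptp_threshold Peak-to-peak limit in microvolts (default 100).
#' @param n_keep Number of epochs to retain (default 10).
#' @return Screened `epoch_set` (subset of input epochs, order preserved).
#' @export
reject_artifacts <- function(es, ptp_threshold = 100, n_keep = 10) {
  stopifnot(inherits(es, "epoch_set"))
  if (n_keep < 1) stop("n_keep must be at least 1")
  ptp <- vapply(es$epochs, function(ep) {
    max(apply(ep, 1, function(ch) diff(range(ch))))
  }, numeric(1))
  clean <- which(ptp <= ptp_threshold)
  if (length(clean) == 0) {
    stop("no epoch passes the ", ptp_threshold,
         " uV peak-to-peak threshold; per-epoch maxima: ",
         paste(sprintf("%.1f", ptp), collapse = ", "))
  }
  if (length(clean) < n_keep) {
    warning("only ", length(clean), " clean epoch(s) available (asked for ",
            n_keep, "); keeping all of them")
  }
  keep <- clean[seq_len(min(n_keep, length(clean)))]
  out <- es
  out$epochs <- es$epochs[keep]
  attr(out, "kept_indices") <- keep
  attr(out, "n_rejected") <- length(es$epochs) - length(clean)
  out
}
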