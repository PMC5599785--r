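#' Construct a multichannel EEG recording
#'
#' The basic container for continuous multichannel data: a channels x samples
#' numeric matrix with channel labels and a sampling rate. Amplitudes are in
#' microvolts by convention (the artifact threshold default assumes this).
#'
#' @param data Numeric matrix, one row per channel.
#' @param channel_labels Character vector, one label per row of `data`.
#' @param fs Sampling rate in Hz.
#' @param reference_note Free-text provenance of the reference scheme.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, channel_labels = NULL, fs,
                          reference_note = "as recorded") {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("data must be a numeric matrix (channels x samples)")
  }
  if (is.null(channel_labels)) {
    channel_labels <- sprintf("ch%02d", seq_len(nrow(data)))
  }
  if (length(channel_labels) != nrow(data)) {
    stop("channel_labels length (", length(channel_labels),
         ") does not match the number of rows (", nrow(data), ")")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("fs must be a single positive number")
  }
  if (!all(is.finite(data))) stop("recording contains non-finite samples")
  rownames(data) <- channel_labels
  structure(list(data = data, channel_labels = as.character(channel_labels),
                 fs = as.numeric(fs), reference_note = reference_note),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording: %d channels x %d samples @ %g Hz (%.1f s); ref: %s>\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              x$reference_note))
  invisible(x)
}

#' Read a recording from a plain-text matrix file
#'
#' One channel per row, whitespace-separated samples. Channel labels are not
#' stored in the file; supply them or accept generated `chNN` labels.
#'
#' @param path File path.
#' @param fs Sampling rate in Hz (from the manifest sidecar).
#' @param channel_labels Optional labels; recycled defaults otherwise.
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, fs, channel_labels = NULL) {
  if (!file.exists(path)) stop("recording file not found: ", path)
  dat <- as.matrix(utils::read.table(path, header = FALSE,
                                     colClasses = "numeric"))
  dimnames(dat) <- NULL
  eeg_recording(dat, channel_labels = channel_labels, fs = fs,
                reference_note = paste0("loaded from ", basename(path)))
}

#' Write a recording as a plain-text matrix file
#'
#' @param rec An [eeg_recording()].
#' @param path Output path.
#' @param digits Significant digits retained (controls file size).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, digits = 6) {
  stopifnot(inherits(rec, "eeg_recording"))
  m <- signif(rec$data, digits)
  utils::write.table(m, path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a subject manifest
#'
#' Tab-separated with header; required columns `subject_id`, `group`, `path`,
#' `fs_hz`. Additional columns are treated as numeric covariates
#' (conventionally `ftnd`, `cigarettes_per_day`, `pack_years`, `onset_age`).
#' Relative recording paths are resolved against the manifest's directory.
#'
#' @param path Manifest file path.
#' @return A data.frame with one row per subject.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  required <- c("subject_id", "group", "path", "fs_hz")
  missing <- setdiff(required, names(man))
  if (length(missing) > 0) {
    stop("manifest ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  }
  rel <- !grepl("^(/|[A-Za-z]:)", man$path)
  man$path[rel] <- file.path(dirname(path), man$path[rel])
  man
}

#' Write a subject manifest
#'
#' @param manifest Data.frame as produced by [generate_group_dataset()] /
#'   [simulate_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
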