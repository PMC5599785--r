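#' Define a frequency band
#'
#' A band is a named half-open passband used for band-pass filtering and for
#' labelling downstream connectivity and tree metrics. Edges are interpreted
#' as half-power (-3 dB) corner frequencies of the band-pass filter.
#'
#' @param name Band label, e.g. `"alpha"`.
#' @param low Lower corner frequency in Hz. Must be positive.
#' @param high Upper corner frequency in Hz. Must exceed `low`.
#' @return An object of class `band_definition`.
#' @examples
#' band_definition("alpha", 8, 13)
#' @export
band_definition <- function(name, low, high) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(low) || !is.numeric(high) || length(low) != 1L ||
      length(high) != 1L || low <= 0 || high <= low) {
    stop("band edges must satisfy 0 < low < high (got low=", low,
         ", high=", high, ")")
  }
  structure(list(name = name, low = as.numeric(low), high = as.numeric(high)),
            class = "band_definition")
}

#' Canonical EEG frequency bands
#'
#' The four classical bands used throughout the pipeline: delta 0.5-4 Hz,
#' theta 4-8 Hz, alpha 8-13 Hz and beta 13-25 Hz.
#'
#' @return Named list of [band_definition()] objects.
#' @export
default_bands <- function() {
  list(
    delta = band_definition("delta", 0.5, 4),
    theta = band_definition("theta", 4, 8),
    alpha = band_definition("alpha", 8, 13),
    beta  = band_definition("beta", 13, 25)
  )
}

#' @export
print.band_definition <- function(x, ...) {
  cat(sprintf("<band %s: %g-%g Hz>\n", x$name, x$low, x$high))
  invisible(x)
}

# validity of a band against a sampling rate (edges below Nyquist)
check_band_vs_fs <- function(band, fs) {
  if (band$high >= fs / 2) {
    stop("band '", band$name, "' upper edge (", band$high,
         " Hz) is at or above the Nyquist frequency (", fs / 2, " Hz)")
  }
  invisible(TRUE)
}
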