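# Synthetic phase-coupled EEG. Each channel is A*sin(theta_i(t)) where
# theta_i integrates an instantaneous frequency inside the carrier band;
# a coupled follower tracks its driver's phase plus a fixed lag plus white
# Gaussian phase jitter of sd (1 - strength) * pi/4. Optional square mixing
# simulates zero-lag field spread (volume conduction); independent Gaussian
# sensor noise is added after mixing.

#' Specify a ground-truth coupling topology
#'
#' @param n_channels Number of channels.
#' @param coupling_edges Data.frame with columns `i` (driver), `j`
#'   (follower), `lag` (radians, in (-pi, pi\]), `strength` (in \[0, 1\]).
#'   Zero rows for an uncoupled ensemble. A node may follow at most one
#'   driver.
#' @param carrier_band [band_definition()] the oscillators live in (default
#'   alpha, 8-13 Hz).
#' @param noise_sd Sensor noise standard deviation, same amplitude units as
#'   the signal (default 5).
#' @param amplitude Oscillation amplitude (default 40, i.e. ~80 uV
#'   peak-to-peak, comfortably below the 100 uV artifact threshold).
#' @param mixing Optional n_channels x n_channels mixing matrix applied to
#'   the clean channel signals (zero-lag superposition).
#' @param seed Integer seed making the recording reproducible.
#' @return A `topology_spec`.
#' @export
topology_spec <- function(n_channels, coupling_edges = NULL,
                          carrier_band = band_definition("alpha", 8, 13),
                          noise_sd = 5, amplitude = 40, mixing = NULL,
                          seed = 1L) {
  stopifnot(n_channels >= 1)
  if (is.null(coupling_edges)) {
    coupling_edges <- data.frame(i = integer(0), j = integer(0),
                                 lag = numeric(0), strength = numeric(0))
  }
  coupling_edges <- as.data.frame(coupling_edges)
  stopifnot(all(c("i", "j", "lag", "strength") %in% names(coupling_edges)))
  if (nrow(coupling_edges) > 0) {
    if (any(coupling_edges$i > n_channels | coupling_edges$j > n_channels |
            coupling_edges$i < 1 | coupling_edges$j < 1)) {
      stop("coupling edge node index outside 1..n_channels")
    }
    if (any(coupling_edges$lag <= -pi | coupling_edges$lag > pi)) {
      stop("phase lags must lie in (-pi, pi]")
    }
    if (any(coupling_edges$strength < 0 | coupling_edges$strength > 1)) {
      stop("coupling strengths must lie in [0, 1]")
    }
    if (anyDuplicated(coupling_edges$j)) {
      stop("a channel can follow at most one driver")
    }
  }
  if (!is.null(mixing)) {
    if (!is.matrix(mixing) || nrow(mixing) != n_channels ||
        ncol(mixing) != n_channels || !is.numeric(mixing)) {
      stop("mixing must be a numeric ", n_channels, " x ", n_channels,
           " matrix")
    }
  }
  structure(list(n_channels = as.integer(n_channels),
                 coupling_edges = coupling_edges,
                 carrier_band = carrier_band, noise_sd = noise_sd,
                 amplitude = amplitude, mixing = mixing,
                 seed = as.integer(seed)),
            class = "topology_spec")
}

#' Star and chain coupling presets
#'
#' `star_topology`: one hub (node 1) drives every other channel with a
#' common lag, producing a hub-dominated ("star-like") ground truth.
#' `chain_topology`: node i drives node i+1 with a per-hop lag, producing a
#' sequential ("path-like") ground truth.
#'
#' @param n_channels Number of channels.
#' @param strength Coupling strength in \[0, 1\].
#' @param lag Phase lag in radians (per edge / per hop).
#' @param ... Passed to [topology_spec()].
#' @return A `topology_spec`.
#' @export
star_topology <- function(n_channels, strength = 0.9, lag = pi / 4, ...) {
  edges <- data.frame(i = 1L, j = 2:n_channels, lag = lag,
                      strength = strength)
  topology_spec(n_channels, edges, ...)
}

#' @rdname star_topology
#' @export
chain_topology <- function(n_channels, strength = 0.9, lag = pi / 4, ...) {
  edges <- data.frame(i = 1:(n_channels - 1), j = 2:n_channels, lag = lag,
                      strength = strength)
  topology_spec(n_channels, edges, ...)
}

# deterministic processing order: roots first (ascending), then followers
# whose driver is already placed
channel_order <- function(spec) {
  n <- spec$n_channels
  driver <- rep(NA_integer_, n)
  driver[spec$coupling_edges$j] <- spec$coupling_edges$i
  placed <- rep(FALSE, n)
  ord <- integer(0)
  repeat {
    driver_placed <- !is.na(driver) & placed[ifelse(is.na(driver), 1L, driver)]
    ready <- which(!placed & (is.na(driver) | driver_placed))
    if (length(ready) == 0) {
      if (all(placed)) break
      stop("coupling graph contains a driver cycle")
    }
    ord <- c(ord, ready)
    placed[ready] <- TRUE
  }
  ord
}

#' Generate a surrogate multichannel recording
#'
#' @param spec A [topology_spec()].
#' @param fs Sampling rate in Hz (default 512). Must exceed twice the upper
#'   carrier-band edge.
#' @param duration Recording length in seconds (default 120, i.e. fifteen
#'   8-s epochs). Must cover at least two 8-s epochs.
#' @return An [eeg_recording()]; identical spec (including seed) gives a
#'   bit-identical result.
#' @export
generate_recording <- function(spec, fs = 512, duration = 120) {
  stopifnot(inherits(spec, "topology_spec"))
  if (duration <= 0) stop("duration must be positive")
  band <- spec$carrier_band
  if (fs <= 2 * band$high) {
    stop("fs (", fs, " Hz) must exceed twice the carrier band's upper edge (",
         band$high, " Hz)")
  }
  n_samp <- round(fs * duration)
  if (n_samp < 2 * round(8 * fs)) {
    stop("duration (", duration, " s) must cover at least two 8-s epochs")
  }
  n <- spec$n_channels
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(spec$seed)
  bw <- band$high - band$low
  driver_of <- rep(NA_integer_, n)
  lag_of <- rep(NA_real_, n)
  strength_of <- rep(NA_real_, n)
  if (nrow(spec$coupling_edges) > 0) {
    driver_of[spec$coupling_edges$j] <- spec$coupling_edges$i
    lag_of[spec$coupling_edges$j] <- spec$coupling_edges$lag
    strength_of[spec$coupling_edges$j] <- spec$coupling_edges$strength
  }
  theta <- matrix(0, n, n_samp)
  for (ch in channel_order(spec)) {
    if (is.na(driver_of[ch])) {
      # free oscillator: base frequency inside the band plus slight white FM
      f0 <- stats::runif(1, band$low + 0.15 * bw, band$high - 0.15 * bw)
      f_inst <- f0 + stats::rnorm(n_samp, sd = 0.02 * bw)
      phi0 <- stats::runif(1, -pi, pi)
      theta[ch, ] <- phi0 + 2 * pi * cumsum(f_inst) / fs
    } else {
      jitter_sd <- (1 - strength_of[ch]) * pi / 4
      jit <- if (jitter_sd > 0) stats::rnorm(n_samp, sd = jitter_sd) else 0
      theta[ch, ] <- theta[driver_of[ch], ] + lag_of[ch] + jit
    }
  }
  x <- spec$amplitude * sin(theta)
  if (!is.null(spec$mixing)) x <- spec$mixing %*% x
  if (spec$noise_sd > 0) {
    x <- x + matrix(stats::rnorm(n * n_samp, sd = spec$noise_sd), n, n_samp)
  }
  eeg_recording(x, fs = fs,
                reference_note = sprintf("synthetic (seed %d)", spec$seed))
}

# smoking covariates drawn from the cohort's reported distributions:
# FTND 4.6 (1.5), cigarettes/day 14.05 (3.9), pack-years 3.0 (1.8),
# onset age 15.3 (1.8)
draw_covariates <- function(is_smoker) {
  if (!is_smoker) {
    return(list(ftnd = NA_real_, cigarettes_per_day = NA_real_,
                pack_years = NA_real_, onset_age = NA_real_))
  }
  list(ftnd = round(min(10, max(0, stats::rnorm(1, 4.6, 1.5)))),
       cigarettes_per_day = round(max(1, stats::rnorm(1, 14.05, 3.9))),
       pack_years = round(max(0.1, stats::rnorm(1, 3.0, 1.8)), 2),
       onset_age = round(max(10, stats::rnorm(1, 15.3, 1.8)), 1))
}

#' Generate a two-group surrogate cohort
#'
#' Derives one reproducible seed per subject from the master seed, generates
#' a recording per subject from its group's topology, and attaches subject
#' metadata (group label plus synthetic smoking covariates for the smoker
#' group).
#'
#' @param n_per_group Subjects per group (>= 2; group statistics are
#'   undefined below that).
#' @param spec_smoker,spec_nonsmoker [topology_spec()] per group (the
#'   per-subject seed overrides the spec's own seed).
#' @param fs,duration As in [generate_recording()].
#' @param seed Master seed.
#' @return List of subjects, each a list with `recording` and `record`
#'   (subject_id, group, covariates).
#' @export
generate_group_dataset <- function(n_per_group, spec_smoker, spec_nonsmoker,
                                   fs = 512, duration = 120, seed = 1L) {
  if (n_per_group < 2) {
    stop("need at least 2 subjects per group (group statistics undefined)")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)
  n_total <- 2 * n_per_group
  subject_seeds <- sample.int(.Machine$integer.max - 1, n_total)
  groups <- rep(c("smoker", "nonsmoker"), each = n_per_group)
  lapply(seq_len(n_total), function(k) {
    spec <- if (groups[k] == "smoker") spec_smoker else spec_nonsmoker
    spec$seed <- subject_seeds[k]
    set.seed(subject_seeds[k] %% 100000 + 7L)
    cov <- draw_covariates(groups[k] == "smoker")
    list(recording = generate_recording(spec, fs, duration),
         record = c(list(subject_id = sprintf("S%03d", k), group = groups[k]),
                    cov))
  })
}

#' Write a ready-to-run surrogate dataset to disk
#'
#' Generates recordings subject by subject (so memory stays flat), writes
#' each as a plain-text matrix, and writes a tab-separated manifest the
#' pipeline consumes unchanged.
#'
#' @param preset `"star_vs_chain"` (nonsmokers star-coupled, smokers
#'   chain-coupled, alpha carrier) or `"null"` (both groups uncoupled).
#' @param n_per_group Subjects per group.
#' @param out_dir Output directory (created if absent).
#' @param seed Master seed.
#' @param n_channels Channels per recording (default 64).
#' @param fs,duration As in [generate_recording()].
#' @param strength Coupling strength for the coupled preset (default 0.9).
#' @return Path of the written manifest.
#' @export
simulate_dataset <- function(preset = c("star_vs_chain", "null"),
                             n_per_group = 20, out_dir, seed = 1L,
                             n_channels = 64, fs = 512, duration = 120,
                             strength = 0.9) {
  preset <- match.arg(preset)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  specs <- switch(preset,
    star_vs_chain = list(smoker = chain_topology(n_channels, strength),
                         nonsmoker = star_topology(n_channels, strength)),
    null = {
      s <- topology_spec(n_channels)
      list(smoker = s, nonsmoker = s)
    })
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)
  n_total <- 2 * n_per_group
  subject_seeds <- sample.int(.Machine$integer.max - 1, n_total)
  groups <- rep(c("smoker", "nonsmoker"), each = n_per_group)
  rows <- vector("list", n_total)
  for (k in seq_len(n_total)) {
    spec <- specs[[groups[k]]]
    spec$seed <- subject_seeds[k]
    rec <- generate_recording(spec, fs, duration)
    sid <- sprintf("S%03d", k)
    fname <- paste0(sid, ".txt")
    write_recording(rec, file.path(out_dir, fname))
    set.seed(subject_seeds[k] %% 100000 + 7L)
    cov <- draw_covariates(groups[k] == "smoker")
    rows[[k]] <- data.frame(subject_id = sid, group = groups[k], path = fname,
                            fs_hz = fs, ftnd = cov$ftnd,
                            cigarettes_per_day = cov$cigarettes_per_day,
                            pack_years = cov$pack_years,
                            onset_age = cov$onset_age)
  }
  manifest_path <- file.path(out_dir, "manifest.tsv")
  write_manifest(do.call(rbind, rows), manifest_path)
  manifest_path
}
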