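#' Specification of a synthetic neonatal EEG recording
#'
#' Describes a seeded, reproducible synthetic multichannel recording:
#' 1/f-shaped Gaussian background at neonatal amplitudes (tens of uV,
#' peaks below 100 uV) contaminated by all-channel flat-line segments
#' (optionally flanked by sharp deflections) and by high-amplitude
#' movement bursts (low frequency, > 150 uV peaks) or muscle bursts
#' (>= 55 Hz content).
#'
#' @param n_channels number of EEG channels (default 9, as in 9-electrode
#'   clinical montages; 19 matches full 10-20 caps).
#' @param fs sampling rate in Hz (default 250).
#' @param duration_s recording duration in seconds (default 1200 = 20 min,
#'   the annotated segment length used for detector evaluation).
#' @param background_rms background RMS amplitude in uV (default 20).
#' @param background_exponent spectral exponent of the 1/f background
#'   power spectrum (default 1).
#' @param flats list of flat events, each a list with `onset_s`,
#'   `duration_s`, optional `channels` (default all) and `edge_uv`
#'   (one-sample deflection amplitude at each edge, default 0).
#' @param bursts list of burst events, each a list with `onset_s`,
#'   `duration_s`, `peak_uv` and `kind` (`"movement"` = 2 Hz, or
#'   `"muscle"` = 60 Hz), optional `freq_hz` override.
#' @param seed RNG seed making the recording reproducible.
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_channels = 9, fs = 250, duration_s = 1200,
                            background_rms = 20, background_exponent = 1,
                            flats = list(), bursts = list(), seed = 1) {
  ok_event <- function(ev) ev$onset_s >= 0 &&
    ev$onset_s + ev$duration_s <= duration_s
  if (!all(vapply(flats, ok_event, TRUE)) ||
      !all(vapply(bursts, ok_event, TRUE))) {
    stop("all events must lie within [0, duration_s]")
  }
  structure(list(n_channels = n_channels, fs = fs, duration_s = duration_s,
                 background_rms = background_rms,
                 background_exponent = background_exponent,
                 flats = flats, bursts = bursts, seed = seed),
            class = "simulation_spec")
}

#' Generate the 1/f Gaussian background
#'
#' Per-channel Gaussian noise shaped in the frequency domain to a
#' `1/f^exponent` power spectrum (flattened below 0.5 Hz to keep the
#' variance finite) and scaled to the target RMS.  Deterministic under
#' the spec's seed.
#'
#' @param spec a [simulation_spec()].
#' @return A [recording()].
#' @export
generate_background <- function(spec) {
  set.seed(spec$seed)
  n <- round(spec$duration_s * spec$fs)
  freqs <- seq(0, spec$fs - spec$fs / n, length.out = n)
  freqs <- pmin(freqs, spec$fs - freqs)          # two-sided frequency axis
  shape <- 1 / pmax(freqs, 0.5)^(spec$background_exponent / 2)
  shape[1L] <- 0                                 # no DC offset
  data <- matrix(0, spec$n_channels, n)
  for (ch in seq_len(spec$n_channels)) {
    white <- stats::rnorm(n)
    x <- Re(stats::fft(stats::fft(white) * shape, inverse = TRUE)) / n
    data[ch, ] <- x * spec$background_rms / sqrt(mean(x^2))
  }
  recording(data, spec$fs, paste0("Ch", seq_len(spec$n_channels)))
}

#' Inject a flat-line event
#'
#' The selected channels hold their last pre-onset value exactly constant
#' over the event, emulating lost head-box contact; optionally a
#' one-sample deflection of `edge_uv` microvolts is placed just outside
#' each edge (flat lines are often preceded/followed by sharp
#' deflections).
#'
#' @param rec a [recording()].
#' @param onset_s,duration_s event placement in seconds.
#' @param channels channel indices affected (default: all).
#' @param edge_uv edge-deflection amplitude in uV (default 0 = none).
#' @return A list with the modified `recording` and the ground-truth
#'   `interval` (an [interval_set()] labelled `"flatline"`).
#' @export
inject_flat <- function(rec, onset_s, duration_s, channels = NULL,
                        edge_uv = 0) {
  if (is.null(channels)) channels <- seq_len(n_channels(rec))
  fs <- rec$fs
  i0 <- round(onset_s * fs) + 1L
  i1 <- min(round((onset_s + duration_s) * fs), n_samples(rec))
  stopifnot(i0 >= 1L, i1 >= i0)
  hold_idx <- max(i0 - 1L, 1L)
  for (ch in channels) {
    rec$data[ch, i0:i1] <- rec$data[ch, hold_idx]
    if (edge_uv != 0) {
      if (i0 > 1L) rec$data[ch, i0 - 1L] <- rec$data[ch, i0 - 1L] + edge_uv
      if (i1 < n_samples(rec)) {
        rec$data[ch, i1 + 1L] <- rec$data[ch, i1 + 1L] + edge_uv
      }
    }
  }
  list(recording = rec,
       interval = interval_set(onset_s, onset_s + duration_s, "flatline"))
}

#' Inject a movement or muscle burst
#'
#' Adds a Tukey-tapered oscillation on top of the background in all
#' channels: movement bursts are low-frequency (default 2 Hz) and reach
#' the requested peak amplitude; muscle bursts are high-frequency
#' (default 60 Hz), above the 50 Hz spectral split, so they raise the RFC
#' on the notch-only view while the band-pass view barely sees them.
#' Outside the event the signal is untouched.
#'
#' @param rec a [recording()].
#' @param onset_s,duration_s event placement in seconds.
#' @param peak_uv burst peak amplitude in uV.
#' @param kind `"movement"` or `"muscle"`.
#' @param freq_hz oscillation frequency override in Hz.
#' @param alpha Tukey taper fraction (default 0.25).
#' @return A list with the modified `recording` and the ground-truth
#'   `interval` (labelled `"large_amplitude"`).
#' @export
inject_burst <- function(rec, onset_s, duration_s, peak_uv,
                         kind = c("movement", "muscle"), freq_hz = NULL,
                         alpha = 0.25) {
  kind <- match.arg(kind)
  if (is.null(freq_hz)) freq_hz <- if (kind == "movement") 2 else 60
  fs <- rec$fs
  i0 <- round(onset_s * fs) + 1L
  i1 <- min(round((onset_s + duration_s) * fs), n_samples(rec))
  stopifnot(i0 >= 1L, i1 >= i0)
  t <- (seq(i0, i1) - i0) / fs
  burst <- peak_uv * tukey_window(length(t), alpha) *
    sin(2 * pi * freq_hz * t + pi / 2)
  for (ch in seq_len(n_channels(rec))) {
    rec$data[ch, i0:i1] <- rec$data[ch, i0:i1] + burst
  }
  list(recording = rec,
       interval = interval_set(onset_s, onset_s + duration_s,
                               "large_amplitude"))
}

# Tukey (tapered cosine) window: flat top, cosine ramps over alpha/2 of
# the length at each end.
tukey_window <- function(n, alpha = 0.25) {
  if (n == 1L) return(1)
  t <- (seq_len(n) - 1) / (n - 1)
  w <- rep(1, n)
  edge <- alpha / 2
  lo <- t < edge
  hi <- t > 1 - edge
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (1 - t[hi]) / alpha - 1)))
  w
}

#' Generate a full synthetic dataset with ground truth
#'
#' Composes background, flat events and bursts according to the spec and
#' returns the recording plus the ground-truth annotation set.  If `dir`
#' is given, an EDF file and an annotation CSV are also written there.
#'
#' @param spec a [simulation_spec()].
#' @param dir optional output directory for `recording.edf` and
#'   `annotations.csv`.
#' @return A list with `recording`, `truth` (an [interval_set()]) and,
#'   when written, `edf_path` / `csv_path`.
#' @export
generate_dataset <- function(spec, dir = NULL) {
  rec <- generate_background(spec)
  truth <- empty_interval_set()
  for (ev in spec$bursts) {
    res <- inject_burst(rec, ev$onset_s, ev$duration_s, ev$peak_uv,
                        kind = ev$kind %||% "movement",
                        freq_hz = ev$freq_hz)
    rec <- res$recording
    truth <- interval_set(c(truth$start_s, res$interval$start_s),
                          c(truth$end_s, res$interval$end_s),
                          c(truth$label, res$interval$label))
  }
  for (ev in spec$flats) {
    res <- inject_flat(rec, ev$onset_s, ev$duration_s,
                       channels = ev$channels, edge_uv = ev$edge_uv %||% 0)
    rec <- res$recording
    truth <- interval_set(c(truth$start_s, res$interval$start_s),
                          c(truth$end_s, res$interval$end_s),
                          c(truth$label, res$interval$label))
  }
  out <- list(recording = rec, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    out$edf_path <- write_edf(rec, file.path(dir, "recording.edf"))
    out$csv_path <- write_annotations(truth, file.path(dir, "annotations.csv"))
  }
  out
}

#' Default synthetic study conditions
#'
#' Nine channels at 250 Hz for 20 minutes, two all-channel flat segments
#' (3 s and 10 s, with 300 uV edge deflections) and six movement/muscle
#' bursts with peaks of 200-300 uV — the fixture used throughout the test
#' suite.
#'
#' @param seed RNG seed.
#' @return A [simulation_spec()].
#' @export
default_simulation_spec <- function(seed = 1) {
  simulation_spec(
    n_channels = 9, fs = 250, duration_s = 1200, seed = seed,
    flats = list(
      list(onset_s = 300, duration_s = 3, edge_uv = 300),
      list(onset_s = 700, duration_s = 10, edge_uv = 300)
    ),
    bursts = list(
      list(onset_s = 100, duration_s = 5, peak_uv = 300, kind = "movement"),
      list(onset_s = 200, duration_s = 4, peak_uv = 250, kind = "movement"),
      list(onset_s = 450, duration_s = 6, peak_uv = 280, kind = "movement"),
      list(onset_s = 600, duration_s = 3, peak_uv = 200, kind = "movement"),
      list(onset_s = 900, duration_s = 5, peak_uv = 60, kind = "muscle"),
      list(onset_s = 1050, duration_s = 4, peak_uv = 300, kind = "movement")
    )
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
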