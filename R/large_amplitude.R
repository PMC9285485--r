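#' Segment a recording into non-overlapping analysis windows
#'
#' Tiles `[0, n_samples/fs)` with contiguous windows of `window_s`
#' seconds.  If the trailing remainder is at least 1 s it becomes one
#' shorter final window; a remainder under 1 s is appended to the last
#' full window so that spectral estimates stay stable.  A recording
#' shorter than one window yields a single window covering it entirely.
#'
#' @param n_samples recording length in samples.
#' @param fs sampling rate in Hz.
#' @param window_s window duration in seconds (1-7 s admissible, 3 s
#'   recommended).
#' @return Data frame (`window_grid`) with columns `start_s`, `end_s`.
#' @export
segment_windows <- function(n_samples, fs, window_s = 3) {
  if (window_s <= 0) stop("window_s must be positive")
  duration <- n_samples / fs
  n_full <- floor(duration / window_s)
  if (n_full == 0L) {
    grid <- data.frame(start_s = 0, end_s = duration)
  } else {
    starts <- (seq_len(n_full) - 1) * window_s
    ends <- starts + window_s
    rem <- duration - n_full * window_s
    if (rem >= 1) {
      starts <- c(starts, n_full * window_s)
      ends <- c(ends, duration)
    } else if (rem > 0) {
      ends[n_full] <- duration
    }
    grid <- data.frame(start_s = starts, end_s = ends)
  }
  class(grid) <- c("window_grid", "data.frame")
  grid
}

#' Per-window amplitude and spectral features
#'
#' `compute_mafd` is the maximal absolute first difference of a window,
#' `max |x(n+1) - x(n)|`, sensitive to abrupt amplitude changes.
#' `compute_maa` is the maximal absolute amplitude, `max |x|`.
#' `compute_rfc` is the ratio of spectral power strictly above `cut_hz`
#' to total power, estimated with Welch's method (Hamming sub-windows of
#' `min(256, length(x))` samples, 50% overlap, one-sided); it is a
#' surrogate for muscle (EMG) contamination and lies in `[0, 1]`.  An
#' all-zero window has RFC 0 by definition.
#'
#' @param x numeric vector: one channel of one window.
#' @return A non-negative scalar (uV for MAFD/MAA, dimensionless for RFC).
#' @export
compute_mafd <- function(x) {
  if (length(x) < 2L) stop("MAFD needs at least 2 samples")
  max(abs(diff(x)))
}

#' @rdname compute_mafd
#' @export
compute_maa <- function(x) {
  if (length(x) < 1L) stop("MAA needs at least 1 sample")
  max(abs(x))
}

#' @rdname compute_mafd
#' @param fs sampling rate in Hz.
#' @param cut_hz spectral split frequency in Hz (default 50).
#' @export
compute_rfc <- function(x, fs, cut_hz = 50) {
  if (all(x == 0)) return(0)
  w <- welch_psd(x, fs)
  tot <- sum(w$psd)
  if (tot == 0) return(0)
  sum(w$psd[w$freq > cut_hz]) / tot
}

# Welch PSD: Hamming taper, 50% overlap, one-sided, segment length
# min(256, length(x)).  Absolute scaling is irrelevant for RFC (ratios).
welch_psd <- function(x, fs, nseg = min(256L, length(x))) {
  n <- length(x)
  stopifnot(nseg >= 2L)
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(nseg) - 1) / (nseg - 1))
  hop <- max(1L, nseg %/% 2L)
  starts <- seq(1L, n - nseg + 1L, by = hop)
  nh <- nseg %/% 2L + 1L
  acc <- numeric(nh)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)] * w
    p <- Mod(stats::fft(seg))^2
    half <- p[seq_len(nh)]
    if (nseg %% 2L == 0L) {
      half[2:(nh - 1L)] <- half[2:(nh - 1L)] + rev(p[(nh + 1L):nseg])
    } else {
      half[2:nh] <- half[2:nh] + rev(p[(nh + 1L):nseg])
    }
    acc <- acc + half
  }
  list(freq = (seq_len(nh) - 1L) * fs / nseg,
       psd = acc / (length(starts) * sum(w^2) * fs))
}

#' Window-feature table for a recording
#'
#' Computes MAFD, MAA (on the band-pass view) and RFC (on the notch-only
#' view) for every channel and window, returning a `window_features`
#' object: a list of channels-by-windows matrices `mafd`, `maa`, `rfc`
#' plus the window grid.
#'
#' @param band [recording()], notch + band-pass view (amplitude features).
#' @param notched [recording()], notch-only view (spectral feature).
#' @param grid a window grid from [segment_windows()]; defaults to tiling
#'   `band` with `config$window_s`.
#' @param config a [detector_config()].
#' @return A `window_features` object.
#' @export
compute_window_features <- function(band, notched, grid = NULL,
                                    config = detector_config()) {
  stopifnot(n_samples(band) == n_samples(notched),
            n_channels(band) == n_channels(notched))
  if (is.null(grid)) {
    grid <- segment_windows(n_samples(band), band$fs, config$window_s)
  }
  nw <- nrow(grid); nc <- n_channels(band); fs <- band$fs
  mafd <- maa <- rfc <- matrix(0, nc, nw)
  for (k in seq_len(nw)) {
    i0 <- round(grid$start_s[k] * fs) + 1L
    i1 <- round(grid$end_s[k] * fs)
    for (ch in seq_len(nc)) {
      xb <- band$data[ch, i0:i1]
      mafd[ch, k] <- compute_mafd(xb)
      maa[ch, k] <- compute_maa(xb)
      rfc[ch, k] <- compute_rfc(notched$data[ch, i0:i1], fs, config$rfc_cut_hz)
    }
  }
  window_features(mafd, maa, rfc, grid)
}

#' @rdname compute_window_features
#' @param mafd,maa,rfc channels-by-windows numeric matrices.
#' @export
window_features <- function(mafd, maa, rfc, grid = NULL) {
  stopifnot(is.matrix(mafd), all(dim(maa) == dim(mafd)),
            all(dim(rfc) == dim(mafd)))
  if (any(mafd < 0) || any(maa < 0) || any(rfc < 0) || any(rfc > 1)) {
    stop("features out of range: MAFD/MAA must be >= 0, RFC in [0, 1]")
  }
  structure(list(mafd = mafd, maa = maa, rfc = rfc, grid = grid),
            class = "window_features")
}

#' Channel-specific robust thresholds
#'
#' For each channel, over all windows of the recording, the MAFD and RFC
#' thresholds are `mult * (median + MAD)` where MAD is the unscaled
#' median absolute deviation (median of absolute deviations from the
#' median, no normal-consistency factor).
#'
#' @param features a [window_features()] object with at least 2 windows.
#' @param config a [detector_config()] providing `mafd_mult`, `rfc_mult`.
#' @return Data frame with columns `channel`, `mafd_cut`, `rfc_cut`.
#' @export
channel_thresholds <- function(features, config = detector_config()) {
  if (ncol(features$mafd) < 2L) {
    stop("channel thresholds need at least 2 windows per channel")
  }
  med_mad <- function(v) stats::median(v) + stats::mad(v, constant = 1)
  data.frame(
    channel = seq_len(nrow(features$mafd)),
    mafd_cut = config$mafd_mult * apply(features$mafd, 1L, med_mad),
    rfc_cut = config$rfc_mult * apply(features$rfc, 1L, med_mad)
  )
}

#' Apply the four large-amplitude removal criteria
#'
#' A window is selected for removal iff one of four criteria is met in at
#' least one channel (all comparisons strict):
#' 1. `MAFD > mafd_mult * (median(MAFD) + MAD(MAFD))` (channel-specific);
#' 2. `MAA > pt150` — certainly not cortical at term age;
#' 3. `pt100 < MAA < pt150` and `RFC > rfc_mult * (median(RFC) + MAD(RFC))`
#'    — doubtful amplitude with muscle-band contamination;
#' 4. `pt100 < MAA < pt150` and the window before and/or after was already
#'    selected by criteria 1-3.
#'
#' Criterion 4 is a single sweep over the selections of criteria 1-3; it
#' does not propagate through chains of doubtful windows.  The doubtful
#' amplitude and the neighbouring selection may come from different
#' channels.
#'
#' @param features a [window_features()] object.
#' @param thresholds output of [channel_thresholds()].
#' @param config a [detector_config()]; `config$criteria` switches
#'   individual criteria off.
#' @return A `selection_table` data frame with columns `window`,
#'   `selected`, `criterion` (1-4, `NA` when unselected).
#' @export
apply_criteria <- function(features, thresholds,
                           config = detector_config()) {
  nw <- ncol(features$maa)
  nc <- nrow(features$maa)
  stopifnot(nrow(thresholds) == nc)
  en <- config$criteria
  doubtful <- features$maa > config$pt100 & features$maa < config$pt150

  c1 <- en[1] & features$mafd > thresholds$mafd_cut
  c2 <- en[2] & features$maa > config$pt150
  c3 <- en[3] & doubtful & features$rfc > thresholds$rfc_cut

  w1 <- apply(c1, 2L, any); w2 <- apply(c2, 2L, any); w3 <- apply(c3, 2L, any)
  pass_a <- w1 | w2 | w3

  # criterion 4: doubtful amplitude in any channel, adjacent to a pass-A window
  any_doubt <- apply(doubtful, 2L, any)
  nb_a <- c(FALSE, pass_a[-nw]) | c(pass_a[-1L], FALSE)
  w4 <- en[4] & any_doubt & nb_a & !pass_a

  criterion <- rep(NA_integer_, nw)
  criterion[w4] <- 4L
  criterion[w3] <- 3L
  criterion[w2] <- 2L
  criterion[w1] <- 1L
  out <- data.frame(window = seq_len(nw), selected = pass_a | w4,
                    criterion = criterion)
  class(out) <- c("selection_table", "data.frame")
  out
}

#' Merge selected windows into removal intervals
#'
#' Consecutive selected windows fuse into one interval; resulting
#' intervals separated by at most `merge_gap_s` seconds (inclusive) fuse
#' again, so that one physical movement episode is removed as one piece.
#'
#' @param selection a selection table from [apply_criteria()].
#' @param grid the matching window grid from [segment_windows()].
#' @param merge_gap_s maximal bridged gap in seconds (default 6).
#' @return An [interval_set()] labelled `"large_amplitude"`.
#' @export
merge_selected <- function(selection, grid, merge_gap_s = 6) {
  sel <- which(selection$selected)
  if (!length(sel)) return(empty_interval_set())
  iv <- interval_set(grid$start_s[sel], grid$end_s[sel], "large_amplitude")
  merge_within_gap(iv, merge_gap_s)
}

#' Detect large-amplitude fluctuations
#'
#' Full large-amplitude chain: tile the recording into windows, compute
#' MAFD/MAA on the band view and RFC on the notch-only view, derive the
#' channel-specific robust thresholds, apply the four removal criteria
#' and merge the selected windows into removal intervals.
#'
#' @param band [recording()], notch + band-pass view.
#' @param notched [recording()], notch-only view.
#' @param config a [detector_config()].
#' @param details if `TRUE`, return a list with the interval set plus the
#'   feature table, thresholds and selection table.
#' @return An [interval_set()] labelled `"large_amplitude"` (or a list,
#'   see `details`).
#' @export
detect_large_amplitude <- function(band, notched,
                                   config = detector_config(),
                                   details = FALSE) {
  grid <- segment_windows(n_samples(band), band$fs, config$window_s)
  features <- compute_window_features(band, notched, grid, config)
  thresholds <- channel_thresholds(features, config)
  selection <- apply_criteria(features, thresholds, config)
  intervals <- merge_selected(selection, grid, config$merge_gap_s)
  if (details) {
    list(intervals = intervals, features = features,
         thresholds = thresholds, selection = selection, grid = grid)
  } else {
    intervals
  }
}

#' Export a window feature/selection table as CSV
#'
#' Long-format table with one row per channel and window:
#' `window_start_s, channel, mafd, maa, rfc, selected, criterion`.
#'
#' @param detail the `details = TRUE` output of [detect_large_amplitude()].
#' @param path output CSV path.
#' @export
write_feature_table <- function(detail, path) {
  nc <- nrow(detail$features$mafd); nw <- ncol(detail$features$mafd)
  tab <- data.frame(
    window_start_s = rep(detail$grid$start_s, each = nc),
    channel = rep(seq_len(nc), nw),
    mafd = as.vector(detail$features$mafd),
    maa = as.vector(detail$features$maa),
    rfc = as.vector(detail$features$rfc),
    selected = rep(detail$selection$selected, each = nc),
    criterion = rep(detail$selection$criterion, each = nc)
  )
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
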