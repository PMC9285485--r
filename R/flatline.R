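#' Second difference of a signal
#'
#' `z(n) = x(n+2) - 2 x(n+1) + x(n)`, the discrete second difference used
#' to find stretches where the signal is exactly constant: both constant
#' and linearly drifting segments map to zero.
#'
#' @param x numeric vector of at least 3 samples.
#' @return Numeric vector of length `length(x) - 2`; element `n` is
#'   attributed to the time of sample `n`.
#' @export
second_difference <- function(x) {
  if (length(x) < 3L) stop("second difference needs at least 3 samples")
  diff(x, differences = 2L)
}

#' Flag sub-threshold second-difference samples in 1-s bins
#'
#' Time is partitioned into consecutive 1-s bins.  Within each bin the
#' samples with `|z| < threshold` (strict) are counted — they need not be
#' consecutive — and if at least `min_flags` such samples occur, all of
#' them are flagged as suspected flat-line samples; bins with fewer are
#' discarded entirely.
#'
#' @param z second-difference signal (element `n` at time `(n-1)/fs`).
#' @param fs sampling rate in Hz.
#' @param threshold flatness threshold in uV (default 1e-4).
#' @param min_flags minimum sub-threshold samples per bin (default 2).
#' @return Sorted numeric vector of flagged sample times in seconds.
#' @export
flag_flat_samples <- function(z, fs, threshold = 1e-4, min_flags = 2) {
  stopifnot(threshold > 0, min_flags >= 1)
  sub <- which(abs(z) < threshold)
  if (!length(sub)) return(numeric())
  times <- (sub - 1L) / fs
  bins <- floor(times)
  counts <- table(bins)
  good <- as.numeric(names(counts))[counts >= min_flags]
  sort(times[bins %in% good])
}

#' Group flagged sample times into candidate intervals
#'
#' Maximal chains of flagged times whose successive gaps are at most
#' `gap_s` seconds (inclusive) become one candidate interval spanning
#' `[first, last + 1/fs)`; singleton chains are allowed.  The tolerance
#' exists so that isolated samples slightly above the flatness threshold
#' do not split one physical flat-line segment in two.
#'
#' @param times sorted flagged sample times in seconds.
#' @param fs sampling rate in Hz.
#' @param gap_s maximal bridged gap in seconds (default 2.5).
#' @return An [interval_set()] of per-channel candidates (label `other`).
#' @export
group_flags <- function(times, fs, gap_s = 2.5) {
  if (!length(times)) return(empty_interval_set())
  times <- sort(times)
  brk <- which(diff(times) > gap_s)
  starts <- times[c(1L, brk + 1L)]
  ends <- times[c(brk, length(times))] + 1 / fs
  interval_set(starts, ends, "other")
}

#' Channel consensus on candidate flat-line intervals
#'
#' A time sample belongs to a consensus interval iff at least
#' `K = round(fraction * n_channels)` channels have a candidate interval
#' covering it; maximal such runs are returned.  At the default fraction
#' 0.75 this gives K = 14 for 19 channels and K = 7 for 9 channels.
#'
#' @param candidates list of per-channel [interval_set()]s.
#' @param fs sampling rate in Hz.
#' @param n_samples recording length in samples (consensus grid).
#' @param fraction required fraction of channels (default 0.75).
#' @return An [interval_set()] (label `other`) of consensus runs.
#' @export
flat_consensus <- function(candidates, fs, n_samples, fraction = 0.75) {
  n_ch <- length(candidates)
  if (n_ch == 0L) stop("consensus needs at least one channel")
  k <- max(1L, round(fraction * n_ch))
  counts <- integer(n_samples)
  for (iv in candidates) {
    counts <- counts + intervals_to_mask(iv, fs, n_samples)
  }
  mask_to_intervals(counts >= k, fs, "other")
}

#' Pad detected flat-line intervals
#'
#' Flat lines are often preceded/followed by sharp deflections, so each
#' detected interval grows on both sides before removal: by `pad_short_s`
#' if its (unpadded) duration is at most `cutoff_s`, else by `pad_long_s`.
#' Padded intervals are clipped to the recording and re-merged if they now
#' overlap.
#'
#' @param intervals disjoint [interval_set()] of detected flat lines.
#' @param duration_s recording duration for clipping.
#' @param cutoff_s duration cutoff in seconds (default 5).
#' @param pad_short_s,pad_long_s padding in seconds (defaults 1 and 3).
#' @return The padded [interval_set()].
#' @export
pad_intervals <- function(intervals, duration_s, cutoff_s = 5,
                          pad_short_s = 1, pad_long_s = 3) {
  if (nrow(intervals) == 0L) return(intervals)
  len <- intervals$end_s - intervals$start_s
  pad <- ifelse(len > cutoff_s, pad_long_s, pad_short_s)
  clip_intervals(
    interval_set(intervals$start_s - pad, intervals$end_s + pad,
                 intervals$label),
    duration_s
  )
}

#' Detect all-channel flat-line segments
#'
#' Full flat-line chain on the raw (unfiltered) recording: per channel,
#' the absolute second difference is thresholded and flagged in 1-s bins,
#' flags are grouped into candidate intervals, the channel consensus is
#' taken, and the surviving intervals are padded according to their
#' duration.
#'
#' @param rec a [recording()] (raw view).
#' @param config a [detector_config()].
#' @return An [interval_set()] labelled `"flatline"`, sorted and disjoint.
#' @export
detect_flatlines <- function(rec, config = detector_config()) {
  if (n_samples(rec) < 3L) stop("recording too short for flat-line detection")
  candidates <- lapply(seq_len(n_channels(rec)), function(ch) {
    z <- second_difference(rec$data[ch, ])
    tt <- flag_flat_samples(z, rec$fs, config$flat_threshold,
                            config$flat_min_flags_per_second)
    group_flags(tt, rec$fs, config$flat_group_gap_s)
  })
  cons <- flat_consensus(candidates, rec$fs, n_samples(rec),
                         config$consensus_fraction)
  padded <- pad_intervals(cons, rec_duration(rec), config$pad_cutoff_s,
                          config$pad_short_s, config$pad_long_s)
  if (nrow(padded) == 0L) return(empty_interval_set())
  interval_set(padded$start_s, padded$end_s, "flatline")
}
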