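# Small fixture makers and independent brute-force oracles used across
# the suite.  Everything is generated in code at test time.

short_spec <- function(seed = 1, duration_s = 120, n_channels = 9,
                       fs = 250, ...) {
  simulation_spec(n_channels = n_channels, fs = fs,
                  duration_s = duration_s, seed = seed, ...)
}

# brute-force truth-table evaluation of the four removal criteria,
# independent of apply_criteria's vectorized implementation
oracle_criteria <- function(features, thresholds, config) {
  nw <- ncol(features$maa); nc <- nrow(features$maa)
  en <- config$criteria
  pass_a <- logical(nw)
  for (w in seq_len(nw)) {
    for (ch in seq_len(nc)) {
      mafd <- features$mafd[ch, w]; maa <- features$maa[ch, w]
      rfc <- features$rfc[ch, w]
      if (en[1] && mafd > thresholds$mafd_cut[ch]) pass_a[w] <- TRUE
      if (en[2] && maa > config$pt150) pass_a[w] <- TRUE
      if (en[3] && maa > config$pt100 && maa < config$pt150 &&
          rfc > thresholds$rfc_cut[ch]) pass_a[w] <- TRUE
    }
  }
  sel <- pass_a
  if (en[4]) {
    for (w in seq_len(nw)) {
      if (pass_a[w]) next
      nb <- (w > 1 && pass_a[w - 1]) || (w < nw && pass_a[w + 1])
      doubt <- any(features$maa[, w] > config$pt100 &
                     features$maa[, w] < config$pt150)
      if (nb && doubt) sel[w] <- TRUE
    }
  }
  sel
}

# per-sample channel-count consensus oracle: membership of every sample
# time is tested directly against the interval bounds
oracle_consensus <- function(candidates, fs, n_samples, fraction) {
  k <- max(1L, round(fraction * length(candidates)))
  t <- (seq_len(n_samples) - 1) / fs
  counts <- integer(n_samples)
  for (iv in candidates) {
    if (!nrow(iv)) next
    inside <- rep(FALSE, n_samples)
    for (j in seq_len(nrow(iv))) {
      inside <- inside | (iv$start_s[j] <= t & t < iv$end_s[j])
    }
    counts <- counts + inside
  }
  mask_to_intervals(counts >= k, fs, "other")
}

random_feature_table <- function(nc = 3, nw = 8) {
  window_features(
    mafd = matrix(stats::rexp(nc * nw, rate = 0.1), nc, nw),
    maa = matrix(stats::runif(nc * nw, 0, 200), nc, nw),
    rfc = matrix(stats::runif(nc * nw), nc, nw)
  )
}

random_interval_set <- function(n = 5, duration = 30, fs = 10) {
  # disjoint, grid-aligned intervals
  grid <- sort(sample(0:(duration * fs), 2 * n))
  starts <- grid[seq(1, 2 * n, by = 2)] / fs
  ends <- grid[seq(2, 2 * n, by = 2)] / fs
  keep <- ends > starts
  if (!any(keep)) return(empty_interval_set())
  interval_set(starts[keep], ends[keep], "other")
}
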