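test_that("window segmentation handles full, trailing and short remainders", {
  g <- segment_windows(60 * 250, 250, 3)
  expect_equal(nrow(g), 20L)
  expect_equal(g$end_s[20], 60)

  g2 <- segment_windows(61.5 * 250, 250, 3)
  expect_equal(nrow(g2), 21L)
  expect_equal(g2$end_s[21] - g2$start_s[21], 1.5)

  g3 <- segment_windows(60.4 * 250, 250, 3)     # <1 s remainder absorbed
  expect_equal(nrow(g3), 20L)
  expect_equal(g3$end_s[20] - g3$start_s[20], 3.4)

  expect_error(segment_windows(100, 250, 0), "positive")
  # windows tile the recording without gaps
  expect_equal(g2$start_s[-1], g2$end_s[-nrow(g2)])
})

test_that("MAFD and MAA match hand values and scale homogeneously", {
  expect_equal(compute_mafd(rep(4, 10)), 0)
  expect_equal(compute_mafd(c(0, 5, -3)), 8)
  expect_equal(compute_maa(numeric(3)), 0)
  expect_equal(compute_maa(c(-120, 80)), 120)
  expect_error(compute_mafd(1), "2 samples")
  expect_error(compute_maa(numeric(0)), "1 sample")
  set.seed(2)
  x <- rnorm(100)
  expect_equal(compute_mafd(3 * x), 3 * compute_mafd(x))
  expect_gte(compute_maa(x), compute_mafd(x) / 2)  # triangle inequality
})

test_that("RFC separates low- and high-frequency content", {
  fs <- 250
  t <- seq(0, 3 - 1 / fs, by = 1 / fs)
  expect_lt(compute_rfc(sin(2 * pi * 10 * t), fs), 0.01)
  expect_gt(compute_rfc(sin(2 * pi * 70 * t), fs), 0.9)
  expect_equal(compute_rfc(numeric(750), fs), 0)
  # flat spectrum: expected ratio (125-50)/125 = 0.6
  set.seed(4)
  rfcs <- replicate(20, compute_rfc(rnorm(750), fs))
  expect_equal(mean(rfcs), 0.6, tolerance = 0.05)
})

test_that("channel thresholds use the unscaled median + MAD", {
  f <- window_features(
    mafd = matrix(c(1, 1, 1, 1, 11), 1),
    maa = matrix(rep(10, 5), 1),
    rfc = matrix(rep(0.1, 5), 1)
  )
  th <- channel_thresholds(f)
  expect_equal(th$mafd_cut, 4.5 * (1 + 0))       # median 1, MAD 0
  expect_equal(th$rfc_cut, 1.5 * 0.1)

  # permutation invariance of the order statistics
  perm <- c(3, 5, 1, 2, 4)
  f2 <- window_features(f$mafd[, perm, drop = FALSE],
                        f$maa[, perm, drop = FALSE],
                        f$rfc[, perm, drop = FALSE])
  expect_equal(channel_thresholds(f2), channel_thresholds(f))

  f1 <- window_features(matrix(1), matrix(1), matrix(0.1))
  expect_error(channel_thresholds(f1), "at least 2 windows")
})

test_that("the four criteria behave at their printed boundaries", {
  cfg <- detector_config()
  base <- function(maa5 = 20, rfc5 = 0.1) window_features(
    mafd = matrix(rep(1, 9), 1),
    maa = matrix(c(rep(20, 4), maa5, rep(20, 4)), 1),
    rfc = matrix(c(rep(0.1, 4), rfc5, rep(0.1, 4)), 1)
  )
  th <- channel_thresholds(base(), cfg)

  # criterion 2: MAA 160 selects regardless of the rest
  sel <- apply_criteria(base(maa5 = 160), th, cfg)
  expect_true(sel$selected[5])
  expect_equal(sel$criterion[5], 2L)

  # doubtful 120 uV with low RFC and unselected neighbours is retained
  sel2 <- apply_criteria(base(maa5 = 120), th, cfg)
  expect_false(any(sel2$selected))

  # doubtful 120 uV with RFC above the channel cut goes by criterion 3
  sel3 <- apply_criteria(base(maa5 = 120, rfc5 = 0.2), th, cfg)
  expect_true(sel3$selected[5])
  expect_equal(sel3$criterion[5], 3L)

  # criterion 4 takes the adjacent doubtful window but does not propagate
  f4 <- window_features(
    mafd = matrix(rep(1, 9), 1),
    maa = matrix(c(20, 20, 120, 160, 120, 120, 20, 20, 20), 1),
    rfc = matrix(rep(0.1, 9), 1)
  )
  sel4 <- apply_criteria(f4, channel_thresholds(f4, cfg), cfg)
  expect_equal(which(sel4$selected), c(3, 4, 5))  # window 6 not reached
  expect_equal(sel4$criterion[c(3, 4, 5)], c(4L, 2L, 4L))

  # boundary equality never selects: MAFD == cut (w9), MAA == 150 (w9),
  # doubtful MAA with RFC == cut (w10)
  fb <- window_features(
    mafd = matrix(c(rep(1, 8), 4.5 * 1, 1), 1),
    maa = matrix(c(rep(20, 8), 150, 120), 1),
    rfc = matrix(c(rep(0.1, 9), 0.15), 1)
  )
  selb <- apply_criteria(fb, channel_thresholds(fb, cfg), cfg)
  expect_false(any(selb$selected))
})

test_that("apply_criteria equals the brute-force truth-table oracle", {
  cfg_all <- detector_config()
  set.seed(99)
  for (i in 1:200) {
    f <- random_feature_table()
    th <- channel_thresholds(f, cfg_all)
    cfg <- cfg_all
    cfg$criteria <- stats::runif(4) > 0.2     # random enable pattern
    expect_equal(apply_criteria(f, th, cfg)$selected,
                 oracle_criteria(f, th, cfg))
  }
  # all criteria off: nothing selected; enabling them is monotone
  f <- random_feature_table()
  th <- channel_thresholds(f, cfg_all)
  off <- cfg_all; off$criteria <- rep(FALSE, 4)
  expect_false(any(apply_criteria(f, th, off)$selected))
  prev <- rep(FALSE, ncol(f$maa))
  for (k in 1:4) {
    cfg <- cfg_all
    cfg$criteria <- c(rep(TRUE, k), rep(FALSE, 4 - k))
    cur <- apply_criteria(f, th, cfg)$selected
    expect_true(all(cur[prev]))
    prev <- cur
  }
})

test_that("selected windows merge across gaps of at most 6 s", {
  grid <- segment_windows(30 * 250, 250, 3)
  sel <- data.frame(window = 1:10, selected = FALSE, criterion = NA_integer_)
  sel$selected[c(1, 2)] <- TRUE               # adjacent windows fuse
  m <- merge_selected(sel, grid, 6)
  expect_equal(c(m$start_s, m$end_s), c(0, 6))

  sel2 <- data.frame(window = 1:10, selected = FALSE, criterion = NA_integer_)
  sel2$selected[c(1, 4)] <- TRUE              # [0,3) and [9,12): gap 6
  m2 <- merge_selected(sel2, grid, 6)
  expect_equal(nrow(m2), 1L)
  expect_equal(m2$end_s, 12)
  expect_equal(m2$label, "large_amplitude")

  expect_equal(nrow(merge_selected(sel2[0, ], grid, 6)), 0L)
})

test_that("detect_large_amplitude flags movement bursts, spares background", {
  spec <- short_spec(seed = 31, duration_s = 300)
  rec <- generate_background(spec)
  rec <- inject_burst(rec, 100, 5, peak_uv = 300, kind = "movement")$recording
  v <- prepare_views(rec)
  iv <- detect_large_amplitude(v$band, v$notched)
  m <- intervals_to_mask(iv, 250, n_samples(rec))
  truth <- intervals_to_mask(interval_set(100, 105, "large_amplitude"),
                             250, n_samples(rec))
  expect_gt(hit_rate(confusion_from_masks(m, truth)), 0.9)

  # stationary background alone: under 5% of samples removed
  bg <- generate_background(short_spec(seed = 32, duration_s = 300,
                                       background_rms = 30))
  vb <- prepare_views(bg)
  ivb <- detect_large_amplitude(vb$band, vb$notched)
  expect_lt(mean(intervals_to_mask(ivb, 250, n_samples(bg))), 0.05)
})

test_that("doubling amplitudes of a sub-100 uV recording is monotone for fixed thresholds", {
  spec <- short_spec(seed = 33, duration_s = 120, background_rms = 15)
  rec <- generate_background(spec)
  cfg <- detector_config(criteria = c(FALSE, TRUE, TRUE, TRUE))
  v1 <- prepare_views(rec, cfg)
  v2 <- prepare_views(recording(2.2 * rec$data, rec$fs), cfg)
  m1 <- intervals_to_mask(detect_large_amplitude(v1$band, v1$notched, cfg),
                          rec$fs, n_samples(rec))
  m2 <- intervals_to_mask(detect_large_amplitude(v2$band, v2$notched, cfg),
                          rec$fs, n_samples(rec))
  expect_true(all(m2[m1]))
})
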