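test_that("background is seed-deterministic with the target RMS and peaks", {
  spec <- short_spec(seed = 41, duration_s = 60, n_channels = 4)
  a <- generate_background(spec)
  b <- generate_background(spec)
  expect_identical(a$data, b$data)
  c <- generate_background(short_spec(seed = 42, duration_s = 60,
                                      n_channels = 4))
  expect_false(identical(a$data, c$data))

  rms <- sqrt(rowMeans(a$data^2))
  expect_true(all(abs(rms - 20) / 20 < 0.1))

  # neonatal amplitude regime: peak under 100 uV in >= 99% of 1-s bins
  peaks <- apply(a$data, 1, function(x) {
    tapply(abs(x), rep(1:60, each = 250), max)
  })
  expect_gte(mean(peaks < 100), 0.99)
})

test_that("flat injection is exactly constant with optional edge deflections", {
  spec <- short_spec(seed = 43, duration_s = 60, n_channels = 3)
  rec <- generate_background(spec)
  res <- inject_flat(rec, 20, 5, edge_uv = 500)
  i0 <- 20 * 250 + 1; i1 <- 25 * 250
  for (ch in 1:3) {
    z <- second_difference(res$recording$data[ch, i0:i1])
    expect_true(all(z == 0))
    d <- abs(diff(res$recording$data[ch, (i0 - 3):(i0 + 1)]))
    expect_gte(max(d), 500 - 100)         # sharp deflection at the edge
  }
  expect_equal(res$interval$start_s, 20)
  expect_equal(res$interval$end_s, 25)
  expect_equal(res$interval$label, "flatline")

  # overlapping flat events merge in the truth set
  spec2 <- short_spec(
    seed = 43, duration_s = 60, n_channels = 3,
    flats = list(list(onset_s = 10, duration_s = 5),
                 list(onset_s = 13, duration_s = 5))
  )
  ds <- generate_dataset(spec2)
  expect_equal(nrow(ds$truth), 1L)
  expect_equal(c(ds$truth$start_s, ds$truth$end_s), c(10, 18))
})

test_that("burst injection reaches its peak and is additive outside events", {
  spec <- short_spec(seed = 44, duration_s = 60, n_channels = 2)
  rec <- generate_background(spec)
  res <- inject_burst(rec, 30, 5, peak_uv = 300, kind = "movement")
  i0 <- 30 * 250 + 1; i1 <- 35 * 250
  expect_gte(max(abs(res$recording$data[1, i0:i1])), 0.95 * 300)
  expect_identical(res$recording$data[, 1:(i0 - 1)], rec$data[, 1:(i0 - 1)])
  expect_identical(res$recording$data[, (i1 + 1):15000],
                   rec$data[, (i1 + 1):15000])

  # muscle burst raises the window RFC on the unfiltered signal
  resm <- inject_burst(rec, 10, 4, peak_uv = 60, kind = "muscle")
  rfc <- compute_rfc(resm$recording$data[1, (10 * 250 + 1):(14 * 250)], 250)
  expect_gt(rfc, 0.5)
})

test_that("generate_dataset round-trips through EDF and CSV on disk", {
  dir <- withr::local_tempdir()
  spec <- short_spec(
    seed = 45, duration_s = 120, n_channels = 9,
    flats = list(list(onset_s = 50, duration_s = 4, edge_uv = 300)),
    bursts = list(list(onset_s = 90, duration_s = 5, peak_uv = 250,
                       kind = "movement"))
  )
  ds <- generate_dataset(spec, dir = dir)
  back <- read_edf(ds$edf_path)
  expect_equal(dim(back$data), dim(ds$recording$data))
  expect_lt(max(abs(back$data - ds$recording$data)), 2000 / 65535)
  truth <- read_annotations(ds$csv_path)
  expect_equal(truth$start_s, ds$truth$start_s)
  expect_equal(truth$label, ds$truth$label)
})

test_that("the default fixture exercises every removal criterion and the flat path", {
  cfg <- detector_config()
  # default fixture: unconditional PT150 removals and the flat-line path
  ds <- generate_dataset(default_simulation_spec(seed = 46))
  v <- prepare_views(ds$recording, cfg)
  det <- detect_large_amplitude(v$band, v$notched, cfg, details = TRUE)
  expect_true(2L %in% det$selection$criterion[det$selection$selected])
  expect_gt(nrow(detect_flatlines(v$raw, cfg)), 0)

  # quieter companion fixture for the remaining criteria, so that the
  # doubtful 100-150 uV range is not blurred by background peaks
  rec <- generate_background(short_spec(seed = 47, duration_s = 300,
                                        background_rms = 10))
  # fast large oscillation: abrupt slope fires the MAFD criterion (1)
  rec <- inject_burst(rec, 36, 3, peak_uv = 300, kind = "movement",
                      freq_hz = 20)$recording
  # doubtful amplitude + muscle content fires criterion 3
  rec <- inject_burst(rec, 150, 3, peak_uv = 120, kind = "movement")$recording
  rec <- inject_burst(rec, 150, 3, peak_uv = 90, kind = "muscle")$recording
  # doubtful window adjacent to an unconditional (PT150) window: criterion 4
  rec <- inject_burst(rec, 249, 3, peak_uv = 200, kind = "movement")$recording
  rec <- inject_burst(rec, 252, 3, peak_uv = 120, kind = "movement")$recording
  v2 <- prepare_views(rec, cfg)
  det2 <- detect_large_amplitude(v2$band, v2$notched, cfg, details = TRUE)
  fired <- det2$selection$criterion[det2$selection$selected]
  expect_true(all(1:4 %in% fired))
})

test_that("events outside the recording are rejected", {
  expect_error(
    simulation_spec(duration_s = 100,
                    flats = list(list(onset_s = 95, duration_s = 10))),
    "within"
  )
})
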