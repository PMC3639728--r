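test_that("spectrogram places a pure tone on its frequency in every frame", {
  ts <- make_ts(sin(2 * pi * 10 * seq(0, 9999) / 1000))
  sg <- power_spectrogram(ts, window = 1000, overlap = 0.5)
  ridge <- mesoburst:::ridge_frequency(sg, band = c(1, 40))
  binw <- sg$fs / sg$nfft
  expect_true(all(abs(ridge - 10) <= 1 / 1 + binw))  # 1 Hz natural resolution
})

test_that("spectrogram tracks a descending chirp monotonically", {
  t <- seq(0, 9999)
  f0 <- 15; f1 <- 12
  phase <- 2 * pi * (f0 * t / 1000 - (f0 - f1) * t^2 / (2 * 10000 * 1000))
  sg <- power_spectrogram(make_ts(sin(phase)), window = 1000, overlap = 0.75)
  ridge <- mesoburst:::ridge_frequency(sg, band = c(1, 40))
  binw <- sg$fs / sg$nfft
  expect_true(all(diff(ridge) <= binw + 1e-9))
  expect_lt(abs(ridge[1] - 15), 1 + binw)
  expect_lt(abs(ridge[length(ridge)] - 12), 1 + binw)
})

test_that("spectrogram frames conserve windowed power (Parseval)", {
  set.seed(3)
  x <- stats::rnorm(4096)
  ts <- make_ts(x)
  sg <- power_spectrogram(ts, window = 512, overlap = 0.5)
  df <- sg$fs / sg$nfft
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(sg$nwin) / (sg$nwin + 1))
  starts <- seq(1, length(x) - sg$nwin + 1, by = sg$nwin / 2)
  for (j in seq_along(starts)) {
    seg <- x[starts[j] + seq_len(sg$nwin) - 1]
    seg <- (seg - mean(seg)) * w
    expect_equal(sum(sg$power[, j]) * df, sum(seg^2) / sum(w^2),
                 tolerance = 0.01)
  }
  expect_error(power_spectrogram(ts, window = 1e6), "longer than")
})

test_that("segmentation recovers the on/off structure of a gated tone", {
  ts <- am_tone(freq = 10, cycles = 10)
  seg <- segment_bursts(ts, smooth = 50, min_burst = 200, min_gap = 200)
  expect_equal(nrow(seg$bursts), 10)
  bs <- burst_statistics(seg, ts)
  expect_lt(abs(bs$suppression_ratio - 0.5), 0.05)
  expect_lt(abs(bs$mean_burst_ms - 1000), 100)
})

test_that("flat and sub-threshold records yield zero bursts", {
  flat <- make_ts(rep(3.7, 5000))
  seg <- segment_bursts(flat)
  expect_equal(nrow(seg$bursts), 0)
  expect_equal(burst_statistics(seg, flat)$suppression_ratio, 1)
  loud <- am_tone(cycles = 5)
  seg2 <- segment_bursts(loud, threshold = 1e6)
  expect_equal(nrow(seg2$bursts), 0)
})

test_that("segmentation is invariant under constant offsets", {
  ts <- am_tone(cycles = 6)
  shifted <- make_ts(ts$h_e + 42)
  expect_equal(segment_bursts(ts)$bursts, segment_bursts(shifted)$bursts)
})

test_that("intervals partition the analyzed span and ratios sum to one", {
  ts <- fig3_run()
  seg <- fig3_stats()$seg
  iv <- rbind(seg$bursts, seg$suppression)
  iv <- iv[order(iv$start), ]
  expect_equal(iv$start[1], seg$span[1])
  expect_equal(iv$end[nrow(iv)], seg$span[2])
  expect_true(all(abs(iv$end[-nrow(iv)] - iv$start[-1]) <= 1))
  bs <- fig3_stats()$stats
  burst_frac <- sum(seg$bursts$end - seg$bursts$start) /
    (sum(seg$bursts$end - seg$bursts$start) +
       sum(seg$suppression$end - seg$suppression$start))
  expect_equal(bs$suppression_ratio + burst_frac, 1)
})

test_that("burst statistics from a constructed segmentation are exact", {
  x <- rep(0, 4001)
  ts <- make_ts(x)
  seg <- structure(list(
    bursts = data.frame(start = c(0, 2000), end = c(1000, 3000)),
    suppression = data.frame(start = c(1000, 3000), end = c(2000, 4000)),
    threshold = 0.5, smooth = 50, span = c(0, 4000), channel = "h_e"),
    class = "meso_segments")
  bs <- burst_statistics(seg, ts)
  expect_equal(bs$suppression_ratio, 0.5)
  expect_equal(bs$mean_burst_ms, 1000)
  expect_equal(bs$n_bursts, 2L)
})

test_that("onset and offset frequencies recover constructed chirp bursts", {
  dt <- 1
  t <- seq(0, 1999)
  chirp <- sin(2 * pi * (15 * t / 1000 - 3 * t^2 / (2 * 2000 * 1000)))
  x <- c(rep(0, 1500), chirp, rep(0, 1500), chirp, rep(0, 1500))
  ts <- make_ts(x, dt)
  seg <- segment_bursts(ts, smooth = 50, min_burst = 500)
  expect_equal(nrow(seg$bursts), 2)
  bs <- burst_statistics(seg, ts)
  expect_lt(abs(bs$onset_freq_hz - 15), 2)
  expect_lt(abs(bs$offset_freq_hz - 12), 2)
  expect_gt(bs$onset_freq_hz, bs$offset_freq_hz)
})

test_that("a single-point sweep equals the direct pipeline", {
  P <- tbl3()
  slow <- preset_slow("fig3")
  st <- sim_settings(duration = 15000, dt = 0.1, record_dt = 1,
                     transient_discard = 5000)
  row <- sweep_bursting(P, slow, list(theta_i = 0.1818), st)
  ts <- simulate_model(P, slow, st)
  bs <- burst_statistics(segment_bursts(ts), ts)
  expect_equal(row$n_bursts, bs$n_bursts)
  expect_equal(row$mean_burst_ms, bs$mean_burst_ms)
  expect_equal(row$suppression_ratio, bs$suppression_ratio)
  expect_true(is.na(row$error))
})

test_that("sweep rows record failures without aborting the sweep", {
  P <- tbl3()
  st <- sim_settings(duration = 3000, dt = 0.1, record_dt = 1)
  # the degenerate row falls back to the resting initial state (warning)
  # before its simulation fails
  res <- suppressWarnings(sweep_bursting(P, NULL, list(tau_e = c(138.366, 0)),
                                         st))
  expect_equal(nrow(res), 2)
  expect_true(is.na(res$error[1]))
  expect_false(is.na(res$error[2]))
})
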