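test_that("CSV round trip preserves samples and sampling rate", {
  w <- waveform(stats::rnorm(1000) + 30, fs = 125, channel = "ABP")
  path <- withr::local_tempfile(fileext = ".csv")
  write_waveform_csv(w, path)
  back <- read_waveform(path, "ABP")
  expect_equal(wave_fs(back), 125)
  expect_equal(nrow(back), 1000)
  expect_equal(wave_duration(back), 8)
  expect_equal(back$value, w$value, tolerance = 1e-9)
})

test_that("non-monotonic time column is rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(time_s = c(0, 0.2, 0.1, 0.3),
                                  value = 1:4), path)
  expect_error(read_waveform(path, "ABP"), "monotonic")
})

test_that("EDF round trip recovers both channels within quantization", {
  s <- make_clean_subject(duration_s = 60, seed = 8)
  path <- withr::local_tempfile(fileext = ".edf")
  # generator rounds the beat grid up, so a sub-second tail is dropped
  expect_warning(write_edf(list(ABP = s$abp, FLOW = s$flow), path),
                 "truncated")
  abp2 <- read_waveform(path, "ABP")
  flow2 <- read_edf(path, "FLOW")
  expect_equal(wave_fs(abp2), 125)
  n <- min(nrow(abp2), nrow(s$abp))
  q_abp <- diff(range(s$abp$value)) / 65535
  expect_lt(max(abs(abp2$value[1:n] - s$abp$value[1:n])), 2 * q_abp)
  q_fl <- diff(range(s$flow$value)) / 65535
  m <- min(nrow(flow2), nrow(s$flow))
  expect_lt(max(abs(flow2$value[1:m] - s$flow$value[1:m])), 2 * q_fl)
  expect_error(read_edf(path, "ECG"), "not in EDF")
})

test_that("downsampling 1 kHz to 125 Hz keeps length, peaks and amplitude", {
  t <- seq(0, 10 - 1e-3, by = 1e-3)
  w <- waveform(sin(2 * pi * 1 * t), fs = 1000, channel = "ABP")
  d <- downsample(w, 125)
  expect_equal(nrow(d), 1250)
  expect_equal(wave_fs(d), 125)
  expect_lt(abs(max(d$value) - 1), 0.01)      # 1 Hz passband amplitude
  expect_error(downsample(w, 300), "integer multiple")
  expect_identical(downsample(w, 1000), w)
  # peak positions preserved within one output sample
  abp1k <- gen_abp_waveform(rep(400, 50), rep(42, 50), rep(29, 50),
                            fs = 1000)
  b1k <- detect_beats(waveform(abp1k$value[seq(1, nrow(abp1k), 8)],
                               fs = 125, channel = "ABP"))
  bds <- detect_beats(downsample(abp1k, 125))
  m <- min(nrow(b1k), nrow(bds))
  expect_lt(max(abs(b1k$beat_time_s[1:m] - bds$beat_time_s[1:m])), 1 / 125 + 1e-9)
})

test_that("detrending preserves the mean and is idempotent in practice", {
  s <- make_clean_subject(duration_s = 300, seed = 14)
  inj <- inject_artifacts(s$abp, drift_amplitude = 10, seed = 15)
  d1 <- remove_nonlinear_trend(inj$wave)
  expect_lt(abs(mean(d1$detrended$value) - mean(inj$wave$value)) /
              abs(mean(inj$wave$value)), 1e-6)
  expect_lt(abs(mean(d1$trend$trend)), 1e-9 * stats::sd(inj$wave$value))
  # near-idempotence: a second application only touches the
  # transition-band remnant of the first (H(1-H) skirt), a few % at
  # most of the first application's change
  d2 <- remove_nonlinear_trend(d1$detrended)
  change1 <- sqrt(mean((d1$detrended$value - inj$wave$value)^2))
  change2 <- sqrt(mean((d2$detrended$value - d1$detrended$value)^2))
  expect_lt(change2, 0.05 * change1)
  expect_error(remove_nonlinear_trend(s$flow), "ABP")
  short <- waveform(stats::rnorm(125), fs = 125, channel = "ABP")
  expect_error(remove_nonlinear_trend(short), "shorter")
})

test_that("detrending a drift-free constant-beat signal is a near-identity", {
  abp <- gen_abp_waveform(rep(400, 400), rep(42, 400), rep(29, 400))
  d <- remove_nonlinear_trend(abp)
  expect_lt(max(abs(d$detrended$value - abp$value)), 0.5)
})

test_that("detrending leaves DFA exponents of trend-free series intact", {
  s <- make_clean_subject(duration_s = 1800, dbp_alpha = 0.93, seed = 21)
  b0 <- detect_beats(s$abp)
  bd <- detect_beats(remove_nonlinear_trend(s$abp)$detrended)
  n <- min(sum(!is.na(b0$dbp)), sum(!is.na(bd$dbp)))
  a0 <- scaling_exponents(b0$dbp[1:n])
  ad <- scaling_exponents(bd$dbp[1:n])
  expect_lt(abs(ad$alpha1 - a0$alpha1), 0.05)
  expect_lt(abs(ad$alpha2 - a0$alpha2), 0.05)
})

test_that("feature tables round-trip and keep the lead column order", {
  rows <- tibble::tibble(DBP_mu = c(25, 27), subject_id = c("A", "A"),
                         window_start_s = c(0, 30),
                         qc_pass = c(TRUE, TRUE))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(rows, path)
  back <- read_feature_table(path)
  expect_equal(names(back)[1:3],
               c("subject_id", "window_start_s", "qc_pass"))
  expect_equal(back$DBP_mu, c(25, 27))
  write_feature_table(rows[0, ], path)
  expect_equal(nrow(read_feature_table(path)), 0)
})
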