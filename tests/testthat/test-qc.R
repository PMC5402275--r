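test_that("window enumeration follows the 10-min / 30-s grid", {
  w <- iter_windows(660)
  expect_equal(w$start_s, c(0, 30, 60))
  expect_equal(unique(w$end_s - w$start_s), 600)
  expect_equal(nrow(iter_windows(600)), 1)
  expect_equal(nrow(iter_windows(9360)), 293)
  expect_warning(short <- iter_windows(500), "shorter")
  expect_equal(nrow(short), 0)
})

test_that("successive-change outlier removal follows the 150% rule", {
  r <- remove_outliers(c(100, 110, 105))
  expect_equal(r$loss_fraction, 0)
  r <- remove_outliers(c(100, 300, 110))
  expect_equal(r$values, c(100, 110))
  expect_equal(r$loss_fraction, 1 / 3)
  # the reference is the last RETAINED point: a spike cannot cascade
  r <- remove_outliers(c(100, 900, 101, 102))
  expect_equal(r$values, c(100, 101, 102))
  # first point never dropped
  r <- remove_outliers(c(1000, 100, 101))
  expect_true(r$kept[1])
  expect_error(remove_outliers(c(-1, 2)), "positive")
})

test_that("QC verdicts match hand-computed ground truth on fixtures", {
  s <- make_clean_subject(duration_s = 660, seed = 61)
  beats <- detect_beats(s$abp)
  breaths <- detect_breaths(s$flow)
  clean <- qc_window(0, 600, beats, breaths)
  expect_true(clean$qc_pass)
  expect_equal(clean$reject_reasons[[1]], character(0))

  # 20 s beat gap -> BEAT_GAP
  gap <- inject_artifacts(s$abp,
                          gap_spec = tibble::tibble(start_s = 100,
                                                    duration_s = 20))$wave
  qg <- qc_window(0, 600, detect_beats(gap), breaths)
  expect_false(qg$qc_pass)
  expect_true("BEAT_GAP" %in% qg$reject_reasons[[1]])

  # one spiked beat driving the SBP range to >= 30 mmHg -> SBP_RANGE
  spiked <- beats
  spiked$sbp[50] <- spiked$sbp[50] + 35
  qs <- qc_window(0, 600, spiked, breaths)
  expect_true("SBP_RANGE" %in% qs$reject_reasons[[1]])

  # breath rate at exactly 20/min fails (strict), heart rate bounds inclusive
  few_breaths <- breaths[seq_len(200), ]   # 200 in 600 s = 20/min
  qb <- qc_window(0, 600, beats, few_breaths)
  expect_true("BREATH_LOW" %in% qb$reject_reasons[[1]])

  empty_beats <- beats[0, ]
  qe <- qc_window(0, 600, empty_beats, breaths)
  expect_true(all(c("RATE_LOW", "BEAT_GAP") %in% qe$reject_reasons[[1]]))
})

test_that("windows reject when the 30% loss cap is exceeded", {
  s <- make_clean_subject(duration_s = 660, seed = 62)
  beats <- detect_beats(s$abp)
  breaths <- detect_breaths(s$flow)
  corrupted <- beats
  set.seed(63)
  idx <- sample(which(!is.na(corrupted$pi_ms)),
                round(0.4 * nrow(corrupted)))
  corrupted$pi_ms[idx] <- corrupted$pi_ms[idx] * 10  # 900% jumps
  q <- qc_window(0, 600, corrupted, breaths)
  expect_true("LOSS_EXCEEDED" %in% q$reject_reasons[[1]])
  expect_gt(q$loss[[1]][["PI"]], 0.30)
})

test_that("QC is deterministic and monotone under added artifacts", {
  s <- make_clean_subject(duration_s = 660, seed = 64)
  beats <- detect_beats(s$abp)
  breaths <- detect_breaths(s$flow)
  q1 <- qc_window(0, 600, beats, breaths)
  q2 <- qc_window(0, 600, beats, breaths)
  expect_identical(q1$qc_pass, q2$qc_pass)
  expect_identical(q1$reject_reasons, q2$reject_reasons)
  # adding an artifact can remove a pass but never create one
  spiked <- beats
  spiked$sbp[10] <- spiked$sbp[10] + 50
  expect_false(qc_window(0, 600, spiked, breaths)$qc_pass &&
                 !q1$qc_pass)
})

test_that("artifact-free full windows all qualify", {
  s <- make_clean_subject(duration_s = 720, seed = 65)
  qc <- qc_windows(detect_beats(s$abp), detect_breaths(s$flow), 720)
  expect_equal(nrow(qc), 5)
  expect_true(all(qc$qc_pass))
  rep <- qc_report(qc)
  expect_true(all(rep$pass))
  expect_true(all(rep$reasons == ""))
  expect_true(all(c("loss_SBP", "loss_IBI") %in% names(rep)))
})
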