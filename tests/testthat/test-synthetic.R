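test_that("beat-series generator hits target mean, sd, and exponent", {
  x <- gen_beat_series(1500, mean = 29.0, sd = 4.6, alpha_target = 0.93,
                       seed = 11)$value
  expect_lt(abs(mean(x) - 29.0) / 29.0, 0.10)
  expect_lt(abs(stats::sd(x) - 4.6) / 4.6, 0.10)
  a <- scaling_exponents(x)
  expect_gte(a$alpha2, 0.78)
  expect_lte(a$alpha2, 1.08)
  expect_error(gen_beat_series(1500, 29, 0, 0.9), "sd")
  expect_error(gen_beat_series(1500, 29, 2, 1.6), "alpha_target")
  expect_error(gen_beat_series(10, 29, 2, 0.9), "n_beats")
})

test_that("shuffling an uncorrelated series leaves alpha unchanged", {
  x <- gen_beat_series(2000, 100, 10, 0.5, seed = 5)$value
  a0 <- scaling_exponents(x)
  set.seed(6)
  a1 <- scaling_exponents(sample(x))
  expect_lt(abs(a1$alpha1 - a0$alpha1), 0.1)
  expect_lt(abs(a1$alpha2 - a0$alpha2), 0.1)
})

test_that("ABP waveform carries one detectable peak per beat with exact extrema", {
  abp <- gen_abp_waveform(rep(400, 150), rep(42, 150), rep(29, 150))
  expect_equal(wave_fs(abp), 125)
  b <- detect_beats(abp)
  expect_equal(nrow(b), 150)
  expect_true(all(abs(b$pi_ms[-150] - 400) <= 8))
  expect_lt(max(abs(b$sbp - 42)), 0.1)
  expect_lt(max(abs(b$dbp - 29), na.rm = TRUE), 0.1)
  expect_error(gen_abp_waveform(rep(400, 5), rep(30, 5), rep(35, 5)),
               "SBP > DBP")
})

test_that("variable per-beat series round-trip through the waveform", {
  s <- make_clean_subject(duration_s = 180, seed = 31)
  b <- detect_beats(s$abp)
  m <- min(nrow(b), length(s$sbp))
  expect_lt(max(abs(b$sbp[1:m] - s$sbp[1:m])), 0.1)
  # trough between peaks k,k+1 is the following beat's diastolic value
  expect_lt(max(abs(b$dbp[1:(m - 1)] - s$dbp[2:m])), 0.1)
})

test_that("airflow waveform yields exact breath counts and IBI recovery", {
  fl <- gen_airflow_waveform(rep(1000, 60))
  br <- detect_breaths(fl)
  expect_gte(nrow(br), 59)  # final onset can fall on the record edge
  expect_lte(nrow(br), 60)
  expect_lt(max(abs(br$ibi_ms - 1000), na.rm = TRUE), 8)
  expect_error(gen_airflow_waveform(c(1000, 400)), "500")
})

test_that("detected-IBI series preserves the generator's DFA exponent", {
  devs <- vapply(1:5, function(s) {
    ibi <- gen_beat_series(400, 1000, 60, 0.8, seed = 200 + s)$value
    ibi <- pmin(pmax(ibi, 520), 2950)
    br <- detect_breaths(gen_airflow_waveform(ibi))
    got <- scaling_exponents(br$ibi_ms[!is.na(br$ibi_ms)])$alpha2
    want <- scaling_exponents(ibi[seq_len(nrow(br) - 1)])$alpha2
    got - want
  }, numeric(1))
  expect_lt(max(abs(devs)), 0.15)
})

test_that("artifact injection is the identity at zero rates and logs events", {
  s <- make_clean_subject(duration_s = 120, seed = 41)
  out0 <- inject_artifacts(s$abp, 0, spike_rate = 0, seed = 1)
  expect_equal(out0$wave$value, s$abp$value)
  expect_equal(nrow(out0$events), 0)
  gap <- tibble::tibble(start_s = 40, duration_s = 20)
  outg <- inject_artifacts(s$abp, gap_spec = gap)
  expect_true("gap" %in% outg$events$type)
  seg <- outg$wave$value[(45 * 125):(55 * 125)]
  expect_lt(stats::sd(seg), 1e-9)
  outs <- inject_artifacts(s$abp, spike_rate = 6, seed = 2)
  expect_gt(sum(outs$events$type == "spike"), 0)
})

test_that("feature-level cohort draws group distributions and is seed-stable", {
  co <- gen_cohort(n_cases = 60, n_controls = 60, seed = 9)
  expect_equal(nrow(co), 120)
  p <- default_feature_params()
  dbp <- p[p$feature == "DBP_mu", ]
  m1 <- mean(co$DBP_mu[co$label == 1])
  m0 <- mean(co$DBP_mu[co$label == 0])
  expect_lt(abs(m1 - dbp$case_mean), 2 * dbp$case_sd / sqrt(60))
  expect_lt(abs(m0 - dbp$control_mean), 2 * dbp$control_sd / sqrt(60))
  expect_identical(co, gen_cohort(n_cases = 60, n_controls = 60, seed = 9))
})

test_that("identical group parameters carry no discriminative signal", {
  p <- default_feature_params()
  p$case_mean <- p$control_mean
  p$case_sd <- p$control_sd
  co <- gen_cohort(n_cases = 100, n_controls = 100, feature_params = p,
                   seed = 13)
  r <- roc_with_delong(co$DBP_mu, co$label)
  expect_lt(abs(r$auc - 0.5), 0.1)
})

test_that("large-n cohort AUC matches the binormal closed form", {
  co <- gen_cohort(n_cases = 500, n_controls = 500, seed = 17)
  p <- default_feature_params()
  dbp <- p[p$feature == "DBP_mu", ]
  want <- binormal_auc(dbp$case_mean, dbp$case_sd,
                       dbp$control_mean, dbp$control_sd)
  got <- roc_with_delong(-co$DBP_mu, co$label)$auc  # cases have lower DBP
  expect_lt(abs(got - want), 0.02)
})
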