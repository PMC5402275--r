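test_that("Mann-Whitney AUC matches the brute-force all-pairs count", {
  expect_equal(mann_whitney(c(1, 2, 3), c(4, 5, 6))$auc_equivalent, 1)
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$auc_equivalent, 0.5)
  for (s in 1:10) {
    set.seed(s)
    a <- stats::rnorm(20); b <- stats::rnorm(7) + 0.5
    expect_equal(mann_whitney(a, b)$auc_equivalent, all_pairs_auc(a, b))
  }
  # identical values across both groups
  r <- mann_whitney(rep(2, 5), rep(2, 5))
  expect_equal(r$p, 1)
  expect_equal(r$auc_equivalent, 0.5)
})

test_that("Mann-Whitney p agrees with the tie-corrected normal approximation", {
  set.seed(4)
  a <- round(stats::rnorm(20), 1); b <- round(stats::rnorm(7) + 1, 1)
  wt <- stats::wilcox.test(b, a, exact = FALSE, correct = FALSE)
  expect_equal(mann_whitney(a, b)$p, wt$p.value, tolerance = 1e-12)
})

test_that("binormal closed form reproduces known values", {
  expect_equal(binormal_auc(5, 1, 5, 2), 0.5)
  expect_equal(binormal_auc(25.0, 3.9, 29.0, 4.6), 0.7464, tolerance = 1e-4)
  expect_equal(binormal_auc(24.6, 3.5, 29.4, 4.1), 0.8134, tolerance = 1e-4)
})

test_that("empirical AUC equals U/(n1 n2) exactly on identical scores", {
  for (s in 1:10) {
    set.seed(s)
    y <- c(rep(1, 7), rep(0, 20))
    x <- round(stats::rnorm(27) + y, 1)  # rounding forces ties
    expect_equal(roc_with_delong(x, y)$auc,
                 mann_whitney(x[y == 0], x[y == 1])$auc_equivalent,
                 tolerance = 1e-12)
  }
})

test_that("DeLong AUC, SE and CI match the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(7)
  y <- c(rep(1, 7), rep(0, 20))
  x <- stats::rnorm(27) + 1.3 * y
  mine <- roc_with_delong(x, y)
  ref <- suppressMessages(pROC::roc(y, x, direction = "<"))
  expect_equal(mine$auc, as.numeric(pROC::auc(ref)))
  ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(mine$ci, ci[c(1, 3)], tolerance = 1e-9)
  y2 <- stats::rnorm(27) + 0.8 * y
  cmp <- delong_compare(x, y2, y)
  ref2 <- suppressMessages(pROC::roc(y, y2, direction = "<"))
  rt <- pROC::roc.test(ref, ref2, method = "delong", paired = TRUE)
  expect_equal(cmp$p, rt$p.value, tolerance = 1e-9)
})

test_that("self-comparison yields p = 1 and mismatched inputs error", {
  set.seed(8)
  y <- c(rep(1, 5), rep(0, 10)); x <- stats::rnorm(15)
  expect_equal(delong_compare(x, x, y)$p, 1)
  expect_error(delong_compare(x, x[-1], y), "same subjects")
  expect_error(roc_with_delong(x, rep(1, 15)), "both")
})

test_that("perfectly separated scores give AUC 1, SE 0 and LR+ 4", {
  y <- c(rep(0, 20), rep(1, 7))
  x <- c(stats::rnorm(20), stats::rnorm(7) + 100)
  r <- roc_with_delong(x, y)
  expect_equal(r$auc, 1)
  expect_equal(r$se, 0)
  lr <- lr_at_specificity(r, 0.75)
  expect_equal(lr$lr_plus, 4)
  # a useless classifier sits near LR+ 1
  set.seed(9)
  r0 <- roc_with_delong(stats::rnorm(400), rep(c(0, 1), 200))
  expect_lt(abs(lr_at_specificity(r0)$lr_plus - 1), 0.5)
})

test_that("5 of 7 cases above the specificity-75% threshold gives LR+ 2.86", {
  # discrete 7-vs-20 cohort constructed so exactly 5 controls and
  # 5 cases exceed the chosen operating threshold
  controls <- c(seq(1, 15), 21:25)
  cases <- c(16, 17, 26:30)
  y <- c(rep(0, 20), rep(1, 7))
  r <- roc_with_delong(c(controls, cases), y)
  lr <- lr_at_specificity(r, 0.75)
  expect_equal(lr$specificity, 0.75)
  expect_equal(lr$lr_plus, (5 / 7) / 0.25, tolerance = 1e-9)
})

test_that("logistic fit matches glm and keeps rank invariances", {
  set.seed(11)
  y <- c(rep(1, 7), rep(0, 20))
  x <- stats::rnorm(27) + y
  df <- tibble::tibble(label = y, f = x)
  m <- fit_logistic(df, predictors = "f")
  g <- stats::glm(label ~ f, data = df, family = stats::binomial())
  expect_equal(unname(m$coefficients), unname(stats::coef(g)),
               tolerance = 1e-6)
  expect_true(all(m$probabilities > 0 & m$probabilities < 1))
  # monotone transform of the sole predictor leaves the ROC unchanged
  m2 <- fit_logistic(tibble::tibble(label = y, f = exp(x)),
                     predictors = "f")
  expect_equal(m2$auc, m$auc)
  # permuted labels carry no signal
  set.seed(12)
  null_auc <- replicate(100, {
    fit_logistic(tibble::tibble(label = sample(y), f = x),
                 predictors = "f")$auc
  })
  expect_lt(abs(mean(null_auc) - 0.5), 0.1)
})

test_that("separated data fall back to a flagged penalized fit", {
  y <- c(rep(0, 10), rep(1, 10))
  df <- tibble::tibble(label = y, f = c(1:10, 21:30))
  m <- fit_logistic(df, predictors = "f")
  expect_equal(m$method, "firth")
  expect_true(all(is.finite(m$coefficients)))
  expect_equal(m$auc, 1)
})

test_that("large-n single-predictor model approaches the binormal AUC", {
  co <- gen_cohort(n_cases = 500, n_controls = 500, seed = 15)
  m <- fit_logistic(co, predictors = "DBP_mu")
  p <- default_feature_params()
  dbp <- p[p$feature == "DBP_mu", ]
  want <- binormal_auc(dbp$case_mean, dbp$case_sd,
                       dbp$control_mean, dbp$control_sd)
  expect_lt(abs(m$auc - want), 0.02)
  # cases have LOWER mean DBP: the fitted coefficient must be negative
  expect_lt(m$coefficients[["DBP_mu"]], 0)
})

test_that("collinearity screen excludes identical and near-identical pairs", {
  set.seed(16)
  feats <- tibble::tibble(a = stats::rnorm(27))
  feats$b <- feats$a + stats::rnorm(27) * 0.01
  feats$c <- stats::rnorm(27)
  out <- collinearity_screen(
    data.frame(f1 = c("a", "a"), f2 = c("b", "c")), feats)
  expect_false(out$allowed[out$feature_2 == "b"])
  # independent features: ~5% exclusion rate
  set.seed(17)
  excl <- replicate(400, {
    f <- tibble::tibble(x = stats::rnorm(27), y = stats::rnorm(27))
    !collinearity_screen(data.frame("x", "y"), f)$allowed
  })
  expect_lt(abs(mean(excl) - 0.05), 0.03)
})

test_that("LOOCV produces one held-out probability per subject,
           order-invariant, and is not optimistic", {
  set.seed(18)
  y <- c(rep(1, 7), rep(0, 20))
  x <- stats::rnorm(27) + 1.5 * y
  df <- tibble::tibble(label = y, f = x)
  lv <- loocv_evaluate(df, predictors = "f")
  expect_length(lv$loocv$probabilities, 27)
  perm <- sample(27)
  lv2 <- loocv_evaluate(df[perm, ], predictors = "f")
  expect_equal(lv2$loocv$probabilities, lv$loocv$probabilities[perm],
               tolerance = 1e-9)
  # optimism: held-out AUC does not beat the apparent AUC on average
  set.seed(19)
  gaps <- replicate(20, {
    xx <- stats::rnorm(27) + 1.2 * y
    d <- tibble::tibble(label = y, f = xx)
    m <- loocv_evaluate(d, predictors = "f")
    m$auc - m$loocv$auc
  })
  expect_gte(mean(gaps), 0)
  # under permuted labels pooled LOOCV is pessimistic, never optimistic
  set.seed(20)
  null_auc <- replicate(50, {
    d <- tibble::tibble(label = sample(y), f = x)
    loocv_evaluate(d, predictors = "f")$loocv$auc
  })
  expect_lt(mean(null_auc), 0.62)
})

test_that("model tidiers expose coefficients and summary metrics", {
  set.seed(21)
  y <- c(rep(1, 7), rep(0, 20))
  df <- tibble::tibble(label = y, f = stats::rnorm(27) + y)
  m <- loocv_evaluate(df, predictors = "f")
  td <- tidy(m)
  expect_equal(td$term, c("(Intercept)", "f"))
  gl <- glance(m)
  expect_equal(gl$auc, m$auc)
  expect_false(is.na(gl$loocv_auc))
  expect_s3_class(ggplot2::autoplot(m), "ggplot")
})
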