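#' Pipeline configuration with study defaults
#'
#' Every numeric default reproduces the reference analysis parameters:
#' 125 Hz working rate, 1000 ms median window for baseline detrending,
#' 10 min windows shifted by 30 s, heart-rate band 40-250 bpm, breath
#' rate strictly above 20/min, 15 s beat-gap limit, beat-to-beat SBP
#' range below 30 mmHg, 150% successive-change outlier rule with a 30%
#' per-window loss cap, and DFA exponents over 4-15 and 15-50 events.
#'
#' @param target_fs working sampling rate (Hz).
#' @param intermediate_fs rate at which the detrending median runs.
#' @param median_window_ms detrending median window (ms).
#' @param window_s,step_s analysis window length and shift (s).
#' @param hr_bpm inclusive heart-rate band (bpm).
#' @param breath_min_per_min strict breath-rate lower bound (/min).
#' @param max_gap_s beat-gap limit (s).
#' @param sbp_range_mmHg SBP range limit (mmHg).
#' @param max_change successive-change limit (1.5 = 150%).
#' @param max_loss per-window loss cap (0.30 = 30%).
#' @param dfa_range1,dfa_range2 DFA box ranges (events).
#' @param detrend detrend the ABP signal before beat extraction.
#' @param lr_specificity specificity for LR+ reporting.
#' @param conf_level CI level for DeLong intervals.
#' @param seed integer seed for any stochastic stage.
#' @return a named list of class `run_config`.
#' @export
run_config <- function(target_fs = 125, intermediate_fs = 5,
                       median_window_ms = 1000, window_s = 600,
                       step_s = 30, hr_bpm = c(40, 250),
                       breath_min_per_min = 20, max_gap_s = 15,
                       sbp_range_mmHg = 30, max_change = 1.5,
                       max_loss = 0.30, dfa_range1 = c(4, 15),
                       dfa_range2 = c(15, 50), detrend = TRUE,
                       lr_specificity = 0.75, conf_level = 0.95,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(all(vapply(cfg[c("target_fs", "intermediate_fs",
                             "median_window_ms", "window_s", "step_s",
                             "max_gap_s", "sbp_range_mmHg", "max_change",
                             "max_loss")], function(v) all(v > 0),
                       logical(1))))
  class(cfg) <- "run_config"
  cfg
}

#' Extract per-window features from one subject's recordings
#'
#' Downsample to the working rate, detrend the pressure channel, detect
#' beats and breaths, qualify windows and compute features.
#'
#' @param abp,flow [waveform()] tibbles for one subject.
#' @param subject_id identifier for the output rows.
#' @param config a [run_config()].
#' @return list: `features` (per-window tibble), `qc` (full QC tibble),
#'   `beats`, `breaths`.
#' @export
extract_subject <- function(abp, flow, subject_id = "S001",
                            config = run_config()) {
  abp <- downsample(abp, config$target_fs)
  flow <- downsample(flow, config$target_fs)
  if (config$detrend)
    abp <- remove_nonlinear_trend(
      abp, intermediate_fs = config$intermediate_fs,
      median_window_ms = config$median_window_ms)$detrended
  beats <- detect_beats(abp)
  breaths <- detect_breaths(flow)
  dur <- min(wave_duration(abp), wave_duration(flow))
  qc <- qc_windows(beats, breaths, dur,
                   window_s = config$window_s, step_s = config$step_s,
                   hr_bpm = config$hr_bpm,
                   breath_min_per_min = config$breath_min_per_min,
                   max_gap_s = config$max_gap_s,
                   sbp_range_mmHg = config$sbp_range_mmHg,
                   max_change = config$max_change,
                   max_loss = config$max_loss)
  feats <- window_features(qc, subject_id = subject_id,
                           range1 = config$dfa_range1,
                           range2 = config$dfa_range2)
  list(features = feats, qc = qc, beats = beats, breaths = breaths)
}

#' Run the full analysis pipeline on a cohort
#'
#' simulate/load -> preprocess -> extract -> window/QC -> DFA ->
#' aggregate -> fit/evaluate, as one reproducible run. The cohort is a
#' tibble as produced by [gen_cohort()]: waveform-level (list-columns
#' `abp`, `flow`) or feature-level (feature columns already present,
#' in which case extraction is skipped).
#'
#' @param cohort cohort tibble with `subject_id` and `label` columns.
#' @param config a [run_config()].
#' @param predictors list of character vectors, one model each;
#'   default: univariate detrended mean DBP.
#' @param loocv also evaluate each model with leave-one-out CV.
#' @return list of class `ivh_run`: `window_features`,
#'   `subject_features` (with labels joined), `qc_summary`, `models`
#'   (named list of `ivh_model`), and `config`.
#' @export
run_pipeline <- function(cohort, config = run_config(),
                         predictors = list("DBP_mu"), loocv = FALSE) {
  waveform_level <- all(c("abp", "flow") %in% names(cohort))
  if (waveform_level) {
    per_subj <- purrr::pmap(
      list(cohort$abp, cohort$flow, cohort$subject_id),
      function(a, f, id) extract_subject(a, f, id, config))
    window_features <- purrr::map_dfr(per_subj, "features")
    qc_summary <- purrr::map_dfr(seq_along(per_subj), function(i) {
      rep <- qc_report(per_subj[[i]]$qc)
      dplyr::mutate(rep, subject_id = cohort$subject_id[i],
                    .before = 1)
    })
    subject_features <- aggregate_subjects(window_features)
  } else {
    feat_cols <- intersect(default_feature_params()$feature,
                           names(cohort))
    if (!length(feat_cols))
      stop("cohort has neither waveforms nor feature columns",
           call. = FALSE)
    window_features <- NULL
    qc_summary <- NULL
    subject_features <- cohort[c("subject_id", feat_cols)]
  }
  subject_features <- dplyr::inner_join(
    cohort[c("subject_id", "label")], subject_features,
    by = "subject_id")
  if (nrow(subject_features) == 0 ||
      length(unique(subject_features$label)) < 2)
    stop("no usable subjects in both classes after QC", call. = FALSE)
  models <- purrr::map(predictors, function(pv) {
    if (loocv)
      loocv_evaluate(subject_features, outcome = "label",
                     predictors = pv,
                     lr_specificity = config$lr_specificity,
                     conf_level = config$conf_level)
    else
      fit_logistic(subject_features, outcome = "label",
                   predictors = pv,
                   lr_specificity = config$lr_specificity,
                   conf_level = config$conf_level)
  })
  names(models) <- purrr::map_chr(predictors, paste, collapse = "+")
  out <- list(window_features = window_features,
              subject_features = subject_features,
              qc_summary = qc_summary,
              models = models, config = config)
  class(out) <- "ivh_run"
  out
}

#' @export
print.ivh_run <- function(x, ...) {
  cat(sprintf("<ivh_run> %d subjects, %d model(s)\n",
              nrow(x$subject_features), length(x$models)))
  for (nm in names(x$models)) {
    m <- x$models[[nm]]
    cat(sprintf("  %-24s AUC %.3f (%.3f, %.3f)\n", nm, m$auc,
                m$ci[1], m$ci[2]))
  }
  invisible(x)
}

#' Per-window predicted probability trace for one subject
#'
#' Applies a fitted model to each analysis window of a recording pair,
#' in time order. Non-qualifying windows are emitted with `NA`
#' probability — never interpolated — mirroring how a bedside monitor
#' would display gaps.
#'
#' @param abp,flow the subject's recordings.
#' @param model a fitted `ivh_model` whose predictors are window
#'   features.
#' @param config a [run_config()].
#' @return tibble: `window_start_s`, `qc_pass`, `probability`.
#' @export
monitor_probability <- function(abp, flow, model,
                                config = run_config()) {
  ex <- extract_subject(abp, flow, "monitor", config)
  f <- ex$features
  prob <- rep(NA_real_, nrow(f))
  ok <- f$qc_pass & stats::complete.cases(f[model$predictors])
  if (any(ok)) prob[ok] <- predict(model, f[ok, ])
  tibble::tibble(window_start_s = f$window_start_s,
                 qc_pass = f$qc_pass, probability = prob)
}
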