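#' Extract per-window features from qualified windows
#'
#' For each window and each of the five series (MAP, SBP, DBP, PI,
#' IBI): the mean and the two DFA scaling exponents of the cleaned
#' series, as columns `<SERIES>_<mu|alpha1|alpha2>`. Exponents are `NA`
#' where the cleaned series is shorter than 100 events (too short for
#' the 50-event box) or degenerate. Non-qualifying windows keep their
#' row with `qc_pass = FALSE` and `NA` features so the window grid
#' stays complete.
#'
#' @param qc tibble from [qc_windows()].
#' @param subject_id identifier copied into every row.
#' @param dfa_scales,range1,range2 passed to [scaling_exponents()].
#' @return tibble: `subject_id`, `window_start_s`, `qc_pass`, 15
#'   feature columns.
#' @export
window_features <- function(qc, subject_id = "S001", dfa_scales = 4:50,
                            range1 = c(4, 15), range2 = c(15, 50)) {
  one <- function(row) {
    base <- tibble::tibble(subject_id = subject_id,
                           window_start_s = row$start_s,
                           qc_pass = row$qc_pass)
    feats <- purrr::imap(row$series[[1]], function(v, nm) {
      out <- c(mu = NA_real_, alpha1 = NA_real_, alpha2 = NA_real_)
      if (!row$qc_pass) return(stats::setNames(out, paste0(nm, "_", names(out))))
      out["mu"] <- mean(v)
      if (length(v) >= 100 && stats::sd(v) > 0) {
        d <- scaling_exponents(v, scales = dfa_scales,
                               range1 = range1, range2 = range2)
        if (!d$degenerate) {
          out["alpha1"] <- d$alpha1
          out["alpha2"] <- d$alpha2
        }
      }
      stats::setNames(out, paste0(nm, "_", names(out)))
    })
    dplyr::bind_cols(base, tibble::as_tibble(as.list(unlist(unname(feats)))))
  }
  purrr::map_dfr(seq_len(nrow(qc)), function(i) one(qc[i, ]))
}

#' Aggregate window features to one vector per subject
#'
#' Arithmetic mean of each feature across a subject's qualifying
#' windows. Subjects with no qualifying window are excluded and listed
#' in the `excluded` attribute.
#'
#' @param features per-window feature tibble ([window_features()] rows
#'   for one or more subjects).
#' @return tibble with one row per retained subject.
#' @export
aggregate_subjects <- function(features) {
  feat_cols <- setdiff(names(features),
                       c("subject_id", "window_start_s", "qc_pass"))
  qualified <- dplyr::filter(features, .data$qc_pass)
  excluded <- setdiff(unique(features$subject_id),
                      unique(qualified$subject_id))
  if (length(excluded))
    message("excluded (no qualifying windows): ",
            paste(excluded, collapse = ", "))
  out <- qualified |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(feat_cols),
                                   ~ mean(.x, na.rm = TRUE)),
                     n_windows = dplyr::n(), .groups = "drop")
  attr(out, "excluded") <- excluded
  out
}
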