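# Sliding-window qualification: running 10-min windows shifted in 30-s
# increments, with rule-based rejection and per-series outlier removal.

#' Enumerate running analysis windows
#'
#' Half-open windows `[k step, k step + window)` for
#' `k = 0 .. floor((duration - window) / step)`; no partial trailing
#' window is emitted.
#'
#' @param duration_s total record duration in seconds.
#' @param window_s window length (default 600 s = 10 min).
#' @param step_s shift between consecutive windows (default 30 s).
#' @return tibble of `start_s`, `end_s`; zero rows (with a warning) if
#'   the record is shorter than one window.
#' @export
#' @examples
#' iter_windows(660) # 3 windows: 0, 30, 60
iter_windows <- function(duration_s, window_s = 600, step_s = 30) {
  check_number(window_s, "window_s", lower = 0, strict_lower = TRUE)
  check_number(step_s, "step_s", lower = 0, strict_lower = TRUE)
  if (duration_s < window_s) {
    warning("record shorter than one analysis window")
    return(tibble::tibble(start_s = numeric(), end_s = numeric()))
  }
  k <- 0:((duration_s - window_s) %/% step_s)
  tibble::tibble(start_s = k * step_s, end_s = k * step_s + window_s)
}

#' Remove successive-change outliers from a per-event series
#'
#' Scans left to right and drops point `i` when its relative change
#' from the last *retained* point exceeds `max_change` (150%):
#' `|x_i - x_ref| / x_ref > 1.5`. Referencing the last retained (not
#' last raw) point prevents one spike from cascading rejections of the
#' valid points after it. The first point is never dropped (it has no
#' reference).
#'
#' @param x numeric vector of positive per-event values (length >= 2).
#' @param max_change maximum allowed relative change (1.5 = 150%).
#' @return list with `values` (retained points), `kept` (logical mask),
#'   and `loss_fraction` (dropped / total). Callers reject a window
#'   when `loss_fraction` exceeds the 30% cap.
#' @export
#' @examples
#' remove_outliers(c(100, 300, 110))$loss_fraction # 300 dropped -> 1/3
remove_outliers <- function(x, max_change = 1.5) {
  if (length(x) < 2) stop("series must have length >= 2", call. = FALSE)
  if (any(x <= 0 | is.na(x))) stop("values must be positive", call. = FALSE)
  kept <- logical(length(x))
  kept[1] <- TRUE
  ref <- x[1]
  for (i in 2:length(x)) {
    if (abs(x[i] - ref) / ref <= max_change) {
      kept[i] <- TRUE
      ref <- x[i]
    }
  }
  list(values = x[kept], kept = kept,
       loss_fraction = mean(!kept))
}

#' Qualify one analysis window and clean its series
#'
#' Applies the qualification rules to the beats and breaths falling in
#' `[start_s, end_s)`:
#' \describe{
#'   \item{RATE_LOW / RATE_HIGH}{mean heart rate outside 40-250 bpm
#'     (bounds inclusive: 40 and 250 pass);}
#'   \item{BREATH_LOW}{mean breath rate of 20/min or less (strictly
#'     more than 20 passes);}
#'   \item{BEAT_GAP}{any gap without detected beats longer than 15 s,
#'     counting the edges from window start to the first beat and from
#'     the last beat to window end;}
#'   \item{SBP_RANGE}{beat-to-beat SBP range of 30 mmHg or more;}
#'   \item{LOSS_EXCEEDED}{any series losing more than 30% of its
#'     points to successive-change outlier removal.}
#' }
#' Outlier removal ([remove_outliers()]) is applied per series (SBP,
#' DBP, MAP, PI, IBI) and the cleaned series are returned with the
#' verdict. QC failure is data, not an error.
#'
#' @param start_s,end_s window bounds (half-open).
#' @param beats a `beat_tbl` from [detect_beats()] covering the record.
#' @param breaths a `breath_tbl` from [detect_breaths()].
#' @param hr_bpm inclusive allowed mean heart-rate range.
#' @param breath_min_per_min strict lower bound on mean breath rate.
#' @param max_gap_s beat-gap limit in seconds.
#' @param sbp_range_mmHg SBP range must stay strictly below this.
#' @param max_change,max_loss outlier-removal parameters.
#' @return one-row tibble: bounds, `qc_pass`, `reject_reasons`
#'   (list-column of rule codes), `series` (list-column of cleaned
#'   per-series values) and `loss` (list-column of per-series loss
#'   fractions).
#' @export
qc_window <- function(start_s, end_s, beats, breaths,
                      hr_bpm = c(40, 250), breath_min_per_min = 20,
                      max_gap_s = 15, sbp_range_mmHg = 30,
                      max_change = 1.5, max_loss = 0.30) {
  dur_min <- (end_s - start_s) / 60
  bw <- beats[beats$beat_time_s >= start_s & beats$beat_time_s < end_s, ]
  rw <- breaths[breaths$breath_time_s >= start_s &
                  breaths$breath_time_s < end_s, ]
  reasons <- character()
  hr <- nrow(bw) / dur_min
  if (hr < hr_bpm[1]) reasons <- c(reasons, "RATE_LOW")
  if (hr > hr_bpm[2]) reasons <- c(reasons, "RATE_HIGH")
  br <- nrow(rw) / dur_min
  if (br <= breath_min_per_min) reasons <- c(reasons, "BREATH_LOW")
  gaps <- diff(c(start_s, bw$beat_time_s, end_s))
  if (length(gaps) == 0 || any(gaps > max_gap_s))
    reasons <- c(reasons, "BEAT_GAP")
  if (nrow(bw) >= 2 && diff(range(bw$sbp)) >= sbp_range_mmHg)
    reasons <- c(reasons, "SBP_RANGE")

  raw <- list(SBP = bw$sbp,
              DBP = bw$dbp[!is.na(bw$dbp)],
              MAP = bw$map[!is.na(bw$map)],
              PI = bw$pi_ms[!is.na(bw$pi_ms)],
              IBI = rw$ibi_ms[!is.na(rw$ibi_ms)])
  cleaned <- purrr::map(raw, function(v) {
    if (length(v) < 2) return(list(values = v, loss_fraction = 1))
    remove_outliers(v, max_change = max_change)
  })
  loss <- purrr::map_dbl(cleaned, "loss_fraction")
  if (any(loss > max_loss)) reasons <- c(reasons, "LOSS_EXCEEDED")

  tibble::tibble(
    start_s = start_s, end_s = end_s,
    qc_pass = length(reasons) == 0,
    reject_reasons = list(reasons),
    series = list(purrr::map(cleaned, "values")),
    loss = list(loss)
  )
}

#' Qualify every window of a recording
#'
#' Maps [qc_window()] over [iter_windows()] for the full record.
#'
#' @param beats,breaths detected event series for the record.
#' @param duration_s record duration in seconds.
#' @param ... passed to [qc_window()].
#' @inheritParams iter_windows
#' @return tibble with one row per window.
#' @export
qc_windows <- function(beats, breaths, duration_s, window_s = 600,
                       step_s = 30, ...) {
  win <- iter_windows(duration_s, window_s = window_s, step_s = step_s)
  purrr::map2_dfr(win$start_s, win$end_s,
                  function(s, e) qc_window(s, e, beats, breaths, ...))
}

#' Per-window QC report
#'
#' Flat summary of a [qc_windows()] result, one row per window, with
#' reasons collapsed to a `;`-separated string and per-series loss
#' fractions as columns — the shape written to the QC report CSV.
#'
#' @param qc tibble from [qc_windows()].
#' @return tibble.
#' @export
qc_report <- function(qc) {
  loss <- purrr::map_dfr(qc$loss, function(l)
    tibble::as_tibble(as.list(stats::setNames(l, paste0("loss_", names(l))))))
  tibble::tibble(
    window_start_s = qc$start_s,
    pass = qc$qc_pass,
    reasons = purrr::map_chr(qc$reject_reasons, paste, collapse = ";")
  ) |> dplyr::bind_cols(loss)
}
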