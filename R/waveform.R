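#' Construct a waveform tibble
#'
#' A waveform is a tibble with columns `time_s` and `value` plus
#' attributes for the sampling rate, channel and units. All signal
#' functions in the package take and return this shape, so waveforms
#' chain through dplyr verbs like any other tibble (attribute-dropping
#' verbs aside; use the accessors below).
#'
#' @param value numeric samples; `NA` marks missing samples.
#' @param fs sampling rate in Hz (> 0).
#' @param channel `"ABP"` (arterial blood pressure) or `"FLOW"`
#'   (ventilator airflow).
#' @param units physical units; defaults to mmHg for ABP and arbitrary
#'   flow units otherwise.
#' @param t0 time of the first sample in seconds.
#' @return a `wave_tbl` tibble.
#' @export
#' @examples
#' w <- waveform(sin(2 * pi * seq(0, 1, by = 1 / 125)), fs = 125,
#'               channel = "FLOW")
waveform <- function(value, fs, channel = c("ABP", "FLOW"),
                     units = NULL, t0 = 0) {
  channel <- match.arg(channel)
  check_number(fs, "fs", lower = 0, strict_lower = TRUE)
  if (length(value) < 2) stop("waveform needs >= 2 samples", call. = FALSE)
  if (is.null(units)) units <- if (channel == "ABP") "mmHg" else "a.u."
  out <- tibble::tibble(
    time_s = t0 + (seq_along(value) - 1) / fs,
    value = as.numeric(value)
  )
  attr(out, "fs") <- fs
  attr(out, "channel") <- channel
  attr(out, "units") <- units
  attr(out, "t0") <- t0
  class(out) <- c("wave_tbl", class(out))
  out
}

#' @rdname waveform
#' @param x a `wave_tbl`.
#' @export
wave_fs <- function(x) attr(x, "fs")

#' @rdname waveform
#' @export
wave_channel <- function(x) attr(x, "channel")

#' @rdname waveform
#' @export
wave_units <- function(x) attr(x, "units")

#' @rdname waveform
#' @export
wave_duration <- function(x) nrow(x) / wave_fs(x)

#' @export
print.wave_tbl <- function(x, ...) {
  cat(sprintf("<waveform> channel %s, %g Hz, %.1f s, units %s\n",
              wave_channel(x), wave_fs(x), wave_duration(x), wave_units(x)))
  NextMethod()
}

#' Read a waveform from CSV or EDF
#'
#' CSV files use the two-column dialect `time_s,value` (UTF-8, '.'
#' decimal) holding one channel; EDF files may hold several signals, and
#' `channel` selects by label. The sampling rate is inferred from the
#' time column (CSV) or the header (EDF); a non-uniform or non-monotonic
#' CSV time column is a format error. Missing samples stay `NA` — they
#' are never zero-filled.
#'
#' @param path file path; format chosen by extension (`.csv` / `.edf`).
#' @param channel `"ABP"` or `"FLOW"`.
#' @return a [waveform()] tibble.
#' @export
read_waveform <- function(path, channel = c("ABP", "FLOW")) {
  channel <- match.arg(channel)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "edf") return(read_edf(path, channel))
  df <- readr::read_csv(path, col_types = readr::cols(
    time_s = readr::col_double(), value = readr::col_double()
  ), progress = FALSE)
  if (!all(c("time_s", "value") %in% names(df)))
    stop("CSV must have header `time_s,value`", call. = FALSE)
  dt <- diff(df$time_s)
  if (any(dt <= 0)) stop("non-monotonic time column", call. = FALSE)
  if (diff(range(dt)) > 1e-6 * stats::median(dt) + 1e-9)
    stop("time column is not uniformly sampled", call. = FALSE)
  fs <- round(1 / stats::median(dt), 6)
  waveform(df$value, fs = fs, channel = channel, t0 = df$time_s[1])
}

#' Write a waveform to two-column CSV
#'
#' @param wave a [waveform()] tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(wave, path) {
  readr::write_csv(wave[, c("time_s", "value")], path, progress = FALSE)
  invisible(path)
}

#' Downsample a waveform by an integer factor
#'
#' Zero-phase anti-alias low-pass (4th-order Butterworth at
#' 0.4 x target rate, applied forwards and backwards) followed by
#' decimation. The zero-phase filter keeps systolic peak positions
#' aligned to within one output sample, which protects pulse-interval
#' timing. Recordings sampled at 1 kHz are reduced to 125 Hz before any
#' analysis.
#'
#' @param wave a [waveform()] tibble.
#' @param target_fs target rate in Hz; `wave`'s rate must be an integer
#'   multiple of it.
#' @return a [waveform()] tibble at `target_fs` with
#'   `floor(n * target_fs / fs)` samples.
#' @export
downsample <- function(wave, target_fs = 125) {
  fs <- wave_fs(wave)
  check_number(target_fs, "target_fs", lower = 0, strict_lower = TRUE)
  if (fs == target_fs) return(wave)
  r <- fs / target_fs
  if (abs(r - round(r)) > 1e-9)
    stop("sampling rate must be an integer multiple of `target_fs`",
         call. = FALSE)
  r <- as.integer(round(r))
  bf <- signal::butter(4, 0.8 * target_fs / fs)
  filtered <- signal::filtfilt(bf, wave$value)
  keep <- seq(1L, r * (nrow(wave) %/% r), by = r)
  waveform(filtered[keep], fs = target_fs, channel = wave_channel(wave),
           units = wave_units(wave), t0 = wave$time_s[1])
}

#' Remove the non-linear baseline trend from an arterial pressure signal
#'
#' Estimates slow baseline wander and subtracts its mean-centred form,
#' so the signal's overall mean is preserved while drift is removed.
#' The trend is obtained by (1) anti-aliased downsampling to
#' `intermediate_fs`, (2) a running median over `median_window_ms`
#' (reflect-padded so the record edges are not dragged down), (3)
#' restriction of the median output to the drift band: decimation to
#' 0.5 Hz followed by a boundary-corrected zero-phase low-pass at
#' `trend_cutoff_hz` (fourth-order Butterworth with steady-state
#' initial conditions for the interior, one-sided local-quadratic fits
#' near the record edges where IIR transients would bias the trend),
#' and (4) linear interpolation back onto the original sample grid
#' (linear suffices because the trend is slow by construction).
#'
#' Step (3) is what makes detrending safe for fractal analysis: beat-
#' to-beat fluctuations at 4-50 beat scales (roughly 1.5-20 s, i.e.
#' above ~0.05 Hz) must survive detrending untouched or the scaling
#' exponents would be destroyed, while baseline wander with periods of
#' a minute or more must be removed. The default cutoff of 0.013 Hz
#' separates the two: a 120 s drift is removed to well under 1 mmHg
#' residual while the scaling exponents of trend-free beat series move
#' by under 0.05. The median filter upstream keeps the estimate robust
#' to spikes.
#'
#' Detrending applies to the pressure channel only; ventilator flow is
#' analysed through interval timing, which drift does not disturb.
#'
#' @param wave an ABP [waveform()] at 125 Hz (other rates accepted if
#'   divisible by `intermediate_fs`).
#' @param intermediate_fs rate (Hz) at which the median filter runs.
#' @param median_window_ms median filter window width, a duration, so
#'   the behaviour does not change with `intermediate_fs`.
#' @param trend_cutoff_hz upper frequency bound of the removed trend.
#' @return list with `detrended` (a [waveform()]) and `trend` (a tibble
#'   of `time_s`, `trend` aligned to the input, mean-centred to zero).
#' @export
#' @examples
#' beats <- gen_beat_series(200, mean = 29, sd = 2, alpha_target = 0.9,
#'                          seed = 1)
#' abp <- gen_abp_waveform(rep(400, 200), beats$value + 13, beats$value)
#' out <- remove_nonlinear_trend(abp)
#' max(abs(out$trend$trend)) # drift-free: trend is near zero
remove_nonlinear_trend <- function(wave, intermediate_fs = 5,
                                   median_window_ms = 1000,
                                   trend_cutoff_hz = 0.013) {
  if (wave_channel(wave) != "ABP")
    stop("detrending applies to the ABP channel only", call. = FALSE)
  fs <- wave_fs(wave)
  if (wave_duration(wave) < 2 * median_window_ms / 1000)
    stop("record shorter than twice the median filter window",
         call. = FALSE)
  x <- wave$value
  low <- downsample(wave, target_fs = intermediate_fs)
  xs <- low$value
  k <- round(median_window_ms / 1000 * intermediate_fs)
  if (k %% 2 == 0) k <- k + 1L
  # mirror-pad the pulsatile 5 Hz signal for the median stage (its
  # edge effects span only the 1 s window)
  nx <- length(xs)
  pad <- min(max((k - 1L) %/% 2L, ceiling(10 * intermediate_fs)), nx - 1L)
  padded <- c(rev(xs[2:(pad + 1)]), xs, rev(xs[(nx - pad):(nx - 1)]))
  med <- stats::runmed(padded, k, endrule = "median")
  # decimate the median output to 0.5 Hz, then restrict it to the
  # drift band with the boundary-corrected smoother
  r2 <- max(1L, as.integer(round(intermediate_fs / 0.5)))
  aa <- signal::filtfilt(signal::butter(4, 0.8 / r2), med)
  aa <- aa[(pad + 1):(pad + nx)]
  dec_idx <- seq(1L, nx, by = r2)
  sm2 <- .drift_band(aa[dec_idx], fs = intermediate_fs / r2,
                     cutoff_hz = trend_cutoff_hz)
  sm <- stats::approx(x = dec_idx, y = sm2, xout = seq_len(nx),
                      rule = 2)$y
  r <- fs / intermediate_fs
  trend <- stats::approx(x = (seq_along(xs) - 1) * r + 1, y = sm,
                         xout = seq_along(x), rule = 2)$y
  trend0 <- trend - mean(trend)
  out <- waveform(x - trend0, fs = fs, channel = "ABP",
                  units = wave_units(wave), t0 = wave$time_s[1])
  list(
    detrended = out,
    trend = tibble::tibble(time_s = wave$time_s, trend = trend0)
  )
}

#' Write / read a per-window feature table
#'
#' CSV with columns `subject_id`, `window_start_s`, `qc_pass`, then one
#' column per feature named `<SERIES>_<mu|alpha1|alpha2>`.
#'
#' @param rows a data frame of feature rows sharing one schema.
#' @param path output path.
#' @return `path` invisibly; `read_feature_table()` returns a tibble.
#' @export
write_feature_table <- function(rows, path) {
  lead <- intersect(c("subject_id", "window_start_s", "qc_pass"),
                    names(rows))
  rows <- dplyr::relocate(tibble::as_tibble(rows),
                          dplyr::all_of(lead))
  readr::write_csv(rows, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
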