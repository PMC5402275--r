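#' Detect heartbeats in an arterial pressure waveform
#'
#' Adaptive-threshold systolic peak search on the band-passed
#' (0.5-20 Hz) pressure signal with a 240 ms refractory period
#' (250 bpm ceiling) and a minimum pulse prominence, then refinement of
#' each peak position on the raw waveform. Per-beat values follow the
#' half-open beat convention `[peak_k, peak_{k+1})`:
#' \itemize{
#'   \item SBP: waveform value at the systolic peak;
#'   \item DBP: minimum between consecutive peaks;
#'   \item MAP: time-average of the waveform over the beat;
#'   \item PI: peak-to-peak interval in ms, assigned to the leading
#'     beat.
#' }
#' The last row has `NA` DBP/MAP/PI since its beat interval is
#' incomplete.
#'
#' @param wave an ABP [waveform()] at 125 Hz.
#' @param refractory_ms minimum peak separation.
#' @param min_prominence_mmHg minimum pulse amplitude for a peak to
#'   count as a beat.
#' @param map_method `"time_average"` (mean of samples over the beat)
#'   or `"formula"` (DBP + pulse pressure / 3).
#' @return a `beat_tbl` tibble: `beat_time_s`, `sbp`, `dbp`, `map`,
#'   `pi_ms`. Fewer than 2 detectable peaks yields an empty tibble
#'   flagged with attribute `empty_reason` rather than an error.
#' @export
detect_beats <- function(wave, refractory_ms = 240,
                         min_prominence_mmHg = 5,
                         map_method = c("time_average", "formula")) {
  map_method <- match.arg(map_method)
  stopifnot(wave_channel(wave) == "ABP")
  fs <- wave_fs(wave)
  x <- wave$value
  x[is.na(x)] <- stats::median(x, na.rm = TRUE)
  bp <- signal::filtfilt(signal::butter(2, c(0.5, 20) / (fs / 2)), x)
  # local maxima above an adaptive threshold
  cand <- which(diff(sign(diff(bp))) == -2) + 1L
  thr <- 0.25 * stats::quantile(bp[bp > 0], 0.95, names = FALSE)
  if (!is.finite(thr)) thr <- 0
  cand <- cand[bp[cand] > thr]
  empty <- function(reason) {
    out <- tibble::tibble(beat_time_s = numeric(), sbp = numeric(),
                          dbp = numeric(), map = numeric(),
                          pi_ms = numeric())
    attr(out, "empty_reason") <- reason
    class(out) <- c("beat_tbl", class(out))
    out
  }
  if (length(cand) < 2) return(empty("fewer than 2 candidate peaks"))
  # refractory: keep the larger of peaks closer than refractory_ms
  refr <- refractory_ms / 1000 * fs
  keep <- cand[1]
  for (p in cand[-1]) {
    if (p - keep[length(keep)] >= refr) keep <- c(keep, p)
    else if (bp[p] > bp[keep[length(keep)]]) keep[length(keep)] <- p
  }
  # refine on the raw waveform within +/- 80 ms
  half <- round(0.080 * fs)
  n <- length(x)
  peaks <- vapply(keep, function(p) {
    lo <- max(1L, as.integer(p - half)); hi <- min(n, as.integer(p + half))
    lo + which.max(x[lo:hi]) - 1L
  }, integer(1))
  peaks <- unique(peaks)
  # prominence on the raw signal: pulse amplitude within each beat
  if (length(peaks) >= 2) {
    amp_ok <- logical(length(peaks))
    for (i in seq_along(peaks)) {
      lo <- if (i == 1) max(1L, peaks[1] - round(fs)) else peaks[i - 1]
      hi <- if (i == length(peaks)) min(n, peaks[i] + round(fs))
            else peaks[i + 1]
      amp_ok[i] <- x[peaks[i]] - min(x[lo:hi]) >= min_prominence_mmHg
    }
    peaks <- peaks[amp_ok]
  }
  if (length(peaks) < 2) return(empty("fewer than 2 detected beats"))
  k <- length(peaks)
  dbp <- map <- rep(NA_real_, k)
  for (i in seq_len(k - 1)) {
    seg <- x[peaks[i]:(peaks[i + 1] - 1L)]
    dbp[i] <- min(seg)
    map[i] <- if (map_method == "time_average") mean(seg) else NA_real_
  }
  sbp <- x[peaks]
  if (map_method == "formula")
    map <- dbp + (sbp - dbp) / 3
  out <- tibble::tibble(
    beat_time_s = wave$time_s[peaks],
    sbp = sbp, dbp = dbp, map = map,
    pi_ms = c(diff(wave$time_s[peaks]) * 1000, NA_real_)
  )
  class(out) <- c("beat_tbl", class(out))
  out
}

#' Detect breaths in a ventilator airflow waveform
#'
#' Breath onsets are positive-going zero crossings of the 2 Hz
#' low-passed flow, with a 300 ms refractory period. Ventilated infants'
#' flow crosses zero every cycle, so this is simple and reproducible.
#'
#' @param wave a FLOW [waveform()] at 125 Hz.
#' @param refractory_ms minimum onset separation.
#' @return a `breath_tbl` tibble: `breath_time_s`, `ibi_ms` (`NA` in
#'   the last row). All-zero flow yields an empty flagged tibble.
#' @export
detect_breaths <- function(wave, refractory_ms = 300) {
  stopifnot(wave_channel(wave) == "FLOW")
  fs <- wave_fs(wave)
  x <- wave$value
  x[is.na(x)] <- 0
  empty <- function(reason) {
    out <- tibble::tibble(breath_time_s = numeric(), ibi_ms = numeric())
    attr(out, "empty_reason") <- reason
    class(out) <- c("breath_tbl", class(out))
    out
  }
  if (all(abs(x) < 1e-12)) return(empty("all-zero flow"))
  sm <- signal::filtfilt(signal::butter(2, 2 / (fs / 2)), x)
  up <- which(sm[-length(sm)] <= 0 & sm[-1] > 0)
  if (length(up) < 2) return(empty("fewer than 2 breath onsets"))
  refr <- refractory_ms / 1000 * fs
  keep <- up[1]
  for (p in up[-1]) if (p - keep[length(keep)] >= refr) keep <- c(keep, p)
  # linear interpolation of the crossing instant between samples
  frac <- -sm[keep] / (sm[keep + 1] - sm[keep])
  times <- wave$time_s[keep] + frac / fs
  out <- tibble::tibble(
    breath_time_s = times,
    ibi_ms = c(diff(times) * 1000, NA_real_)
  )
  class(out) <- c("breath_tbl", class(out))
  out
}
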