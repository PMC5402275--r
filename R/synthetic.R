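# Synthetic neonatal recordings: beat/breath series with prescribed DFA
# structure, pulsatile pressure and airflow waveforms, artifact
# injection, and whole cohorts. These emulate the statistical structure
# the analysis assumes so every downstream stage is testable without
# patient data.

#' Generate a beat-to-beat (or breath-to-breath) series with a target
#' DFA exponent
#'
#' For `alpha_target` < 1 the series is exact fractional Gaussian noise
#' with Hurst parameter `alpha_target` (whose DFA exponent equals its
#' Hurst parameter). For 1 <= `alpha_target` < 1.5 the series is the
#' cumulative sum of fGn with Hurst `alpha_target - 1` (a fractional
#' Brownian path, DFA exponent H + 1), re-scaled to the requested
#' sample mean and SD.
#'
#' @param n_beats series length (>= 60).
#' @param mean,sd target sample mean and standard deviation (`sd` > 0).
#' @param alpha_target desired DFA exponent, in (0, 1.5).
#' @param seed optional integer seed.
#' @return tibble with column `value`.
#' @export
#' @examples
#' x <- gen_beat_series(1500, mean = 29, sd = 4.6, alpha_target = 0.93,
#'                      seed = 7)
gen_beat_series <- function(n_beats, mean, sd, alpha_target, seed = NULL) {
  check_number(n_beats, "n_beats", lower = 60)
  check_number(sd, "sd", lower = 0, strict_lower = TRUE)
  check_number(alpha_target, "alpha_target", lower = 0, upper = 1.5,
               strict_lower = TRUE, strict_upper = TRUE)
  n <- as.integer(n_beats)
  x <- local_seed(seed, {
    if (alpha_target < 1) {
      gen_fgn(n, hurst = alpha_target)
    } else {
      h <- max(alpha_target - 1, 0.02)     # fBm-class: alpha = H + 1
      cumsum(gen_fgn(n, hurst = h))
    }
  })
  x <- (x - base::mean(x)) / stats::sd(x) * sd + mean
  tibble::tibble(value = x)
}

#' Synthesize a pulsatile arterial pressure waveform from per-beat values
#'
#' Beat `k` spans `pi_ms[k]` milliseconds and follows a piecewise
#' raised-cosine pulse: a systolic upstroke from diastolic to systolic
#' pressure over the first third of the beat, then a slower
#' raised-cosine decay back to the diastolic value. The asymmetry makes
#' systolic peaks and diastolic troughs unambiguous for any pulse
#' interval in range, so a peak detector recovers the generating
#' series; the per-beat extrema equal the inputs up to sampling error.
#'
#' @param pi_ms per-beat pulse intervals in ms.
#' @param sbp,dbp per-beat systolic and diastolic pressures in mmHg;
#'   same length as `pi_ms`, `sbp > dbp > 0` everywhere.
#' @param fs sampling rate, 125 or 1000 Hz.
#' @param systole_fraction fraction of the beat taken by the upstroke.
#' @return an ABP [waveform()].
#' @export
gen_abp_waveform <- function(pi_ms, sbp, dbp, fs = 125,
                             systole_fraction = 1 / 3) {
  if (!fs %in% c(125, 1000)) stop("fs must be 125 or 1000 Hz", call. = FALSE)
  n <- length(pi_ms)
  if (n < 2 || length(sbp) != n || length(dbp) != n)
    stop("pi_ms, sbp, dbp must have equal length >= 2", call. = FALSE)
  if (any(dbp <= 0) || any(sbp <= dbp))
    stop("need SBP > DBP > 0 for every beat", call. = FALSE)
  onsets_s <- c(0, cumsum(pi_ms)) / 1000   # beat k covers [onset_k, onset_k+1)
  total <- onsets_s[n + 1]
  t <- seq(0, total - 1 / fs, by = 1 / fs)
  beat <- findInterval(t, onsets_s, rightmost.closed = FALSE)
  beat[beat > n] <- n
  phase <- (t - onsets_s[beat]) / (pi_ms[beat] / 1000)
  phase <- pmin(phase, 1 - 1e-12)
  # decay lands on the NEXT beat's diastolic value so the waveform is
  # continuous at beat boundaries and the inter-peak trough equals the
  # following beat's DBP
  dbp_next <- c(dbp[-1], dbp[n])
  rise <- phase < systole_fraction
  v <- numeric(length(t))
  v[rise] <- dbp[beat[rise]] +
    (sbp[beat[rise]] - dbp[beat[rise]]) *
      (1 - cos(pi * phase[rise] / systole_fraction)) / 2
  v[!rise] <- dbp_next[beat[!rise]] +
    (sbp[beat[!rise]] - dbp_next[beat[!rise]]) *
      (1 + cos(pi * (phase[!rise] - systole_fraction) /
                 (1 - systole_fraction))) / 2
  waveform(v, fs = fs, channel = "ABP")
}

#' Synthesize a ventilator airflow waveform from interbreath intervals
#'
#' One full inspiration/expiration sinusoid per interval; flow is
#' zero-mean and crosses zero upward exactly at each breath onset, so a
#' zero-crossing breath detector recovers the interval series to within
#' one sample.
#'
#' @param ibi_ms interbreath intervals in ms, each within 500-3000 ms.
#' @param fs sampling rate in Hz.
#' @param amplitude peak flow (arbitrary units).
#' @return a FLOW [waveform()].
#' @export
gen_airflow_waveform <- function(ibi_ms, fs = 125, amplitude = 1) {
  if (any(ibi_ms < 500 | ibi_ms > 3000))
    stop("all interbreath intervals must lie in [500, 3000] ms",
         call. = FALSE)
  onsets_s <- c(0, cumsum(ibi_ms)) / 1000
  n <- length(ibi_ms)
  total <- onsets_s[n + 1]
  t <- seq(0, total - 1 / fs, by = 1 / fs)
  br <- findInterval(t, onsets_s)
  br[br > n] <- n
  phase <- (t - onsets_s[br]) / (ibi_ms[br] / 1000)
  waveform(amplitude * sin(2 * pi * phase), fs = fs, channel = "FLOW")
}

#' Inject drift, spikes, and flat gaps into a waveform
#'
#' Produces a corrupted copy together with a ground-truth event log so
#' quality-control rules can be tested against known artifact times.
#' Drift is the sum of a slow sinusoid (period >= 60 s) and a smoothed
#' random walk, mimicking non-linear baseline wander; spikes are short
#' (40 ms) triangular pressure excursions; gaps replace the signal with
#' a flat value (no detectable beats).
#'
#' @param wave a [waveform()].
#' @param drift_amplitude peak drift in signal units (0 disables).
#' @param drift_period_s sinusoid period in seconds (>= 60).
#' @param spike_rate expected spikes per minute (Poisson; 0 disables).
#' @param spike_height spike magnitude in signal units.
#' @param gap_spec data frame with columns `start_s`, `duration_s`, or
#'   `NULL` for none.
#' @param seed optional integer seed.
#' @return list with `wave` (modified copy) and `events` (tibble of
#'   `time_s`, `type`, `detail`).
#' @export
inject_artifacts <- function(wave, drift_amplitude = 0,
                             drift_period_s = 120, spike_rate = 0,
                             spike_height = 40, gap_spec = NULL,
                             seed = NULL) {
  check_number(drift_amplitude, "drift_amplitude", lower = 0)
  check_number(spike_rate, "spike_rate", lower = 0)
  if (drift_period_s < 60) stop("drift period must be >= 60 s", call. = FALSE)
  fs <- wave_fs(wave)
  v <- wave$value
  n <- length(v)
  t <- wave$time_s
  events <- list()
  local_seed(seed, {
    if (drift_amplitude > 0) {
      phase <- stats::runif(1, 0, 2 * pi)
      sine <- sin(2 * pi * t / drift_period_s + phase)
      # non-linear wander: random low-frequency sinusoid mixture
      # (periods 80-300 s), a smooth band-limited random walk
      per <- stats::runif(3, 80, 300)
      ph <- stats::runif(3, 0, 2 * pi)
      walk <- rowSums(vapply(1:3, function(i)
        sin(2 * pi * t / per[i] + ph[i]), numeric(n)))
      walk <- walk - mean(walk)
      if (max(abs(walk)) > 0) walk <- walk / max(abs(walk))
      drift <- drift_amplitude * (0.7 * sine + 0.3 * walk)
      v <- v + drift
      events[[length(events) + 1]] <- tibble::tibble(
        time_s = t[1], type = "drift",
        detail = sprintf("amplitude=%g period=%g", drift_amplitude,
                         drift_period_s))
    }
    if (spike_rate > 0) {
      n_spikes <- stats::rpois(1, spike_rate * (n / fs) / 60)
      if (n_spikes > 0) {
        at <- sort(stats::runif(n_spikes, 0, n / fs))
        half <- max(1L, round(0.020 * fs))   # 20 ms half-width
        for (a in at) {
          i0 <- round(a * fs) + 1L
          idx <- max(1L, i0 - half):min(n, i0 + half)
          tri <- 1 - abs(idx - i0) / half
          sgn <- sample(c(-1, 1), 1)
          v[idx] <- v[idx] + sgn * spike_height * tri
        }
        events[[length(events) + 1]] <- tibble::tibble(
          time_s = at, type = "spike",
          detail = sprintf("height=%g", spike_height))
      }
    }
  })
  if (!is.null(gap_spec) && nrow(gap_spec) > 0) {
    for (g in seq_len(nrow(gap_spec))) {
      i0 <- max(1L, round(gap_spec$start_s[g] * fs) + 1L)
      i1 <- min(n, round((gap_spec$start_s[g] + gap_spec$duration_s[g]) * fs))
      v[i0:i1] <- mean(v, na.rm = TRUE)
      events[[length(events) + 1]] <- tibble::tibble(
        time_s = gap_spec$start_s[g], type = "gap",
        detail = sprintf("duration=%g", gap_spec$duration_s[g]))
    }
  }
  out <- waveform(v, fs = fs, channel = wave_channel(wave),
                  units = wave_units(wave), t0 = t[1])
  ev <- if (length(events)) dplyr::bind_rows(events) else
    tibble::tibble(time_s = numeric(), type = character(),
                   detail = character())
  list(wave = out, events = ev)
}

#' Default per-feature group parameters for cohort simulation
#'
#' Mean and SD per feature and group, matching the detrended summary
#' statistics of the reference neonatal cohort for the blood-pressure
#' features. Per-beat interval features (PI, IBI) have no published
#' group statistics and default to identical distributions in both
#' groups (no discriminative signal).
#'
#' @return tibble with columns `feature`, `case_mean`, `case_sd`,
#'   `control_mean`, `control_sd`.
#' @export
default_feature_params <- function() {
  tibble::tribble(
    ~feature,     ~case_mean, ~case_sd, ~control_mean, ~control_sd,
    "MAP_mu",         32.1,      5.6,       35.5,          4.2,
    "MAP_alpha1",      0.96,     0.17,       0.78,         0.19,
    "MAP_alpha2",      1.10,     0.06,       1.00,         0.18,
    "SBP_mu",         41.9,      9.7,       42.7,          5.4,
    "SBP_alpha1",      0.83,     0.11,       0.69,         0.15,
    "SBP_alpha2",      1.04,     0.08,       0.97,         0.16,
    "DBP_mu",         24.6,      3.5,       29.4,          4.1,
    "DBP_alpha1",      0.85,     0.12,       0.68,         0.20,
    "DBP_alpha2",      1.05,     0.06,       0.93,         0.16,
    "PI_mu",         400,       30,        400,           30,
    "PI_alpha1",       0.90,     0.20,       0.90,         0.20,
    "PI_alpha2",       1.00,     0.15,       1.00,         0.15,
    "IBI_mu",       1000,      100,       1000,          100,
    "IBI_alpha1",      0.60,     0.15,       0.60,         0.15,
    "IBI_alpha2",      0.60,     0.15,       0.60,         0.15
  )
}

#' Simulate a cohort of subjects
#'
#' Two tiers. Feature-level (`waveform_level = FALSE`) draws each
#' subject's per-subject feature vector directly from group-specific
#' normal distributions — fast, for statistical tests of the modelling
#' stage. Waveform-level synthesizes full ABP and airflow recordings
#' per subject whose extracted features carry the requested group
#' distributions: the subject's mean DBP, PI and IBI are drawn from the
#' group normals, beat-to-beat series are generated with the group's
#' DFA exponent targets, and waveforms are built from those series.
#'
#' @param n_cases,n_controls group sizes (>= 1).
#' @param feature_params per-feature, per-group (mean, sd) table as in
#'   [default_feature_params()].
#' @param waveform_level generate full recordings instead of features.
#' @param duration_s recording length per subject (waveform level).
#' @param drift_amplitude baseline drift injected into each ABP
#'   recording, mmHg (waveform level).
#' @param artifact_rate spike events per minute (waveform level).
#' @param within_sd_mmHg beat-to-beat SD of the DBP series around the
#'   subject's own mean (waveform level).
#' @param correlation optional correlation applied between features at
#'   the feature level (`NULL` for independent features; no published
#'   between-feature correlations exist, so there is no data-derived
#'   default).
#' @param seed optional integer seed.
#' @return tibble with `subject_id`, `label` (1 = case), gestational
#'   age and birthweight metadata, and either feature columns
#'   (feature level) or list-columns `abp`, `flow` of waveforms plus
#'   list-column `truth` of generating per-beat series.
#' @export
gen_cohort <- function(n_cases = 7, n_controls = 20,
                       feature_params = default_feature_params(),
                       waveform_level = FALSE, duration_s = 660,
                       drift_amplitude = 0, artifact_rate = 0,
                       within_sd_mmHg = 2, correlation = NULL,
                       seed = NULL) {
  check_number(n_cases, "n_cases", lower = 1)
  check_number(n_controls, "n_controls", lower = 1)
  stopifnot(all(feature_params$case_sd > 0),
            all(feature_params$control_sd > 0))
  labels <- c(rep(1L, n_cases), rep(0L, n_controls))
  n <- length(labels)
  ids <- sprintf("S%03d", seq_len(n))
  local_seed(seed, {
    meta <- tibble::tibble(
      subject_id = ids, label = labels,
      gestational_age_wk = round(stats::rnorm(n, 26.9, 1.6), 1),
      birthweight_g = round(stats::rnorm(n, 1050, 290))
    )
    if (!waveform_level) {
      p <- feature_params
      draw <- function(lab) {
        mu <- if (lab == 1) p$case_mean else p$control_mean
        sdv <- if (lab == 1) p$case_sd else p$control_sd
        z <- stats::rnorm(nrow(p))
        if (!is.null(correlation)) {
          # one shared latent factor induces pairwise correlation
          shared <- stats::rnorm(1)
          z <- sqrt(correlation) * shared + sqrt(1 - correlation) * z
        }
        stats::setNames(mu + sdv * z, p$feature)
      }
      feats <- purrr::map(labels, draw)
      return(dplyr::bind_cols(meta, dplyr::bind_rows(feats)))
    }
    param <- function(feat, lab) {
      row <- feature_params[feature_params$feature == feat, ]
      if (lab == 1) c(row$case_mean, row$case_sd)
      else c(row$control_mean, row$control_sd)
    }
    sim_one <- function(lab) {
      dbp_p <- param("DBP_mu", lab); dbp_a2 <- param("DBP_alpha2", lab)
      pi_p <- param("PI_mu", lab); pi_a2 <- param("PI_alpha2", lab)
      ibi_p <- param("IBI_mu", lab); ibi_a2 <- param("IBI_alpha2", lab)
      dbp_mu <- stats::rnorm(1, dbp_p[1], dbp_p[2])
      pi_mu <- max(300, stats::rnorm(1, pi_p[1], pi_p[2]))
      ibi_mu <- min(2500, max(600, stats::rnorm(1, ibi_p[1], ibi_p[2])))
      n_beats <- ceiling(duration_s * 1000 / pi_mu) + 5
      a_dbp <- min(1.45, max(0.1, stats::rnorm(1, dbp_a2[1], dbp_a2[2])))
      a_pi <- min(1.45, max(0.1, stats::rnorm(1, pi_a2[1], pi_a2[2])))
      dbp <- gen_beat_series(n_beats, dbp_mu, within_sd_mmHg, a_dbp)$value
      dbp <- pmax(dbp, 5)
      pp <- pmax(8, 16 + gen_fgn(n_beats, hurst = 0.7, sd = 1.5))
      sbp <- dbp + pp
      piv <- gen_beat_series(n_beats, pi_mu, pi_mu * 0.03, a_pi)$value
      piv <- pmin(pmax(piv, 250), 1400)
      n_br <- ceiling(duration_s * 1000 / ibi_mu) + 3
      a_ibi <- min(1.45, max(0.1, stats::rnorm(1, ibi_a2[1], ibi_a2[2])))
      ibi <- gen_beat_series(n_br, ibi_mu, ibi_mu * 0.05, a_ibi)$value
      ibi <- pmin(pmax(ibi, 520), 2950)
      abp <- gen_abp_waveform(piv, sbp, dbp, fs = 125)
      flow <- gen_airflow_waveform(ibi, fs = 125)
      if (drift_amplitude > 0 || artifact_rate > 0) {
        abp <- inject_artifacts(abp, drift_amplitude = drift_amplitude,
                                spike_rate = artifact_rate)$wave
      }
      list(abp = abp, flow = flow,
           truth = tibble::tibble(series = c("DBP", "PI", "IBI"),
                                  target_mean = c(dbp_mu, pi_mu, ibi_mu),
                                  target_alpha2 = c(a_dbp, a_pi, a_ibi)))
    }
    recs <- purrr::map(labels, sim_one)
    dplyr::mutate(meta,
                  abp = purrr::map(recs, "abp"),
                  flow = purrr::map(recs, "flow"),
                  truth = purrr::map(recs, "truth"))
  })
}
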