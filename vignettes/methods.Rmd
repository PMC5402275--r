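---
title: "Fractal blood-pressure variability and IVH risk: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fractal blood-pressure variability and IVH risk: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(ivhsignals)
```

## The problem

Intraventricular haemorrhage (IVH) in very preterm infants typically
declares itself within the first days of life, and the physiological
groundwork — unstable cerebral perfusion in a pressure-passive
circulation — is laid in the first hours. Continuous arterial blood
pressure (ABP) and ventilator airflow are routinely monitored in this
population, so a risk score computable from those signals alone could
flag high-risk infants before the bleed is visible on cranial
ultrasound.

`ivhsignals` implements such an analysis end to end: the pressure
signal is detrended, beats and breaths are detected, five event series
are derived (beat-to-beat MAP, SBP, DBP, pulse interval PI, and
interbreath interval IBI), a running 10-minute window with strict
quality control yields per-window features — the series mean $\mu$ and
two detrended-fluctuation-analysis scaling exponents $\alpha_1,
\alpha_2$ — windows are averaged per infant, and logistic models over
one or two features are evaluated by ROC/AUC with DeLong variance,
positive likelihood ratios at fixed specificity, and leave-one-out
cross-validation (LOOCV).

The cohort this analysis was designed around (27 low-birth-weight
infants, roughly a quarter of whom developed IVH, recorded for about
156 minutes each at 1 kHz) was never publicly deposited. The package
therefore ships a first-class synthetic-data module that generates
waveform-level cohorts with prescribed group statistics, so every
pipeline stage is testable, and closed-form oracles connect published
group summary statistics to the AUCs a univariate score with those
distributions would achieve.

## Detrended fluctuation analysis

For a series $x_1,\dots,x_N$, DFA integrates the mean-centred series
into a profile $y(k)=\sum_{i\le k}(x_i-\bar x)$, partitions the
profile into non-overlapping boxes of $n$ points, removes the
least-squares line within each box, and computes the RMS residual
$F(n)$. For scale-free series $F(n)\propto n^\alpha$; $\alpha$ is the
slope of $\log_{10}F$ on $\log_{10}n$. White noise gives
$\alpha=0.5$, $1/f$-like series 1.0, integrated noise 1.5, and
fractional Gaussian noise (fGn) with Hurst parameter $H$ gives
$\alpha=H$ — which is why exact fGn (generated here by circulant
embedding, carrying the exact target autocovariance) is the package's
validation fixture.

```{r dfa-example}
x <- gen_fgn(2000, hurst = 0.7, seed = 1)
fit <- scaling_exponents(x)
fit
```

Choices worth stating explicitly:

* **Box sizes** are every integer from 4 to 50 events;
  $\alpha_1$ is fitted over 4–15 and $\alpha_2$ over 15–50, with
  $n=15$ in both ranges. An integer grid removes a free parameter on
  such short ranges.
* **Box coverage** is non-overlapping from the start of the profile
  with the trailing remainder discarded; a reversed-pass average is
  available (`reverse_pass = TRUE`) and shifts $\alpha$ by well under
  0.05 on test series.
* **Integration** is performed by default (classic DFA); disabling it
  (`integrate = FALSE`) analyses a series that is already a profile.
* The OLS fit is unweighted on $(\log_{10}n, \log_{10}F)$.
* A constant input makes $F(n)=0$; the result is flagged degenerate
  and excluded upstream rather than returning an arbitrary number.

## Baseline detrending of the pressure signal

Neonatal ABP recordings wander: catheter drift and slow physiological
trends move the baseline by many mmHg over minutes. That wander biases
the linear features (the per-beat means) and leaks into the scaling
exponents. The package removes a *mean-centred* non-linear trend from
the ABP signal only — flow is analysed through interval timing, which
drift does not disturb — so the overall signal mean is preserved.

The trend estimate runs in four stages: anti-aliased downsampling to
`intermediate_fs` (default 5 Hz), a 1000 ms running median (the robust
core of the estimator; spikes do not drag the trend), decimation to
0.5 Hz, and a drift-band smoother with cutoff `trend_cutoff_hz`
(default 0.013 Hz) whose output is interpolated back onto the sample
grid and subtracted.

The cutoff is the load-bearing number. The scaling exponents live on
fluctuations at 4–50 beat scales — roughly 1.5–20 s, i.e. above
0.05 Hz — so the removed trend must stay well below that band, while
baseline wander with periods of one to several minutes must be removed
almost entirely. 0.013 Hz sits in the gap: a 120-second, 10 mmHg
sinusoidal drift leaves a residual under 1 mmHg, while the exponents
of trend-free beat series move by less than 0.05 (measured on 30-min
records; see below).

Two numerical points deserve a note:

* **Boundaries.** A fourth-order zero-phase Butterworth at 0.013 Hz
  has transients far longer than any practical signal extension, and
  plain reflect-padding leaves multi-mmHg trend bias in the first and
  last minute of a record. The smoother therefore uses steady-state
  initial conditions on an odd-extended signal for the interior
  (the approach scipy's `filtfilt` takes) and switches — with a cosine
  cross-fade over the outer 40 s — to a one-sided local-quadratic
  (loess) fit at the edges, where extrapolation-based padding breaks
  down.
* **Near-idempotence, not idempotence.** Any smooth linear trend
  filter has a transition band in which $H(1-H)$ is a few percent, so
  a second application of the detrend removes a small remnant of
  near-cutoff power (measured at 3–4 % of the first application's
  change when drift sits at 0.0083 Hz). Exact idempotence would
  require a projection smoother, and projection smoothers (truncated
  cosine bases) leak several mmHg of a non-harmonic drift sinusoid —
  an unacceptable trade.
* **Edge zones and record length.** The exponent-stability property is
  assessed on 30-minute records, representative of the multi-hour
  clinical recordings; on very short records (around 11 min) the edge
  zones are ~12 % of the record and the worst-case $\alpha_2$ shift
  grows to ≈0.06 for nearly-$1/f$ series. For series with
  $\alpha \ge 1$ the "trend-free" notion itself dissolves — a
  fractional Brownian series genuinely contains drift-like wander that
  any detrender must partially absorb.

The 1000 ms median window is kept as a duration, so behaviour does not
change with `intermediate_fs`.

## Beat and breath detection

The beat detector band-passes the ABP to 0.5–20 Hz, finds local maxima
above an adaptive threshold with a 240 ms refractory period (250 bpm
ceiling), refines each peak on the raw waveform, and requires a
minimum pulse prominence of 5 mmHg. Beats follow the half-open
convention $[\mathrm{peak}_k, \mathrm{peak}_{k+1})$: SBP is the peak
value, DBP the minimum between consecutive peaks, MAP the time-average
over the beat (a `DBP + PP/3` formula variant is available), and PI
the peak-to-peak interval in ms assigned to the leading beat. PI is
measured between systolic peaks rather than pulse onsets; this shifts
the phase of the PI series but not its variability structure. Breath
onsets are positive-going zero crossings of the 2 Hz low-passed flow
with a 300 ms refractory period — ventilated infants' flow crosses
zero every cycle.

## Windowing and quality control

Features come from running 10-minute windows shifted in 30-second
steps (`iter_windows()`); a trailing partial window is never emitted.
Each window must satisfy, on the detected series:

| rule | code |
|---|---|
| mean heart rate within 40–250 bpm (inclusive) | `RATE_LOW` / `RATE_HIGH` |
| mean breath rate strictly above 20 /min | `BREATH_LOW` |
| no beat-free gap longer than 15 s, edges included | `BEAT_GAP` |
| beat-to-beat SBP range below 30 mmHg | `SBP_RANGE` |
| ≤ 30 % of points lost to outlier removal, per series | `LOSS_EXCEEDED` |

Outlier removal scans each series left to right and drops a point
whose relative change from the last *retained* point exceeds 150 %;
referencing the retained point stops a single spike from cascading
rejections over its valid successors. Edge gaps count toward the 15 s
rule because a window that begins with 20 s of dropout is as unusable
as one containing it. The breath-rate bound is strict (exactly
20 /min fails) while the heart-rate bounds are inclusive, a literal
reading of the stated ranges. QC failure is data, not an error, and
verdicts are pure functions of the window's series.

## Models and evaluation

Per-subject features are the arithmetic mean of each feature over the
subject's qualifying windows. Group contrasts use the two-sided
Mann–Whitney U test (tie-corrected normal approximation), whose
statistic divided by $n_1 n_2$ *is* the empirical AUC — an identity
the test suite asserts exactly. Logistic models (one or two
predictors, z-scored internally for conditioning; ROC quantities are
rank-invariant to this) are evaluated with:

* the empirical ROC and DeLong structural-components variance, with a
  Wald CI truncated to $[0,1]$ (default 95 %, i.e. $z=1.96$; a 90 %
  span corresponding to 5th–95th percentiles is available via
  `conf_level = 0.90`);
* the paired DeLong test for comparing correlated AUCs;
* the positive likelihood ratio at the operating point with the
  smallest specificity at or above 75 % — for a perfect classifier
  exactly $1/0.25 = 4$;
* pooled LOOCV: each subject's held-out predicted probability is
  compiled into a single ROC.

Perfect or quasi-separation — routine at $n = 27$ with strong
predictors — is detected and the model refitted by Firth's penalized
likelihood, flagged in the output. Candidate predictor pairs are
screened for collinearity by a two-sided Spearman rank correlation at
$p<0.05$ (robust to the skewed exponent distributions; Pearson
available), and no multiple-testing correction is applied, matching
the original per-model reporting.

**A caution on pooled LOOCV.** Pooling held-out probabilities across
folds produces a pessimistically biased ROC in small cohorts: leaving
out a case lowers the training prevalence, so held-out cases get
systematically lower probabilities than held-out controls. Under
permuted labels at $n=27$ (7 vs 20) the mean pooled-LOOCV AUC is far
*below* 0.5 (≈0.26, reproduced identically by an independent plain
`glm` loop), not centred on it. The package implements the pooled
method as specified; its tests assert the true property — no optimism
under the null — and users should read absolute pooled-LOOCV AUCs with
this bias in mind.

The binormal closed form
$\mathrm{AUC} = \Phi\!\left(|\mu_1-\mu_2| / \sqrt{\sigma_1^2+\sigma_2^2}\right)$
links published group means/SDs to the AUC a univariate normal score
would achieve and serves as the oracle for end-to-end recovery tests.

## The synthetic-data generator

The generator is the package's substitute for the undeposited
recordings and defines the conditions under which the pipeline is
validated.

* `gen_fgn()` draws exact fGn by circulant (Davies–Harte) embedding —
  the empirical autocovariance matches theory at all lags — falling
  back to clipped-eigenvalue approximate synthesis (with a warning)
  only if the embedding fails numerically.
* `gen_beat_series()` targets a DFA exponent: fGn with $H=\alpha$ for
  $\alpha<1$, a cumulated-fGn (fractional Brownian) path with
  $H=\alpha-1$ for $\alpha\ge 1$, rescaled to the requested mean/SD.
* `gen_abp_waveform()` builds a pulsatile pressure wave from per-beat
  PI/SBP/DBP with a piecewise raised-cosine pulse whose systolic
  upstroke occupies the first third of the beat; the decay lands on
  the *next* beat's diastolic value so the waveform is continuous and
  the inter-peak trough equals the following beat's DBP. Peak
  detection recovers SBP/DBP to within 0.1 mmHg on clean signals.
* `gen_airflow_waveform()` produces one sinusoidal
  inspiration/expiration cycle per interbreath interval with onsets at
  positive-going zero crossings, recovered to within one sample.
* `inject_artifacts()` adds slow drift (a ≥60 s-period sinusoid plus a
  band-limited random wander with periods of 80–300 s), short
  triangular spikes, and flat gaps, returning a ground-truth event log
  for QC tests.
* `gen_cohort()` has two tiers. Feature-level cohorts draw per-subject
  feature vectors from group normal distributions — fast, for
  statistical tests of the modelling stage. Waveform-level cohorts
  synthesize full recordings: each subject's mean DBP, PI, IBI and
  exponent targets are drawn from the group distributions (defaults in
  `default_feature_params()` follow the published group summary
  statistics for the blood-pressure features; interval features have
  no published group statistics and default to identical distributions
  in both groups), SBP is DBP plus a fluctuating pulse pressure, and
  MAP emerges from the waveform. An optional single-factor
  `correlation` parameter induces between-feature correlation at the
  feature level; no data-derived default exists, so it is off unless
  set.

What the generator does *not* emulate: baroreflex or
ventilation-coupled dynamics, patent-ductus haemodynamics, ventilator
pressure waveforms, or realistic artifact morphology beyond
spikes/gaps/drift. Passing tests therefore demonstrate that the
*pipeline machinery* is correct under controlled statistical
structure, not that the published clinical effect sizes replicate —
the cohort AUCs reported for the original infants cannot be reproduced
without their data.

## Problem sizes used in validation

The test suite validates DFA on fGn of length 4096 over 20 seeds per
Hurst value; oracle equivalence on 50 random length-200 profiles to
1e-10 relative; QC on 11-minute fixtures with injected ground-truth
artifacts; detrending on constant-beat records across 12 drift phases
and on 30-minute trend-free records; DeLong calibration on 1000 null
replicates at $n=27$; and end-to-end parameter recovery on a
waveform-level cohort of 300 cases vs 300 controls with 11-minute
recordings, sized so the Monte-Carlo error of the empirical AUC
(≈0.017) makes the 0.05 agreement band a three-sigma bound.

## Known limitations

* Pooled-LOOCV bias, discussed above.
* The detrend cutoff trades drift removal against exponent fidelity;
  drifts with periods at or below ~60 s are inside the protected band
  and are deliberately not removed.
* The beat detector is built for the clean-to-moderately-noisy
  synthetic waveforms the generator produces and for QC-screened
  clinical signal; it is not a general arrhythmia-robust detector.
* EDF support covers the subset the pipeline needs (16-bit, 1 s
  records, integer rates); EDF+ annotations are not parsed.
* Window steps of 30 s make adjacent windows share 95 % of their data;
  per-subject means over windows are therefore means of highly
  correlated quantities, which is the intended behaviour of the
  original running-window design, not an independence claim.
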