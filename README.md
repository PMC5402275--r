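# ivhsignals

Time-series analysis of neonatal arterial blood pressure and
ventilator airflow for early risk prediction of intraventricular
haemorrhage (IVH) in very preterm infants.

IVH develops in the first days of life, after the circulatory
instability that precedes it has already been visible in routinely
monitored signals. `ivhsignals` turns continuous arterial blood
pressure (ABP) and airflow waveforms into a per-infant risk model:

1. **Pre-processing** — downsampling to 125 Hz and removal of a
   mean-centred non-linear baseline trend from the pressure signal
   (1000 ms running median, restricted to the drift band below
   0.013 Hz so the fractal structure of beat-to-beat variability
   survives).
2. **Event series** — beat detection yields beat-to-beat MAP, SBP,
   DBP and pulse interval (PI); breath detection on the airflow yields
   interbreath intervals (IBI).
3. **Windowed features with QC** — a running 10-min window shifted in
   30-s steps; windows qualify only when heart rate is 40–250 bpm,
   breath rate exceeds 20/min, no beat-free gap exceeds 15 s, the SBP
   range stays below 30 mmHg, and per-series outlier removal (150 %
   successive-change rule) loses no more than 30 % of points. Each
   qualifying window contributes the mean μ and two detrended
   fluctuation analysis (DFA) exponents per series: α₁ over 4–15
   events and α₂ over 15–50, the slopes of log₁₀ F(n) vs log₁₀ n where

   F(n) = sqrt( mean over covered points of (y(k) − y_n(k))² ),

   y the integrated mean-centred series and y_n its per-box linear
   trend. α = 0.5 is uncorrelated, 1.0 is 1/f-like, 1.5 is Brownian.
4. **Models** — per-subject window-mean features feed logistic
   regressions (one or two predictors, Firth fallback under
   separation) evaluated with empirical ROC/AUC, DeLong standard
   errors, CIs and paired comparisons, the positive likelihood ratio
   LR+ = sensitivity/(1 − specificity) at 75 % specificity, and pooled
   leave-one-out cross-validation.

Because the original cohort recordings were never deposited, the
package includes a first-class synthetic-data module: exact fractional
Gaussian noise (circulant embedding), beat/breath series with
prescribed DFA exponents, pulsatile ABP and airflow waveform
synthesis, artifact injection with ground-truth logs, and two-tier
cohort generation whose defaults follow the published group summary
statistics. Every pipeline stage is validated against independent
oracles on these fixtures.

## Worked example

Simulate a waveform-level cohort the size of the reference study
(7 IVH vs 20 non-IVH), run the full pipeline, and fit a univariate and
a bivariate model:

```r
library(ivhsignals)

co <- gen_cohort(n_cases = 7, n_controls = 20, waveform_level = TRUE,
                 duration_s = 900, seed = 42)
run <- run_pipeline(co, predictors = list("DBP_mu",
                                          c("DBP_mu", "PI_alpha2")),
                    loocv = TRUE)
run
#> <ivh_run> 27 subjects, 2 model(s)
#>   DBP_mu                   AUC 0.871 (0.689, 1.000)
#>   DBP_mu+PI_alpha2         AUC 0.879 (0.700, 1.000)

glance(run$models[["DBP_mu"]])[, 1:7]
#>   predictors method       auc    ci_low ci_high  delong_se  lr_plus
#> 1     DBP_mu    mle 0.8714286 0.6886119       1 0.09327552 2.857143
```

The univariate detrended mean-DBP model separates the simulated groups
with AUC 0.87 (DeLong 95 % CI 0.69–1.00) and LR+ 2.86 at 75 %
specificity: at the reported threshold, a positive window-mean DBP
test is ~2.9 times more likely in an infant who will develop IVH.
Small-cohort AUCs move substantially between seeds — which is exactly
why the package reports DeLong intervals and LOOCV alongside apparent
AUCs.

The DFA engine recovers known exponents; fGn with Hurst 0.9 should
give α ≈ 0.9 on both ranges:

```r
scaling_exponents(gen_fgn(4096, hurst = 0.9, seed = 1))
#> <dfa_result>
#>   alpha1 (n 4-15): 0.976  (R^2 0.999)
#>   alpha2 (n 15-50): 0.915  (R^2 0.994)
```

And the binormal closed form links group summary statistics to a
univariate AUC — for detrended DBP group statistics of 24.6 ± 3.5 vs
29.4 ± 4.1 mmHg:

```r
binormal_auc(24.6, 3.5, 29.4, 4.1)
#> [1] 0.813
```

Result objects have `tidy()`/`glance()` methods and
`autoplot()` methods (waveforms, log–log DFA fits, ROC curves), and
`monitor_probability()` produces the per-window probability trace a
bedside display would show.

A thin command-line wrapper (`inst/exec/ivhsignals-cli.R`) exposes
`simulate` (writes CSV/EDF recordings plus a ground-truth JSON
sidecar) and `run` (full pipeline to feature tables, QC report, and
model JSON).

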