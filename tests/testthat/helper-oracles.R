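# Independent oracles, deliberately naive: no code shared with the
# package implementations they check.

# direct-summation DFA fluctuation: loop over boxes, lm per box
brute_force_F <- function(y, n) {
  nb <- length(y) %/% n
  ss <- 0
  for (b in seq_len(nb)) {
    idx <- ((b - 1) * n + 1):(b * n)
    t <- seq_len(n)
    fit <- stats::lm.fit(cbind(1, t), y[idx])
    ss <- ss + sum(fit$residuals^2)
  }
  sqrt(ss / (n * nb))
}

brute_force_alpha <- function(x, rng) {
  y <- cumsum(x - mean(x))
  ns <- rng[1]:rng[2]
  f <- vapply(ns, function(n) brute_force_F(y, n), numeric(1))
  unname(stats::coef(stats::lm(log10(f) ~ log10(ns)))[2])
}

# all-pairs AUC count (O(n^2))
all_pairs_auc <- function(neg, pos) {
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + (p > q) + 0.5 * (p == q)
  s / (length(neg) * length(pos))
}

# a clean stationary synthetic subject: ABP + airflow waveforms
make_clean_subject <- function(duration_s = 660, pi_mean = 400,
                               dbp_mean = 29, dbp_alpha = 0.9,
                               seed = 1) {
  n <- ceiling(duration_s * 1000 / pi_mean) + 5
  dbp <- gen_beat_series(n, dbp_mean, 2, dbp_alpha, seed = seed)$value
  dbp <- pmax(dbp, 5)
  sbp <- dbp + pmax(8, 16 + gen_fgn(n, 0.7, sd = 1.5, seed = seed + 1))
  piv <- gen_beat_series(n, pi_mean, pi_mean * 0.03, 0.9,
                         seed = seed + 2)$value
  piv <- pmin(pmax(piv, 250), 1400)
  nbr <- ceiling(duration_s / 1) + 3
  ibi <- gen_beat_series(nbr, 1000, 50, 0.8, seed = seed + 3)$value
  ibi <- pmin(pmax(ibi, 520), 2950)
  list(abp = gen_abp_waveform(piv, sbp, dbp),
       flow = gen_airflow_waveform(ibi),
       dbp = dbp, sbp = sbp, pi = piv, ibi = ibi)
}
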