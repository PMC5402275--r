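# Low-frequency trend extraction with explicit boundary control.
#
# A zero-phase Butterworth at a very low cutoff has the right passband
# for baseline drift but its transient extends far beyond any practical
# signal extension, so the first and last minute of a record come out
# biased. The drift-band smoother therefore combines two estimators:
# a forward-backward Butterworth initialized at its step-response
# steady state (as scipy's filtfilt does) over an odd-extended signal
# for the interior, and a one-sided local-quadratic (loess) fit near
# the record edges where extrapolation-based padding breaks down, the
# two cross-faded over the outer edge zone.

# steady-state filter state for a unit-step input (scipy lfilter_zi)
.lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  b <- b / a[1]; a <- a / a[1]
  A <- rbind(-a[2:n], cbind(diag(n - 2), rep(0, n - 2)))
  B <- b[2:n] - a[2:n] * b[1]
  solve(diag(n - 1) - t(A), B)
}

# direct-form-II-transposed filter with initial state
.df2t <- function(b, a, x, zi) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  b <- b / a[1]; a <- a / a[1]
  z <- zi
  y <- numeric(length(x))
  nz <- n - 1
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    if (nz > 1)
      for (j in seq_len(nz - 1)) z[j] <- b[j + 1] * xi + z[j + 1] - a[j + 1] * yi
    z[nz] <- b[n] * xi - a[n] * yi
    y[i] <- yi
  }
  y
}

# zero-phase filtering with odd extension and steady-state ICs
.filtfilt_zi <- function(b, a, x, pad) {
  nx <- length(x)
  pad <- min(pad, nx - 1L)
  xt <- c(2 * x[1] - x[(pad + 1):2], x,
          2 * x[nx] - x[(nx - 1):(nx - pad)])
  zi <- .lfilter_zi(b, a)
  y <- .df2t(b, a, xt, zi * xt[1])
  y <- rev(.df2t(b, a, rev(y), zi * y[length(y)]))
  y[(pad + 1):(pad + nx)]
}

# drift-band component of a slow series: Butterworth interior +
# one-sided local-quadratic edges, cosine cross-fade
.drift_band <- function(x, fs, cutoff_hz, edge_s = 40, loess_window_s = 50) {
  nd <- length(x)
  if (nd < 8) return(rep(mean(x), nd))
  wn <- min(0.9, 2 * cutoff_hz / fs)
  bf <- signal::butter(4, wn)
  interior <- .filtfilt_zi(bf$b, bf$a, x, pad = ceiling(240 * fs))
  span <- min(1, max(loess_window_s * fs, 8) / nd)
  edges <- stats::predict(stats::loess(
    x ~ idx, data = data.frame(x = x, idx = seq_len(nd)),
    span = span, degree = 2, surface = "direct"))
  ne <- min(max(2L, round(edge_s * fs)), nd %/% 2)
  w <- numeric(nd)
  ramp <- 0.5 * (1 + cos(pi * (0:(ne - 1)) / ne))
  w[1:ne] <- ramp
  w[nd:(nd - ne + 1)] <- ramp
  w * edges + (1 - w) * interior
}
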