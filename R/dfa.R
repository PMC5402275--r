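#' Integrated profile of a time series
#'
#' Cumulative sum of the mean-centred series, the first step of
#' detrended fluctuation analysis. By construction the profile ends at
#' zero: \eqn{y(N) = \sum_i (x_i - \bar x) = 0}.
#'
#' @param x numeric vector, length >= 4, finite.
#' @return numeric profile of the same length.
#' @export
integrate_profile <- function(x) {
  if (length(x) < 4) stop("series must have length >= 4", call. = FALSE)
  check_finite(x, "x")
  cumsum(x - mean(x))
}

#' Root-mean-square fluctuation at one box size
#'
#' Partitions the profile into `floor(N / n)` non-overlapping boxes of
#' `n` points (any trailing remainder is discarded), removes the
#' least-squares line from each box, and returns the RMS of the
#' residuals over all covered points:
#' \deqn{F(n) = \sqrt{\frac{1}{N'}\sum_{k} \left(y(k) - y_n(k)\right)^2}}
#' with \eqn{y_n} the local linear trend and \eqn{N'} the number of
#' covered points.
#'
#' @param y integrated profile (see [integrate_profile()]).
#' @param n box size; must allow at least two boxes.
#' @param reverse_pass if `TRUE`, also partition from the end of the
#'   series and average the two mean-square fluctuations, so the
#'   remainder at the tail is covered by the backward pass.
#' @return scalar F(n).
#' @export
fluctuation <- function(y, n, reverse_pass = FALSE) {
  len <- length(y)
  n <- as.integer(n)
  if (n < 4 || n > len %/% 2)
    stop("box size must satisfy 4 <= n <= floor(length/2)", call. = FALSE)
  ms <- .box_mean_square(y, n)
  if (reverse_pass) ms <- (ms + .box_mean_square(rev(y), n)) / 2
  sqrt(ms)
}

# mean squared residual about per-box least-squares lines
.box_mean_square <- function(y, n) {
  nb <- length(y) %/% n
  m <- matrix(y[seq_len(n * nb)], nrow = n)
  tc <- seq_len(n) - (n + 1) / 2            # centred time within box
  stt <- sum(tc^2)
  slope <- colSums(tc * m) / stt
  resid <- m - outer(tc, slope) - matrix(colMeans(m), n, nb, byrow = TRUE)
  sum(resid^2) / (n * nb)
}

#' Detrended fluctuation analysis with short- and long-range exponents
#'
#' Computes F(n) for every integer box size in `scales` on the
#' integrated profile of `x`, then estimates two scaling exponents as
#' unweighted OLS slopes of log10 F(n) on log10 n: `alpha1` over boxes
#' of 4-15 events (short-term) and `alpha2` over 15-50 events
#' (long-term), the boundary box belonging to both ranges. For
#' uncorrelated series alpha is 0.5, 1/f-like series give 1.0, and
#' integrated (Brownian) series give 1.5; fractional Gaussian noise with
#' Hurst parameter H has alpha = H.
#'
#' @param x numeric series, length >= 100 so the largest box retains at
#'   least two boxes.
#' @param scales integer box sizes (default all of 4-50).
#' @param range1,range2 inclusive (min, max) box-size ranges for the two
#'   exponents.
#' @param integrate integrate the series before box-fitting (classic
#'   DFA). Disable only to analyse a series that is already a profile.
#' @param reverse_pass passed to [fluctuation()].
#' @return an object of class `dfa_result`: a list with `fluctuations`
#'   (a tibble of `n`, `F`), `alpha1`, `alpha2`, per-range `r_squared`,
#'   and `degenerate` (`TRUE` for constant input, where F(n) = 0 and
#'   the exponents are undefined; such series are excluded upstream).
#'   Has [tidy()][generics::tidy] and [autoplot()][ggplot2::autoplot]
#'   methods.
#' @export
#' @examples
#' x <- gen_fgn(2000, hurst = 0.7, seed = 1)
#' fit <- scaling_exponents(x)
#' c(fit$alpha1, fit$alpha2)
scaling_exponents <- function(x, scales = 4:50,
                              range1 = c(4, 15), range2 = c(15, 50),
                              integrate = TRUE, reverse_pass = FALSE) {
  if (length(x) < 100) stop("series must have length >= 100", call. = FALSE)
  check_finite(x, "x")
  scales <- sort(unique(as.integer(scales)))
  scales <- scales[scales >= 4 & scales <= length(x) %/% 2]
  y <- if (integrate) integrate_profile(x) else x
  f <- vapply(scales, function(n) fluctuation(y, n, reverse_pass), numeric(1))
  out <- list(
    fluctuations = tibble::tibble(n = scales, F = f),
    alpha1 = NA_real_, alpha2 = NA_real_,
    r_squared = c(range1 = NA_real_, range2 = NA_real_),
    range1 = range1, range2 = range2,
    degenerate = all(f < .Machine$double.eps^0.5)
  )
  if (out$degenerate) {
    class(out) <- "dfa_result"
    return(out)
  }
  fit_range <- function(rng) {
    keep <- scales >= rng[1] & scales <= rng[2] & f > 0
    if (sum(keep) < 2) return(c(NA_real_, NA_real_))
    lx <- log10(scales[keep]); lf <- log10(f[keep])
    sl <- stats::cov(lx, lf) / stats::var(lx)
    r2 <- stats::cor(lx, lf)^2
    c(sl, r2)
  }
  f1 <- fit_range(range1); f2 <- fit_range(range2)
  out$alpha1 <- f1[1]; out$alpha2 <- f2[1]
  out$r_squared <- c(range1 = f1[2], range2 = f2[2])
  class(out) <- "dfa_result"
  out
}

#' @export
print.dfa_result <- function(x, ...) {
  cat("<dfa_result>\n")
  if (x$degenerate) {
    cat("  degenerate (constant input, F(n) = 0)\n")
  } else {
    cat(sprintf("  alpha1 (n %d-%d): %.3f  (R^2 %.3f)\n",
                x$range1[1], x$range1[2], x$alpha1, x$r_squared[["range1"]]))
    cat(sprintf("  alpha2 (n %d-%d): %.3f  (R^2 %.3f)\n",
                x$range2[1], x$range2[2], x$alpha2, x$r_squared[["range2"]]))
  }
  invisible(x)
}
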