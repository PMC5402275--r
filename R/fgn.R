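#' Theoretical autocovariance of fractional Gaussian noise
#'
#' Autocovariance of stationary fGn with Hurst parameter `hurst` and
#' marginal standard deviation `sd`:
#' \deqn{\gamma(k) = \frac{\sigma^2}{2}\left(|k+1|^{2H} - 2|k|^{2H} +
#'   |k-1|^{2H}\right)}
#'
#' @param lag integer vector of lags (>= 0).
#' @param hurst Hurst parameter in (0, 1).
#' @param sd marginal standard deviation (> 0).
#' @return numeric vector of autocovariances, one per lag.
#' @export
#' @examples
#' fgn_autocov(0:5, hurst = 0.5) # white noise: zero beyond lag 0
fgn_autocov <- function(lag, hurst, sd = 1) {
  check_number(hurst, "hurst", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(sd, "sd", lower = 0, strict_lower = TRUE)
  h2 <- 2 * hurst
  sd^2 * 0.5 * (abs(lag + 1)^h2 - 2 * abs(lag)^h2 + abs(lag - 1)^h2)
}

#' Generate fractional Gaussian noise by circulant embedding
#'
#' Exact (Davies-Harte) simulation of stationary fractional Gaussian
#' noise: the circulant embedding of the fGn covariance is diagonalized
#' by the FFT, so the sampled series carries the exact target
#' autocovariance whenever the embedding is nonnegative definite. For
#' the fGn covariance this holds for all Hurst values in (0, 1); should
#' a numerically negative eigenvalue appear (Hurst very close to 1 with
#' long series), the generator clips it to zero and falls back to the
#' resulting approximate spectral synthesis with a warning.
#'
#' fGn is the increment process of fractional Brownian motion; its DFA
#' scaling exponent equals its Hurst parameter, which is what makes it
#' the canonical validation fixture for DFA implementations.
#'
#' @param n_points series length (>= 2).
#' @param hurst Hurst parameter in (0, 1); 0.5 gives white noise.
#' @param mean,sd target marginal mean and standard deviation.
#' @param seed optional integer seed; the global RNG state is restored
#'   on exit, so generation is reproducible and side-effect free.
#' @return numeric vector of length `n_points`.
#' @export
#' @examples
#' x <- gen_fgn(1024, hurst = 0.9, seed = 1)
gen_fgn <- function(n_points, hurst, mean = 0, sd = 1, seed = NULL) {
  check_number(n_points, "n_points", lower = 2)
  check_number(hurst, "hurst", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(sd, "sd", lower = 0, strict_lower = TRUE)
  n <- as.integer(n_points)
  local_seed(seed, {
    m <- 2L * n
    gam <- fgn_autocov(0:n, hurst = hurst, sd = sd)
    circ <- c(gam, gam[n:2])                     # length 2n circulant row
    lam <- Re(stats::fft(circ))
    if (min(lam) < -1e-8 * max(lam)) {
      warning("embedding not nonnegative-definite; ",
              "falling back to approximate spectral synthesis")
    }
    lam <- pmax(lam, 0)
    z <- complex(real = stats::rnorm(m), imaginary = stats::rnorm(m))
    z[1] <- complex(real = sqrt(2) * Re(z[1]), imaginary = 0)
    z[n + 1] <- complex(real = sqrt(2) * Re(z[n + 1]), imaginary = 0)
    # enforce conjugate symmetry so the transform is real
    z[(n + 2):m] <- Conj(z[n:2])
    w <- sqrt(lam / (2 * m)) * z
    x <- Re(stats::fft(w))[seq_len(n)]
    x + mean
  })
}
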