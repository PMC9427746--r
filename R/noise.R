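#' Multichannel 1/f^alpha noise by spectral synthesis
#'
#' Draws independent Gaussian spectral coefficients with amplitude
#' proportional to `f^(-alpha/2)` (power proportional to `1/f^alpha`) and
#' inverse-transforms them. The DC coefficient is zero, so every channel
#' has exactly zero mean. Channels are synthesized pairwise in a single
#' complex inverse FFT (real and imaginary parts of a non-Hermitian
#' Gaussian spectrum are two independent real noises), which roughly
#' halves the cost.
#'
#' The output is scaled so that each channel has expected standard
#' deviation `scale`.
#'
#' @param n_samples Samples per channel (>= 2).
#' @param n_channels Number of channels.
#' @param alpha Spectral exponent (0 = white, 1 = pink).
#' @param seed Integer seed; identical seeds give identical arrays.
#' @param scale Target per-channel standard deviation (e.g. microvolts).
#' @return Numeric matrix, `n_samples` x `n_channels`.
#' @export
make_pink_noise <- function(n_samples, n_channels, alpha = 1, seed = 1,
                            scale = 1) {
  n <- as.integer(n_samples)
  if (is.na(n) || n < 2) stop("n_samples must be >= 2")
  if (alpha < 0) stop("alpha must be >= 0")
  n_channels <- as.integer(n_channels)
  stopifnot(n_channels >= 1)

  k <- seq_len(n - 1)                    # bins 1..n-1, DC excluded
  a <- pmin(k, n - k)^(-alpha / 2)       # symmetric |f| shape
  norm <- scale / sqrt(sum(a^2))         # Var(Re y_t) = sum(a_k^2)

  n_pair <- ceiling(n_channels / 2)
  out <- matrix(0, n, n_channels)
  g <- with_seed(seed, matrix(stats::rnorm(2 * (n - 1) * n_pair), n - 1L))
  for (p in seq_len(n_pair)) {
    S <- complex(length.out = n)
    S[2:n] <- complex(real = a * g[, 2L * p - 1L], imaginary = a * g[, 2L * p])
    y <- stats::fft(S, inverse = TRUE)
    out[, 2L * p - 1L] <- Re(y) * norm
    if (2L * p <= n_channels) out[, 2L * p] <- Im(y) * norm
  }
  out
}
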