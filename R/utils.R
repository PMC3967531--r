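# evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's state afterwards; all package-level randomness goes through this
with_rng_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# exact (brick-wall) spectral band-limiting of every column: FFT, zero all
# bins outside [low_hz, high_hz], inverse FFT. Used by the signal
# generator, where an exact band edge is wanted; the analysis pipeline uses
# the Butterworth filter in bandpass() instead.
spectral_bandlimit <- function(x, tr_seconds, low_hz, high_hz) {
  vec_in <- is.null(dim(x))
  m <- if (vec_in) matrix(x, ncol = 1L) else as.matrix(x)
  nt <- nrow(m)
  f <- (seq_len(nt) - 1L) / (nt * tr_seconds)
  f <- pmin(f, 1 / tr_seconds - f)  # fold to [0, Nyquist]
  keep <- f >= low_hz & f <= high_hz
  xf <- stats::mvfft(m)
  xf[!keep, ] <- 0
  out <- Re(stats::mvfft(xf, inverse = TRUE)) / nt
  if (vec_in) drop(out) else out
}

# draw a T x k matrix of correlated Gaussian noise with population
# correlation `corr` (must be PSD; eigen-based factor tolerates
# semi-definite matrices where Cholesky would fail)
correlated_noise <- function(n, corr) {
  e <- eigen(corr, symmetric = TRUE)
  vals <- e$values
  if (min(vals) < -1e-8) {
    stop(sprintf("correlation matrix is not PSD (eigenvalue %.3g)", min(vals)))
  }
  root <- e$vectors %*% (sqrt(pmax(vals, 0)) * t(e$vectors))
  matrix(stats::rnorm(n * ncol(corr)), n, ncol(corr)) %*% root
}
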