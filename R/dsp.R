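# Zero-phase IIR filtering with steady-state initial conditions.
#
# signal::filtfilt() starts both passes from a zero internal state, which for
# corner frequencies far below Nyquist leaves step transients that decay over
# thousands of samples. We instead run a direct-form-II-transposed filter whose
# initial state is the steady-state response to a unit step scaled by the first
# sample (the lfilter_zi construction), over an odd-reflection extension of the
# record, exactly as scipy.signal.filtfilt does by default.

# Steady-state DF2T state for a unit-step input.
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  b <- b / a[1]
  a <- a / a[1]
  if (n == 1L) return(numeric(0))
  comp <- matrix(0, n - 1, n - 1)
  comp[1, ] <- -a[-1]
  if (n > 2) comp[cbind(2:(n - 1), 1:(n - 2))] <- 1
  solve(diag(n - 1) - t(comp), b[-1] - a[-1] * b[1])
}

# Direct-form-II-transposed single-pass filter with initial state zi.
lfilter_df2t <- function(b, a, x, zi) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b))) / a[1]
  a <- c(a, rep(0, n - length(a))) / a[1]
  y <- numeric(length(x))
  z <- c(zi, 0)
  for (i in seq_along(x)) {
    y[i] <- b[1] * x[i] + z[1]
    for (k in seq_len(n - 1)) z[k] <- b[k + 1] * x[i] + z[k + 1] - a[k + 1] * y[i]
  }
  y
}

# Forward-backward filtering; pad = reflection length in samples.
filtfilt_ic <- function(b, a, x, pad) {
  n <- length(x)
  pad <- max(1L, min(as.integer(pad), n - 1L))
  zi <- lfilter_zi(b, a)
  ext <- c(2 * x[1] - x[seq(pad + 1, 2)],
           x,
           2 * x[n] - x[seq(n - 1, n - pad)])
  y <- lfilter_df2t(b, a, ext, zi * ext[1])
  y <- rev(lfilter_df2t(b, a, rev(y), zi * y[length(y)]))
  y[(pad + 1):(pad + n)]
}

# Anti-aliased integer-factor decimation by block means. Signal content is
# restricted to a few Hz, so block averaging (a comb low-pass) is an adequate
# pre-filter before the recursive band-pass runs at the reduced rate.
decimate_block_mean <- function(x, m) {
  if (m <= 1L) return(x)
  nfull <- m * (length(x) %/% m)
  colMeans(matrix(x[seq_len(nfull)], nrow = m))
}
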