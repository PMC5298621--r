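# Independent oracles. The PLS oracle solves the same projection problem as
# NIPALS PLS1 but through the Krylov-subspace formulation: the k-factor PLS1
# regression vector is the least-squares solution restricted to
# span{s, (X'X)s, ..., (X'X)^(k-1) s} with s = X'y, solved here by explicit
# normal equations in an orthonormalized Krylov basis. No code is shared with
# fit_pls().
pls_krylov_oracle <- function(X, y, k) {
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean)
  yc <- y - y_mean
  s <- drop(crossprod(Xc, yc))
  K <- matrix(0, ncol(Xc), k)
  v <- s
  for (j in seq_len(k)) {
    K[, j] <- v
    v <- drop(crossprod(Xc, Xc %*% v))
  }
  Q <- qr.Q(qr(K))
  A <- crossprod(Xc %*% Q)          # Q' X'X Q
  rhs <- drop(crossprod(Q, s))      # Q' X'y
  b <- drop(Q %*% solve(A, rhs))
  list(
    coef = b,
    predict = function(Xnew) drop(y_mean + sweep(Xnew, 2, x_mean) %*% b)
  )
}

# Brute-force leave-one-out PRESS using the Krylov oracle.
loo_press_oracle <- function(X, y, k) {
  n <- nrow(X)
  if (k == 0) {
    loo_mean <- (sum(y) - y) / (n - 1)
    return(sum((y - loo_mean)^2))
  }
  sum(vapply(seq_len(n), function(i) {
    fit <- pls_krylov_oracle(X[-i, , drop = FALSE], y[-i], k)
    (fit$predict(X[i, , drop = FALSE]) - y[i])^2
  }, numeric(1)))
}

# Ordinary least squares on centered data (normal equations).
ols_oracle_predict <- function(X, y, Xnew) {
  x_mean <- colMeans(X)
  Xc <- sweep(X, 2, x_mean)
  yc <- y - mean(y)
  b <- solve(crossprod(Xc), crossprod(Xc, yc))
  drop(mean(y) + sweep(Xnew, 2, x_mean) %*% b)
}

# Small fixed beat-matrix fixture (n = 4, L = 3) for PRESS oracle checks.
press_fixture <- function() {
  X <- matrix(c(0.1, 0.9, 0.3, 0.2,
                0.8, 0.4, 0.5, 0.9,
                0.3, 0.2, 0.7, 0.6), nrow = 4)
  y <- c(104, 119, 111, 108)
  list(X = X, y = y)
}

# A train of Gaussian systolic bumps at a fixed rate: an independent pulse
# signal for segmentation tests (no package generator involved).
bump_train <- function(fs, duration_s, bpm, width_s = 0.06, amp = 1) {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  period <- 60 / bpm
  centers <- seq(period / 2, duration_s, by = period)
  x <- numeric(length(t))
  for (ctr in centers) x <- x + amp * exp(-(t - ctr)^2 / (2 * width_s^2))
  x - mean(x)
}

# Quiet, low-noise subject for pipeline tests: exactly linear morphology in
# bp (anchor bump A has zero slope so normalization stays affine).
quiet_subject <- function(id = "Q", bp_mean = 110, bp_sd = 5,
                          detector_noise_sd = 0, ref_noise_sd = 0,
                          heart_rate_bpm = 66) {
  subject_params(
    id, bp_mean = bp_mean, bp_sd = bp_sd, heart_rate_bpm = heart_rate_bpm,
    bp_sensitivity = c(A = 0, B = -0.004, C = 0.005, D = -0.002, E = 0.002),
    ref_noise_sd = ref_noise_sd, detector_noise_sd = detector_noise_sd,
    morph_noise_sd = 0
  )
}
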