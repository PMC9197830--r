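# Shared fixtures: a small 15-bit/4-target codebook sampled at 300 Hz (10
# samples per bit, as in the full-size design) and populations built on it,
# plus constructors for matrices with exactly prescribed properties.

tiny_codebook <- function() {
  codebook(msequence(4, bit_rate = 30), n_targets = 4, lag_bits = 3,
           reference_target = 2)
}

tiny_population <- function(n_subjects = 3, seed = 1,
                            snr_range = c(0.15, 0.30), n_train = 8,
                            n_test_per_target = 3, ...) {
  simulate_population(n_subjects = n_subjects, cb = tiny_codebook(),
                      n_channels = 3, fs = 300, n_train = n_train,
                      n_test_per_target = n_test_per_target,
                      snr_range = snr_range, seed = seed, ...)
}

rand_spd <- function(n, scale = 1) {
  A <- matrix(stats::rnorm(n * n), n, n)
  crossprod(A) / n + scale * diag(n)
}

rand_orth <- function(n) {
  qr.Q(qr(matrix(stats::rnorm(n * n), n, n)))
}

# A trial whose sample covariance is exactly C: whiten white noise, color it.
trial_with_cov <- function(C, nt = 40, seed = 1) {
  X <- withr::with_seed(seed, matrix(stats::rnorm(nrow(C) * nt), nrow(C), nt))
  X <- X - rowMeans(X)
  W <- spd_invsqrt(scm(X), quiet = TRUE)
  spd_sqrtm(C, quiet = TRUE) %*% W %*% X
}

# Independent circular autocorrelation of a ±1-mapped bit vector.
circ_autocorr_pm1 <- function(bits, lag) {
  x <- 2L * bits - 1L
  L <- length(x)
  k <- ((lag %% L) + L) %% L
  sum(x * x[((seq_len(L) - 1 + k) %% L) + 1])
}
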