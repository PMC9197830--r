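# Synthetic multi-subject c-VEP EEG. Each subject has a code-locked visual
# evoked response (a temporal kernel convolved with the ±1 stimulus waveform),
# a fixed source-to-channel projection, a subject-specific invertible channel
# transform (the cross-subject distribution shift that alignment is meant to
# remove), and additive Gaussian channel noise.

#' Visual evoked response kernel
#'
#' A difference-of-gamma-density waveform: a positive component peaking at
#' `peak_s` seconds followed by a weaker negative rebound, normalized to unit
#' peak. This is the simplest smooth, band-limited kernel with the code-locked
#' structure the decoder exploits.
#'
#' @param fs Sampling rate (Hz).
#' @param peak_s Latency of the positive peak (seconds).
#' @param undershoot_s Latency of the negative rebound (seconds).
#' @param undershoot_ratio Amplitude of the rebound relative to the peak.
#' @param duration_s Kernel support (seconds).
#' @return Numeric vector of `round(duration_s * fs)` samples.
#' @export
vep_kernel <- function(fs, peak_s = 0.10, undershoot_s = 0.22,
                       undershoot_ratio = 0.5, duration_s = 0.45) {
  t <- seq(0, duration_s, by = 1 / fs)
  gamma_bump <- function(peak, width) {
    k <- (peak / width)^2
    theta <- width^2 / peak
    g <- stats::dgamma(t, shape = k, scale = theta)
    g / max(g)
  }
  h <- gamma_bump(peak_s, 0.035) - undershoot_ratio * gamma_bump(undershoot_s, 0.08)
  h / max(abs(h))
}

#' Generative model for one synthetic subject
#'
#' @param kernel Evoked-response kernel sampled at `fs` (see [vep_kernel()]).
#' @param mixing Source-to-channel projection, numeric vector of length
#'   `n_channels` (an occipital-like gradient by default).
#' @param channel_transform Invertible `n_channels x n_channels` matrix applied
#'   to the whole recording: the subject-specific linear shift between
#'   subjects' channel frames. Identity means no shift.
#' @param noise_sd Standard deviation of i.i.d. Gaussian channel noise, in
#'   units of the (unit-RMS) source signal.
#' @param latency_s Response delay in seconds (circular within a cycle).
#' @param n_channels Number of channels.
#' @param fs Sampling rate used to sample `kernel` (Hz).
#' @return An object of class `cvep_subject_model`.
#' @export
subject_model <- function(kernel = vep_kernel(fs), mixing = NULL,
                          channel_transform = NULL, noise_sd = 1,
                          latency_s = 0, n_channels = 9, fs = 600) {
  if (is.null(mixing)) mixing <- seq(1, 0.6, length.out = n_channels)
  if (is.null(channel_transform)) channel_transform <- diag(n_channels)
  stopifnot(length(mixing) == n_channels,
            all(dim(channel_transform) == n_channels), noise_sd >= 0)
  sv <- svd(channel_transform, nu = 0, nv = 0)$d
  kappa <- max(sv) / min(sv)
  if (min(sv) <= 0 || !is.finite(kappa) || kappa > 1e8) {
    stop("channel_transform is (near-)singular: condition number ",
         format(kappa), call. = FALSE)
  }
  structure(
    list(kernel = kernel, mixing = as.numeric(mixing),
         channel_transform = channel_transform, noise_sd = noise_sd,
         latency_s = latency_s, n_channels = n_channels, fs = fs,
         condition_number = kappa),
    class = "cvep_subject_model"
  )
}

# ±1 stimulus waveform of one code over one cycle at fs.
code_waveform <- function(bits, bit_rate, fs) {
  L <- length(bits)
  ntc <- round(fs * L / bit_rate)
  bit_idx <- floor((seq_len(ntc) - 1) * bit_rate / fs) %% L + 1
  2 * bits[bit_idx] - 1
}

# Circular convolution of a cycle-long waveform with a kernel.
circ_conv <- function(x, h) {
  n <- length(x)
  hpad <- c(h, rep(0, n - length(h)))
  Re(stats::fft(stats::fft(x) * stats::fft(hpad), inverse = TRUE)) / n
}

circ_shift_vec <- function(x, k) {
  n <- length(x)
  k <- ((k %% n) + n) %% n
  if (k == 0) x else c(x[(n - k + 1):n], x[seq_len(n - k)])
}

# Noiseless unit-RMS source waveforms, one cycle per target, rows = targets.
target_waveforms <- function(model, cb, fs) {
  s0 <- circ_conv(code_waveform(cb$codes[[1]], cb$bit_rate, fs), model$kernel)
  s0 <- circ_shift_vec(s0, round(model$latency_s * fs))
  s0 <- s0 / sqrt(mean(s0^2))
  spb <- fs / cb$bit_rate
  t(vapply(seq_len(cb$n_targets), function(z) {
    circ_shift_vec(s0, round((z - 1) * cb$lag_bits * spb))
  }, numeric(length(s0))))
}

#' Simulate one subject's c-VEP session
#'
#' Generates the training block (`n_train` trials recorded at the codebook's
#' reference target) and the test block (`n_test_per_target` trials for each
#' of the `Z` targets), mirroring a session in which the subject fixates the
#' reference target for the training cycles and then every target in turn.
#' Each trial is `channel_transform %*% (mixing %*% source + noise)` where
#' `source` is the kernel circularly convolved with the target's ±1 code
#' waveform, delayed by the model latency and tiled to `cycle_multiple`
#' stimulus cycles. The source waveform has unit RMS, so `noise_sd` is the
#' noise-to-signal amplitude ratio at the source level.
#'
#' @param model A [subject_model()].
#' @param cb A [codebook()].
#' @param n_train Training trials at the reference target.
#' @param n_test_per_target Test trials per target.
#' @param fs Sampling rate (Hz); must resolve one code bit with at least 2
#'   samples. The default 600 Hz makes one bit exactly 10 samples, so a 4-bit
#'   target lag is exactly 40 samples and circular trial shifting is exact.
#' @param cycle_multiple Trial length in stimulus cycles (may be fractional).
#' @param seed Integer seed; generation is bit-reproducible given the seed.
#' @param subject_id Identifier stored with the data.
#' @return A `cvep_subject`: list with `subject_id`, `trials`
#'   (`[Nc x Nt x n]`), `labels` (1-based target index), `role`
#'   (`"train_reference"`/`"test"`), `fs`, `codebook`, `model`.
#' @export
simulate_subject <- function(model, cb, n_train = 100, n_test_per_target = 5,
                             fs = model$fs, cycle_multiple = 1, seed = 1,
                             subject_id = "s01") {
  stopifnot(inherits(model, "cvep_subject_model"), inherits(cb, "cvep_codebook"))
  if (fs * cb$period_s / cb$base$length < 2) {
    stop("fs too low: fewer than 2 samples per code bit", call. = FALSE)
  }
  ntc <- round(fs * cb$period_s)
  nt <- round(cycle_multiple * fs * cb$period_s)
  wf <- target_waveforms(model, cb, fs)
  tile <- wf[, ((seq_len(nt) - 1) %% ntc) + 1, drop = FALSE]
  nc <- model$n_channels
  labels <- c(rep(cb$reference_target, n_train),
              rep(seq_len(cb$n_targets), each = n_test_per_target))
  role <- c(rep("train_reference", n_train),
            rep("test", n_test_per_target * cb$n_targets))
  n <- length(labels)
  trials <- withr::with_seed(seed, {
    out <- array(0, c(nc, nt, n))
    for (i in seq_len(n)) {
      sig <- model$mixing %o% tile[labels[i], ]
      noise <- matrix(stats::rnorm(nc * nt, sd = model$noise_sd), nc, nt)
      out[, , i] <- model$channel_transform %*% (sig + noise)
    }
    out
  })
  structure(
    list(subject_id = subject_id, trials = trials, labels = as.integer(labels),
         role = role, fs = fs, codebook = cb, model = model),
    class = "cvep_subject"
  )
}

#' Simulate a multi-subject c-VEP population
#'
#' Subjects are assigned round-robin to `similarity_clusters` response
#' prototypes that differ in evoked-kernel peak latency and rebound strength
#' and — decisively for transfer — in scalp topography (the source-to-channel
#' projection is rotated between prototypes within a smooth two-profile
#' subspace). Within a cluster, kernels and topographies get small jitter, so
#' some source subjects resemble any given target subject much more than
#' others (the structure that subject selection exploits). Topography
#' differences are genuine signal-geometry differences that whitening-based
#' alignment does not remove, which is what makes cross-cluster transfer
#' harmful rather than merely unhelpful. Each subject receives a symmetric positive
#' definite channel transform `I + shift_strength * A` with `A` a random
#' symmetric Gaussian matrix (`shift_strength = 0` means all subjects share
#' the channel frame). A symmetric transform is exactly the distortion that
#' congruence-invariant whitening alignment removes: whitening a covariance
#' `T P Tᵀ` cancels the full transform when `T` is symmetric, whereas a
#' rotation component would survive whitening in principle. Noise levels are
#' drawn from `snr_range` (amplitude signal-to-noise: source signal RMS over
#' channel noise SD).
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param cb A [codebook()]; defaults to the 63-bit/16-target/4-bit-lag book.
#' @param n_channels Channels per subject.
#' @param similarity_clusters Number of response prototypes.
#' @param cluster_separation Scale of the spread between cluster prototypes
#'   (1 spreads peak latencies over ~45 ms, rebound strengths over ~0.25 and
#'   topography angles over ~60 degrees; 0 makes all clusters identical).
#' @param shift_strength Magnitude of the per-subject channel transform.
#' @param snr_range Length-2 interval of amplitude SNR to draw from;
#'   `c(Inf, Inf)` gives noiseless subjects.
#' @param n_train,n_test_per_target,fs,cycle_multiple Passed to
#'   [simulate_subject()].
#' @param seed Master seed; per-subject seeds are derived from it.
#' @return A `cvep_dataset`: list with `subjects` (list of `cvep_subject`),
#'   `codebook`, `config`, `seed`.
#' @export
simulate_population <- function(n_subjects = 16, cb = NULL, n_channels = 9,
                                similarity_clusters = 2,
                                cluster_separation = 1, shift_strength = 1,
                                snr_range = c(0.08, 0.15), n_train = 100,
                                n_test_per_target = 5, fs = 600,
                                cycle_multiple = 1, seed = 1) {
  stopifnot(n_subjects >= 2, similarity_clusters >= 1, shift_strength >= 0)
  if (is.null(cb)) cb <- codebook(msequence(6))
  clusters <- rep(seq_len(similarity_clusters), length.out = n_subjects)
  # Cluster prototypes: spread peak latency and rebound over plausible ranges.
  nproto <- max(similarity_clusters, 2)
  proto_peak <- 0.10 + cluster_separation * seq(0, 0.045, length.out = nproto)
  proto_under <- 0.45 + cluster_separation * seq(0, 0.25, length.out = nproto)
  # Topography prototypes: rotations within the span of two smooth profiles.
  m1 <- seq(1, 0.6, length.out = n_channels)
  m1 <- m1 / sqrt(sum(m1^2))
  m2 <- sin(seq(0, pi, length.out = n_channels))
  m2 <- m2 - sum(m2 * m1) * m1
  m2 <- m2 / sqrt(sum(m2^2))
  proto_angle <- cluster_separation * seq(0, pi / 3, length.out = nproto)
  mix_scale <- sqrt(sum(seq(1, 0.6, length.out = n_channels)^2))
  rand_spd_transform <- function() {
    A <- matrix(stats::rnorm(n_channels^2, sd = 1 / sqrt(n_channels)),
                n_channels, n_channels)
    A <- (A + t(A)) / 2
    tr <- diag(n_channels) + shift_strength * A
    ev <- eigen(tr, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 0.05 * max(ev)) rand_spd_transform() else tr
  }
  models <- withr::with_seed(seed, {
    lapply(seq_len(n_subjects), function(i) {
      j <- clusters[i]
      kern <- vep_kernel(
        fs,
        peak_s = proto_peak[j] + stats::rnorm(1, 0, 0.003),
        undershoot_ratio = proto_under[j] + stats::rnorm(1, 0, 0.03)
      )
      mix <- mix_scale * (cos(proto_angle[j]) * m1 + sin(proto_angle[j]) * m2) *
        exp(stats::rnorm(n_channels, 0, 0.1))
      noise_sd <- if (all(is.infinite(snr_range))) 0 else
        1 / stats::runif(1, snr_range[1], snr_range[2])
      subject_model(kernel = kern, mixing = mix,
                    channel_transform = rand_spd_transform(),
                    noise_sd = noise_sd, n_channels = n_channels, fs = fs)
    })
  })
  subjects <- lapply(seq_len(n_subjects), function(i) {
    simulate_subject(models[[i]], cb, n_train = n_train,
                     n_test_per_target = n_test_per_target, fs = fs,
                     cycle_multiple = cycle_multiple,
                     seed = (seed + 7919L * i) %% .Machine$integer.max,
                     subject_id = sprintf("s%02d", i))
  })
  structure(
    list(subjects = subjects, codebook = cb,
         config = list(n_subjects = n_subjects, n_channels = n_channels,
                       similarity_clusters = similarity_clusters,
                       cluster_separation = cluster_separation,
                       clusters = clusters, shift_strength = shift_strength,
                       snr_range = snr_range, n_train = n_train,
                       n_test_per_target = n_test_per_target, fs = fs,
                       cycle_multiple = cycle_multiple),
         seed = seed),
    class = "cvep_dataset"
  )
}

#' @export
print.cvep_subject <- function(x, ...) {
  d <- dim(x$trials)
  cat(sprintf("<cvep_subject> %s: %d trials (%d channels x %d samples), %d train / %d test\n",
              x$subject_id, d[3], d[1], d[2],
              sum(x$role == "train_reference"), sum(x$role == "test")))
  invisible(x)
}

#' @export
print.cvep_dataset <- function(x, ...) {
  cat(sprintf("<cvep_dataset> %d subjects, %d channels, fs %g Hz, %d targets, seed %s\n",
              length(x$subjects), x$config$n_channels, x$config$fs,
              x$codebook$n_targets, format(x$seed)))
  invisible(x)
}
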