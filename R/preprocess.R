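# Band-pass filtering, epoching, reference-target trial shifting and
# template averaging.

#' Band-pass filter specification
#'
#' Butterworth band-pass used before any covariance estimation; the default is
#' 2-30 Hz at (overall) order 8. `zero_phase` applies the filter forward and
#' backward (no group delay), the standard choice for offline analysis;
#' `causal` is a single forward pass, retained for online use. Because a
#' Butterworth band-pass of design order `n` has overall order `2n`, `order`
#' must be even.
#'
#' @param low_hz,high_hz Band edges in Hz.
#' @param order Overall filter order (even).
#' @param phase `"zero_phase"` or `"causal"`.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(low_hz = 2, high_hz = 30, order = 8,
                        phase = c("zero_phase", "causal")) {
  phase <- match.arg(phase)
  stopifnot(low_hz > 0, high_hz > low_hz, order >= 2)
  if (order %% 2 != 0) stop("band-pass `order` must be even", call. = FALSE)
  structure(list(low_hz = low_hz, high_hz = high_hz, order = order,
                 phase = phase), class = "filter_spec")
}

apply_filt <- function(x, bf, phase) {
  if (phase == "zero_phase") signal::filtfilt(bf, x) else signal::filter(bf, x)
}

#' Band-pass filter multichannel trials
#'
#' Filters each channel of each trial with the Butterworth band-pass described
#' by `spec`. Accepts a single trial (channels x samples matrix) or an epoched
#' array (channels x samples x trials). The band must lie below the Nyquist
#' frequency and trials must be at least three filter orders long so edge
#' effects do not dominate.
#'
#' @param trials Matrix `[Nc x Nt]` or array `[Nc x Nt x n]`.
#' @param fs Sampling rate in Hz.
#' @param spec A [filter_spec()].
#' @return Filtered data with the same shape.
#' @export
bandpass_trials <- function(trials, fs, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  if (spec$high_hz >= fs / 2) {
    stop(sprintf("band edge %g Hz is not below the Nyquist frequency %g Hz",
                 spec$high_hz, fs / 2), call. = FALSE)
  }
  one <- is.matrix(trials)
  if (one) trials <- array(trials, c(dim(trials), 1))
  nt <- dim(trials)[2]
  if (nt < 3 * spec$order) {
    stop("trials are too short for the filter's edge effects (need >= 3x order samples)",
         call. = FALSE)
  }
  bf <- signal::butter(spec$order / 2, c(spec$low_hz, spec$high_hz) / (fs / 2),
                       type = "pass")
  out <- trials
  for (k in seq_len(dim(trials)[3])) {
    for (c in seq_len(dim(trials)[1])) {
      out[c, , k] <- apply_filt(trials[c, , k], bf, spec$phase)
    }
  }
  if (one) drop_third(out) else out
}

drop_third <- function(a) {
  m <- a[, , 1, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  m
}

#' Cut continuous data into fixed-length trials
#'
#' @param continuous Matrix, channels x total samples.
#' @param onsets 1-based sample indices where trials start.
#' @param n_samples Trial length in samples.
#' @return Array `[Nc x n_samples x length(onsets)]`. Overlapping onsets are
#'   allowed; any onset whose window leaves the data raises an error naming it.
#' @export
epoch_signal <- function(continuous, onsets, n_samples) {
  stopifnot(is.matrix(continuous), n_samples >= 1)
  onsets <- as.integer(onsets)
  bad <- onsets < 1 | (onsets + n_samples - 1) > ncol(continuous)
  if (any(bad)) {
    stop("onset(s) out of bounds: ", paste(onsets[bad], collapse = ", "),
         call. = FALSE)
  }
  out <- array(0, c(nrow(continuous), n_samples, length(onsets)))
  for (i in seq_along(onsets)) {
    out[, , i] <- continuous[, onsets[i]:(onsets[i] + n_samples - 1)]
  }
  out
}

circ_shift_cols <- function(M, k) {
  n <- ncol(M)
  k <- ((k %% n) + n) %% n
  if (k == 0) return(M)
  M[, c((n - k + 1):n, seq_len(n - k)), drop = FALSE]
}

#' Synthesize training trials of other targets by circular time shifting
#'
#' Because every target flashes the same code at a different circular lag,
#' trials recorded while fixating the reference target can be rotated in time
#' to produce training trials for any other target: target `z` is obtained by
#' rotating right by `(z - reference) * lag_bits` bits, converted to samples
#' at `fs`. Trials must be whole stimulus cycles for the rotation to be exact;
#' a non-integer sample shift is rounded to the nearest sample with a warning
#' reporting the residual (at the package's default simulation rate of 600 Hz
#' one bit is exactly 10 samples, so no rounding occurs).
#'
#' @param trials Reference-target trials, `[Nc x Nt]` or `[Nc x Nt x n]`.
#' @param cb A [codebook()].
#' @param target_z 1-based target index to synthesize.
#' @param fs Sampling rate in Hz.
#' @param reference 1-based index of the target the trials were recorded at.
#' @return Shifted trials with the same shape.
#' @export
shift_trials <- function(trials, cb, target_z, fs,
                         reference = cb$reference_target) {
  stopifnot(inherits(cb, "cvep_codebook"))
  if (target_z < 1 || target_z > cb$n_targets) {
    stop("target_z must lie in 1..n_targets", call. = FALSE)
  }
  delta_bits <- (target_z - reference) * cb$lag_bits
  shift <- delta_bits * fs / cb$bit_rate
  if (abs(shift - round(shift)) > 1e-6) {
    warning(sprintf(
      "non-integer sample shift %.4f rounded to %d (residual %.4f samples)",
      shift, round(shift), shift - round(shift)))
  }
  shift <- as.integer(round(shift))
  one <- is.matrix(trials)
  if (one) trials <- array(trials, c(dim(trials), 1))
  out <- trials
  for (k in seq_len(dim(trials)[3])) {
    slice <- trials[, , k, drop = FALSE]
    dim(slice) <- dim(slice)[1:2]
    out[, , k] <- circ_shift_cols(slice, shift)
  }
  if (one) drop_third(out) else out
}

#' Average trials of the same class into template signals
#'
#' @param trials Array `[Nc x Nt x n]`.
#' @param labels Integer class labels (1-based), one per trial.
#' @param n_classes Number of classes `Z`; every class in `1..Z` must have at
#'   least one trial.
#' @return A `cvep_templates`: list with `templates` (array `[Nc x Nt x Z]`,
#'   the per-class arithmetic means) and `n_per_class`.
#' @export
class_templates <- function(trials, labels, n_classes = max(labels)) {
  stopifnot(is.array(trials), length(dim(trials)) == 3,
            length(labels) == dim(trials)[3])
  labels <- as.integer(labels)
  counts <- tabulate(labels, nbins = n_classes)
  if (any(counts == 0)) {
    stop("no trials for class(es): ", paste(which(counts == 0), collapse = ", "),
         call. = FALSE)
  }
  nc <- dim(trials)[1]; nt <- dim(trials)[2]
  flat <- matrix(trials, nc * nt, dim(trials)[3])
  tpl <- array(0, c(nc, nt, n_classes))
  for (z in seq_len(n_classes)) {
    idx <- which(labels == z)
    tpl[, , z] <- matrix(rowMeans(flat[, idx, drop = FALSE]), nc, nt)
  }
  structure(list(templates = tpl, n_per_class = counts),
            class = "cvep_templates")
}
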