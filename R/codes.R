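# m-sequence generation and the circular-shift codebook that assigns one
# lagged copy of the base code to each stimulus target.

.default_taps <- list(
  `3` = c(3, 2), `4` = c(4, 3), `5` = c(5, 3), `6` = c(6, 5),
  `7` = c(7, 6), `8` = c(8, 6, 5, 4), `9` = c(9, 5), `10` = c(10, 7)
)

#' Generate a maximum-length binary sequence (m-sequence)
#'
#' Steps a Fibonacci linear-feedback shift register: the output bit is the
#' last stage, the feedback bit is the XOR of the tapped stages and is shifted
#' in at the front. With taps corresponding to a primitive feedback polynomial
#' the state cycles through all `2^n - 1` nonzero states, giving a sequence of
#' length `2^n_stages - 1` with `2^(n-1)` ones and `2^(n-1) - 1` zeros and a
#' two-valued circular autocorrelation (`L` at lag 0, `-1` elsewhere, on the
#' `±1`-mapped sequence). Primitivity is verified at run time by measuring the
#' state period; non-primitive taps raise an error naming the measured period.
#'
#' The default degree-6 taps are `c(6, 5)` (feedback polynomial
#' `x^6 + x^5 + 1`, primitive), giving the 63-bit code used with a 60 Hz
#' display, where one cycle spans 63/60 = 1.05 s.
#'
#' @param n_stages Number of shift-register stages (sequence length is
#'   `2^n_stages - 1`).
#' @param taps Stage indices whose XOR forms the feedback bit. Defaults to a
#'   documented primitive set for `n_stages` in 3..10.
#' @param init Initial register state, a nonzero 0/1 vector of length
#'   `n_stages`. Defaults to `c(1, 0, 0, ...)`.
#' @param bit_rate Presentation rate of the code in bits/second (the monitor
#'   refresh rate), stored on the returned code.
#' @return A `cvep_code`: list with `bits` (integer 0/1 vector), `bit_rate`,
#'   `length`.
#' @examples
#' code <- msequence(6)
#' length(code$bits)  # 63
#' sum(code$bits)     # 32
#' @export
msequence <- function(n_stages, taps = NULL, init = NULL, bit_rate = 60) {
  stopifnot(is.numeric(n_stages), length(n_stages) == 1, n_stages >= 2)
  n_stages <- as.integer(n_stages)
  if (is.null(taps)) {
    taps <- .default_taps[[as.character(n_stages)]]
    if (is.null(taps)) stop("no default taps for n_stages = ", n_stages,
                            "; supply `taps`", call. = FALSE)
  }
  taps <- as.integer(taps)
  if (any(taps < 1 | taps > n_stages)) stop("taps must index stages 1..n_stages", call. = FALSE)
  if (!(n_stages %in% taps)) {
    stop("taps must include the last stage (degree-", n_stages,
         " feedback polynomial)", call. = FALSE)
  }
  if (is.null(init)) init <- c(1L, rep(0L, n_stages - 1))
  init <- as.integer(init)
  if (length(init) != n_stages || !all(init %in% c(0L, 1L))) {
    stop("`init` must be a 0/1 vector of length n_stages", call. = FALSE)
  }
  if (all(init == 0L)) stop("initial state must not be all zeros", call. = FALSE)

  L <- as.integer(2^n_stages - 1)
  state <- init
  bits <- integer(L)
  period <- NA_integer_
  for (i in seq_len(L)) {
    bits[i] <- state[n_stages]
    fb <- sum(state[taps]) %% 2L
    state <- c(fb, state[-n_stages])
    if (is.na(period) && all(state == init)) period <- i
  }
  if (!is.na(period) && period < L) {
    stop(sprintf(
      "taps are not primitive: register period is %d, expected %d", period, L),
      call. = FALSE)
  }
  structure(
    list(bits = bits, bit_rate = bit_rate, length = L,
         n_stages = n_stages, taps = taps),
    class = "cvep_code"
  )
}

as_code <- function(bits, bit_rate) {
  structure(list(bits = as.integer(bits), bit_rate = bit_rate,
                 length = length(bits)), class = "cvep_code")
}

#' Circularly shift a binary code
#'
#' Right circular rotation: bit `i` of the result is bit `i - lag_bits`
#' (modulo the code length) of the input, so a positive lag delays the code.
#' Length and bit counts are preserved; the lag is taken modulo the length.
#'
#' @param code A `cvep_code` from [msequence()].
#' @param lag_bits Integer rotation (may be negative or exceed the length).
#' @return A `cvep_code` with rotated bits.
#' @export
code_shift <- function(code, lag_bits) {
  stopifnot(inherits(code, "cvep_code"))
  L <- code$length
  k <- ((as.integer(lag_bits) %% L) + L) %% L
  bits <- code$bits
  if (k > 0) bits <- c(bits[(L - k + 1):L], bits[seq_len(L - k)])
  out <- code
  out$bits <- bits
  out
}

# Circular autocorrelation of the ±1-mapped code at one lag.
code_autocorr <- function(code, lag) {
  x <- 2L * code$bits - 1L
  L <- length(x)
  k <- ((lag %% L) + L) %% L
  sum(x * x[((seq_len(L) - 1 + k) %% L) + 1])
}

#' Build the circular-shift codebook for a multi-target stimulator
#'
#' Target `z` (1-based) is modulated by the base code rotated right by
#' `(z - 1) * lag_bits` bits, so adjacent targets are separated by a fixed
#' time lag of `lag_bits / bit_rate` seconds. One stimulus cycle lasts
#' `period_s = L / bit_rate` seconds (1.05 s for a 63-bit code at 60 Hz).
#' Training data are recorded at a single reference target (the 11th by
#' default) and later shifted in time to synthesize the other classes.
#'
#' @param base A `cvep_code`, typically from [msequence()].
#' @param n_targets Number of stimulus targets `Z` (at least 2).
#' @param lag_bits Bits of circular lag between adjacent targets.
#' @param bit_rate Bits/second; defaults to the base code's rate.
#' @param reference_target 1-based index of the target used to record
#'   training data.
#' @return A `cvep_codebook`: list with `base`, `codes` (list of `Z` bit
#'   vectors), `n_targets`, `lag_bits`, `bit_rate`, `period_s`,
#'   `reference_target`.
#' @examples
#' cb <- codebook(msequence(6), n_targets = 16, lag_bits = 4)
#' cb$period_s  # 1.05
#' @export
codebook <- function(base, n_targets = 16, lag_bits = 4,
                     bit_rate = base$bit_rate, reference_target = 11) {
  stopifnot(inherits(base, "cvep_code"), n_targets >= 2, lag_bits >= 0)
  if (reference_target < 1 || reference_target > n_targets) {
    stop("reference_target must lie in 1..n_targets", call. = FALSE)
  }
  codes <- lapply(seq_len(n_targets) - 1L,
                  function(z) code_shift(base, z * lag_bits)$bits)
  keys <- vapply(codes, paste, character(1), collapse = "")
  if (anyDuplicated(keys)) {
    stop("degenerate lag structure: the ", n_targets,
         " target codes are not pairwise distinct", call. = FALSE)
  }
  structure(
    list(base = base, codes = codes, n_targets = as.integer(n_targets),
         lag_bits = as.integer(lag_bits), bit_rate = bit_rate,
         period_s = base$length / bit_rate,
         reference_target = as.integer(reference_target)),
    class = "cvep_codebook"
  )
}

#' Read and write codebooks as JSON
#'
#' @param cb A `cvep_codebook`.
#' @param path File path.
#' @return `read_codebook()` returns a `cvep_codebook`; `write_codebook()`
#'   returns `path` invisibly.
#' @export
write_codebook <- function(cb, path) {
  stopifnot(inherits(cb, "cvep_codebook"))
  obj <- list(
    bits = paste(cb$base$bits, collapse = ""),
    bit_rate = cb$bit_rate,
    n_targets = cb$n_targets,
    lag_bits = cb$lag_bits,
    reference_target = cb$reference_target
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_codebook
#' @export
read_codebook <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- as_code(as.integer(strsplit(obj$bits, "")[[1]]), obj$bit_rate)
  codebook(base, n_targets = obj$n_targets, lag_bits = obj$lag_bits,
           bit_rate = obj$bit_rate, reference_target = obj$reference_target)
}

#' @export
print.cvep_codebook <- function(x, ...) {
  cat(sprintf(
    "<cvep_codebook> %d-bit code at %g bits/s (cycle %.4g s), %d targets, %d-bit lag, reference target %d\n",
    x$base$length, x$bit_rate, x$period_s, x$n_targets, x$lag_bits,
    x$reference_target))
  invisible(x)
}

#' @export
print.cvep_code <- function(x, ...) {
  cat(sprintf("<cvep_code> length %d at %g bits/s: %s...\n",
              x$length, x$bit_rate,
              paste(utils::head(x$bits, 16), collapse = "")))
  invisible(x)
}
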