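# broom-style tidiers for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a LOSO result into one row per target subject
#'
#' @param x A `cvep_loso` from [run_loso()].
#' @param ... Unused.
#' @return Tibble with columns `subject`, `accuracy`, `n_test`, `n_selected`,
#'   `selected` (list-column of chosen source ids) and `algorithm`.
#' @export
tidy.cvep_loso <- function(x, ...) {
  out <- x$results
  out$algorithm <- x$config$algorithm
  out
}

#' One-row summary of a LOSO result
#'
#' @param x A `cvep_loso`.
#' @param ... Unused.
#' @return Tibble with `algorithm`, `n_train`, `cycle_multiple`, `n_subjects`,
#'   `mean_accuracy`, `se`, `itr_bits_min`, `selection_time_s`.
#' @export
glance.cvep_loso <- function(x, ...) {
  tibble::tibble(
    algorithm = x$config$algorithm,
    n_train = x$config$n_train,
    cycle_multiple = x$config$cycle_multiple,
    n_subjects = nrow(x$results),
    mean_accuracy = x$mean_accuracy,
    se = x$se,
    itr_bits_min = as.numeric(x$itr_bits_min),
    selection_time_s = x$selection_time_s
  )
}

#' Tidy a TSS selection into one row per source subject
#'
#' @param x A `cvep_tss` from [tss_select()].
#' @param ... Unused.
#' @return Tibble with `source`, `accuracy` (singleton training-set accuracy),
#'   `rank` and `selected`.
#' @export
tidy.cvep_tss <- function(x, ...) {
  out <- x$per_source
  out$selected <- out$source %in% x$selected
  out
}

#' One-row summary of a TSS selection
#'
#' @param x A `cvep_tss`.
#' @param ... Unused.
#' @return Tibble with `n_sources`, `C`, `best_pooled_accuracy`,
#'   `best_singleton_accuracy`.
#' @export
glance.cvep_tss <- function(x, ...) {
  tibble::tibble(
    n_sources = nrow(x$per_source),
    C = x$C,
    best_pooled_accuracy = x$pooled$accuracy[x$C],
    best_singleton_accuracy = max(x$per_source$accuracy)
  )
}
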