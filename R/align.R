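# Log-Euclidean data alignment (LEDA). The reference matrix is the inverse
# square root of the log-Euclidean mean of the trials' sample covariances;
# left-multiplying trials by it whitens each subject's data toward a common
# frame, reducing the cross-subject covariance shift. Supervised alignment
# uses one reference per class; unsupervised alignment (for unlabelled test
# data) uses a single global reference.

#' Fit a LEDA alignment model
#'
#' Computes unshrunk sample covariances of the given trials (with the standard
#' eigenvalue floor), their log-Euclidean mean, and the reference matrix
#' `M_ref = P_LE^{-1/2}`. With `labels` supplied the model is supervised: one
#' reference per class from that class's trials. Without labels it is
#' unsupervised: one global reference from all trials (the batch of test
#' trials, in the decoding pipeline).
#'
#' @param trials Array `[Nc x Nt x n]` (raw trials, or super-trials if
#'   aligning at the super-trial stage).
#' @param labels Optional 1-based class labels; every class present must have
#'   at least one trial.
#' @param n_classes Number of classes for supervised mode.
#' @return A `cvep_leda`: list with `mode` and `references` (list of SPD
#'   matrices; one element named `"global"`, or one per class).
#' @export
leda_fit <- function(trials, labels = NULL, n_classes = if (is.null(labels)) NULL else max(labels)) {
  stopifnot(is.array(trials), length(dim(trials)) == 3)
  n <- dim(trials)[3]
  mean_log_cov <- function(idx) {
    L <- 0
    for (i in idx) L <- L + spd_logm(scm(trials[, , i]), quiet = TRUE)
    L / length(idx)
  }
  if (is.null(labels)) {
    refs <- list(global = spd_expm(-0.5 * mean_log_cov(seq_len(n))))
    mode <- "unsupervised"
  } else {
    stopifnot(length(labels) == n)
    labels <- as.integer(labels)
    counts <- tabulate(labels, nbins = n_classes)
    if (any(counts == 0)) {
      stop("no trials for class(es): ",
           paste(which(counts == 0), collapse = ", "), call. = FALSE)
    }
    refs <- lapply(seq_len(n_classes), function(z) {
      spd_expm(-0.5 * mean_log_cov(which(labels == z)))
    })
    names(refs) <- as.character(seq_len(n_classes))
    mode <- "supervised"
  }
  structure(list(mode = mode, references = refs), class = "cvep_leda")
}

#' Apply a LEDA alignment model to trials
#'
#' Left-multiplies each trial by the (class-specific) reference matrix:
#' `X' = M_ref X`, so the aligned covariance is `M_ref P M_refᵀ`. The
#' supervised mode requires a label per trial.
#'
#' @param model A `cvep_leda` from [leda_fit()].
#' @param trials Matrix `[Nc x Nt]` or array `[Nc x Nt x n]`.
#' @param labels Class labels, required for supervised models.
#' @return Aligned trials with the same shape.
#' @export
leda_apply <- function(model, trials, labels = NULL) {
  stopifnot(inherits(model, "cvep_leda"))
  one <- is.matrix(trials)
  if (one) trials <- array(trials, c(dim(trials), 1))
  n <- dim(trials)[3]
  if (model$mode == "supervised") {
    if (is.null(labels)) stop("supervised alignment requires `labels`", call. = FALSE)
    stopifnot(length(labels) == n)
  }
  dref <- nrow(model$references[[1]])
  if (dim(trials)[1] != dref) {
    stop("trial row count ", dim(trials)[1],
         " does not match the reference dimension ", dref, call. = FALSE)
  }
  out <- trials
  for (i in seq_len(n)) {
    M <- if (model$mode == "supervised") {
      model$references[[as.character(as.integer(labels[i]))]]
    } else {
      model$references$global
    }
    slice <- trials[, , i, drop = FALSE]
    dim(slice) <- dim(slice)[1:2]
    out[, , i] <- M %*% slice
  }
  if (one) drop_third(out) else out
}

#' @export
print.cvep_leda <- function(x, ...) {
  cat(sprintf("<cvep_leda> %s alignment, %d reference matrix/matrices of dimension %d\n",
              x$mode, length(x$references), nrow(x$references[[1]])))
  invisible(x)
}
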