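# Super-trials and their shrunk covariance matrices — the decoder's feature
# objects. A super-trial stacks all Z class templates above one trial, so the
# covariance of the stack embeds the trial-template cross-covariances that
# distinguish the lag-coded classes.

#' Stack class templates above a trial to form a super-trial
#'
#' The result has `Nc * (Z + 1)` rows: template blocks for classes `1..Z` in
#' order, then the trial. Test trials of unknown class use the same
#' construction (the trial block is simply the unlabelled trial).
#'
#' @param templates A `cvep_templates` from [class_templates()].
#' @param trial Matrix `[Nc x Nt]` matching the template dimensions.
#' @return Matrix `[Nc * (Z + 1) x Nt]`.
#' @export
super_trial <- function(templates, trial) {
  stopifnot(inherits(templates, "cvep_templates"), is.matrix(trial))
  tpl <- templates$templates
  if (!all(dim(trial) == dim(tpl)[1:2])) {
    stop("trial shape does not match the templates", call. = FALSE)
  }
  nc <- dim(tpl)[1]; z <- dim(tpl)[3]
  out <- matrix(0, nc * (z + 1), ncol(trial))
  for (k in seq_len(z)) out[((k - 1) * nc + 1):(k * nc), ] <- tpl[, , k]
  out[(z * nc + 1):((z + 1) * nc), ] <- trial
  out
}

#' Shrunk covariance of a super-trial
#'
#' Row-centers the super-trial, forms its sample covariance and applies the
#' configured shrinkage (the analytic intensity is computed from the centered
#' super-trial itself). The result is symmetric positive definite whenever the
#' shrinkage weight is positive, even though the unshrunk matrix is rank
#' deficient when `Nc (Z + 1) > Nt - 1`.
#'
#' @param st Super-trial matrix from [super_trial()].
#' @param shrinkage A [shrinkage_config()].
#' @return Covariance matrix `[Nc(Z+1) x Nc(Z+1)]` with `lambda`/`method`
#'   attributes.
#' @export
super_cov <- function(st, shrinkage = shrinkage_config()) {
  P <- scm(st)
  shrink_cov(P, shrinkage, data = st - rowMeans(st))
}

#' Build a labelled covariance set from trials
#'
#' Convenience constructor for the collection of (shrunk) super-trial
#' covariances of a set of trials under one template set. The matrix
#' logarithms are computed once and stored, since every downstream operation
#' (log-Euclidean means, distances, alignment-free pooling) works in the log
#' domain.
#'
#' @param trials Array `[Nc x Nt x n]`.
#' @param templates A `cvep_templates`.
#' @param labels Optional integer labels (1-based); `NA` for unlabelled sets.
#' @param shrinkage A [shrinkage_config()].
#' @param keep_covs Keep the covariance matrices themselves in addition to
#'   their logarithms (needed for the affine-invariant metric).
#' @return A `cvep_covset`: list with `logs` (`[d x d x n]`), optional `covs`,
#'   `labels`, `d`, `n`.
#' @export
super_cov_set <- function(trials, templates, labels = NULL,
                          shrinkage = shrinkage_config(), keep_covs = TRUE) {
  stopifnot(is.array(trials), length(dim(trials)) == 3)
  n <- dim(trials)[3]
  if (is.null(labels)) labels <- rep(NA_integer_, n)
  stopifnot(length(labels) == n)
  tpl <- templates$templates
  if (!all(dim(trials)[1:2] == dim(tpl)[1:2])) {
    stop("trial shape does not match the templates", call. = FALSE)
  }
  nc <- dim(trials)[1]
  nt <- dim(trials)[2]
  z <- dim(tpl)[3]
  # Template rows of every super-trial are identical, so their Gram blocks
  # are computed once; the per-trial work (trial cross products, shrinkage
  # intensity, matrix logarithm) runs in compiled code.
  Tm <- matrix(aperm(tpl, c(1, 3, 2)), nc * z, nt)  # stacked template rows
  Tm <- Tm - rowMeans(Tm)
  res <- supercov_logs_cpp(
    trials, Tm, shrinkage$method,
    if (is.null(shrinkage$lambda)) -1 else shrinkage$lambda,
    keep_covs, 1e-12)
  out <- new_covset(res$logs, res$covs, as.integer(labels))
  out$lambdas <- as.numeric(res$lambdas)
  out
}

new_covset <- function(logs, covs, labels) {
  structure(list(logs = logs, covs = covs, labels = labels,
                 d = dim(logs)[1], n = dim(logs)[3]),
            class = "cvep_covset")
}

#' Concatenate covariance sets
#'
#' @param ... `cvep_covset` objects of a common dimension.
#' @return A `cvep_covset` holding all covariances in argument order.
#' @export
pool_covsets <- function(...) {
  sets <- list(...)
  sets <- sets[!vapply(sets, is.null, logical(1))]
  stopifnot(length(sets) > 0, all(vapply(sets, inherits, logical(1), "cvep_covset")))
  d <- unique(vapply(sets, function(s) s$d, numeric(1)))
  if (length(d) != 1) stop("covariance sets have mismatched dimensions", call. = FALSE)
  logs <- array(unlist(lapply(sets, function(s) s$logs)), c(d, d, sum(vapply(sets, function(s) s$n, numeric(1)))))
  covs <- NULL
  if (all(vapply(sets, function(s) !is.null(s$covs), logical(1)))) {
    covs <- array(unlist(lapply(sets, function(s) s$covs)), dim(logs))
  }
  new_covset(logs, covs, unlist(lapply(sets, function(s) s$labels)))
}

subset_covset <- function(cs, idx) {
  new_covset(cs$logs[, , idx, drop = FALSE],
             if (is.null(cs$covs)) NULL else cs$covs[, , idx, drop = FALSE],
             cs$labels[idx])
}

#' @export
print.cvep_covset <- function(x, ...) {
  cat(sprintf("<cvep_covset> %d covariance matrices of dimension %d x %d (%s)\n",
              x$n, x$d, x$d,
              if (all(is.na(x$labels))) "unlabelled" else
                paste0(length(unique(x$labels)), " classes")))
  invisible(x)
}
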