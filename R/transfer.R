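# Minimum-distance-to-mean classification on super-trial covariances, and
# training-accuracy-based source-subject selection (TSS).

#' Train a minimum-distance-to-mean (MDM) classifier
#'
#' Computes the log-Euclidean mean of each class's training covariances. At
#' classification time a covariance is assigned to the class with the nearest
#' mean under `metric` — by default the log-Euclidean distance, consistent
#' with the log-Euclidean class means; the affine-invariant distance is
#' selectable (class means are then affine-invariant means).
#'
#' @param covset A `cvep_covset` with labels covering every class `1..Z`.
#' @param metric `"log_euclidean"` or `"affine_invariant"`.
#' @param n_classes Number of classes.
#' @return A `cvep_mdm`: list with `logmeans` (`[d x d x Z]`), `metric`,
#'   `n_classes`, and `means` when the affine-invariant metric is used.
#' @export
mdm_train <- function(covset, metric = c("log_euclidean", "affine_invariant"),
                      n_classes = max(covset$labels, na.rm = TRUE)) {
  metric <- match.arg(metric)
  stopifnot(inherits(covset, "cvep_covset"))
  labels <- covset$labels
  counts <- tabulate(labels, nbins = n_classes)
  if (any(counts == 0)) {
    stop("no training covariances for class(es): ",
         paste(which(counts == 0), collapse = ", "), call. = FALSE)
  }
  d <- covset$d
  logmeans <- array(0, c(d, d, n_classes))
  means <- NULL
  if (metric == "affine_invariant") {
    if (is.null(covset$covs)) {
      stop("affine-invariant MDM needs the covariances; build the covset with keep_covs = TRUE",
           call. = FALSE)
    }
    means <- array(0, c(d, d, n_classes))
    for (z in seq_len(n_classes)) {
      M <- mean_ai(covset$covs[, , which(labels == z), drop = FALSE])
      means[, , z] <- M
      logmeans[, , z] <- spd_logm(M, quiet = TRUE)
    }
  } else {
    flat <- matrix(covset$logs, d * d, covset$n)
    for (z in seq_len(n_classes)) {
      idx <- which(labels == z)
      logmeans[, , z] <- matrix(rowMeans(flat[, idx, drop = FALSE]), d, d)
    }
  }
  structure(list(logmeans = logmeans, means = means, metric = metric,
                 n_classes = n_classes, d = d),
            class = "cvep_mdm")
}

#' Classify covariances with an MDM model
#'
#' @param model A `cvep_mdm`.
#' @param covset A `cvep_covset` of matching dimension.
#' @return List with `labels` (predicted class per covariance; ties broken
#'   toward the smallest class index) and `distances` (`n x Z` matrix).
#' @export
mdm_classify <- function(model, covset) {
  stopifnot(inherits(model, "cvep_mdm"), inherits(covset, "cvep_covset"))
  if (covset$d != model$d) {
    stop("covariance dimension ", covset$d, " does not match the model (", model$d, ")",
         call. = FALSE)
  }
  z <- model$n_classes
  if (model$metric == "log_euclidean") {
    # ||log P - log M_z||_F via the expanded inner product, vectorized.
    A <- matrix(covset$logs, covset$d^2, covset$n)
    B <- matrix(model$logmeans, model$d^2, z)
    d2 <- outer(colSums(A^2), colSums(B^2), `+`) - 2 * crossprod(A, B)
    dist <- sqrt(pmax(d2, 0))
  } else {
    dist <- matrix(0, covset$n, z)
    for (i in seq_len(covset$n)) {
      for (k in seq_len(z)) {
        dist[i, k] <- dist_ai(covset$covs[, , i], model$means[, , k])
      }
    }
  }
  list(labels = max.col(-dist, ties.method = "first"), distances = dist)
}

# Per-class sums of log-covariances, the sufficient statistic for pooled
# log-Euclidean class means.
class_log_sums <- function(covset, n_classes) {
  flat <- matrix(covset$logs, covset$d^2, covset$n)
  sums <- matrix(0, covset$d^2, n_classes)
  counts <- integer(n_classes)
  for (z in seq_len(n_classes)) {
    idx <- which(covset$labels == z)
    counts[z] <- length(idx)
    if (length(idx)) sums[, z] <- rowSums(flat[, idx, drop = FALSE])
  }
  list(sums = sums, counts = counts)
}

# Nearest-log-mean labels for flattened class means B (d^2 x Z); ties go to
# the smallest class index.
le_classify_flat <- function(B, covset) {
  A <- matrix(covset$logs, covset$d^2, covset$n)
  d2 <- outer(colSums(A^2), colSums(B^2), `+`) - 2 * crossprod(A, B)
  max.col(-d2, ties.method = "first")
}

#' Train on one covariance set and report accuracy on another
#'
#' @param train_covset,test_covset Labelled `cvep_covset`s.
#' @param metric Distance metric, as in [mdm_train()].
#' @param n_classes Number of classes.
#' @return Fraction of test covariances classified correctly.
#' @export
train_then_test <- function(train_covset, test_covset,
                            metric = "log_euclidean",
                            n_classes = max(train_covset$labels, na.rm = TRUE)) {
  model <- mdm_train(train_covset, metric = metric, n_classes = n_classes)
  pred <- mdm_classify(model, test_covset)$labels
  mean(pred == test_covset$labels)
}

#' Training-accuracy-based source-subject selection (TSS)
#'
#' Ranks source subjects by the accuracy an MDM classifier trained on that
#' subject's covariances alone achieves on the target subject's training set,
#' then evaluates pooling the top `c` sources for `c = 1..n_sources` and keeps
#' the `C` maximizing pooled training-set accuracy (ties go to the smallest
#' `c`; ranking ties keep the source order stable). By default the pooled
#' models inside the selection loop are trained on source data alone, so the
#' target's training set remains a held-out yardstick; with
#' `pool_target = TRUE` the target's training covariances are pooled in as
#' well, which makes the inner accuracy a partly resubstitution estimate and
#' tends to saturate it.
#'
#' @param source_covsets Named list of labelled `cvep_covset`s, one per source
#'   subject.
#' @param target_train Labelled `cvep_covset` of the target's training data,
#'   covering all classes.
#' @param metric Distance metric.
#' @param n_classes Number of classes.
#' @param pool_target Include the target training set when retraining pooled
#'   models inside the selection loop.
#' @return A `cvep_tss`: list with `per_source` (tibble: source, accuracy,
#'   rank), `pooled` (tibble: c, accuracy), `C`, `selected` (ids of the top-C
#'   sources).
#' @export
tss_select <- function(source_covsets, target_train,
                       metric = "log_euclidean",
                       n_classes = max(target_train$labels, na.rm = TRUE),
                       pool_target = FALSE) {
  stopifnot(is.list(source_covsets), length(source_covsets) >= 1)
  ids <- names(source_covsets)
  if (is.null(ids)) ids <- as.character(seq_along(source_covsets))
  n_src <- length(ids)
  if (metric == "log_euclidean") {
    # Pooled class means are running averages of log-covariances, so the
    # singleton and top-c models come from cumulative per-class sums.
    stats_src <- lapply(source_covsets, class_log_sums, n_classes = n_classes)
    bad <- vapply(stats_src, function(s) any(s$counts == 0), logical(1))
    if (any(bad)) {
      stop("source(s) missing classes: ", paste(ids[bad], collapse = ", "),
           call. = FALSE)
    }
    truth <- target_train$labels
    acc <- vapply(stats_src, function(s) {
      mean(le_classify_flat(s$sums %*% diag(1 / s$counts, n_classes),
                            target_train) == truth)
    }, numeric(1))
    ord <- order(-acc)  # stable: ties keep list order
    tstats <- if (pool_target) class_log_sums(target_train, n_classes)
    cum_sums <- if (pool_target) tstats$sums else matrix(0, target_train$d^2, n_classes)
    cum_counts <- if (pool_target) tstats$counts else integer(n_classes)
    pooled_acc <- numeric(n_src)
    for (c_i in seq_len(n_src)) {
      s <- stats_src[[ord[c_i]]]
      cum_sums <- cum_sums + s$sums
      cum_counts <- cum_counts + s$counts
      pooled_acc[c_i] <- mean(le_classify_flat(
        cum_sums %*% diag(1 / cum_counts, n_classes), target_train) == truth)
    }
  } else {
    acc <- vapply(source_covsets, function(cs) {
      train_then_test(cs, target_train, metric = metric, n_classes = n_classes)
    }, numeric(1))
    ord <- order(-acc)
    pooled_acc <- numeric(n_src)
    for (c_i in seq_len(n_src)) {
      pool <- do.call(pool_covsets, c(unname(source_covsets[ord[seq_len(c_i)]]),
                                      if (pool_target) list(target_train)))
      pooled_acc[c_i] <- train_then_test(pool, target_train, metric = metric,
                                         n_classes = n_classes)
    }
  }
  C <- which.max(pooled_acc)  # ties -> smallest c
  structure(
    list(
      per_source = tibble::tibble(source = ids, accuracy = unname(acc),
                                  rank = match(seq_along(ids), ord)),
      pooled = tibble::tibble(c = seq_along(ids), accuracy = pooled_acc),
      C = C,
      selected = ids[ord[seq_len(C)]],
      pool_target = pool_target
    ),
    class = "cvep_tss"
  )
}

#' Train the pooled transfer MDM model
#'
#' Pools the selected source subjects' covariances with the target's training
#' covariances (every trial weighted equally) and trains an MDM classifier.
#' With an empty selection this reduces to the subject-specific model.
#'
#' @param source_covsets List of labelled `cvep_covset`s (may be empty).
#' @param target_train Labelled `cvep_covset`.
#' @param metric Distance metric.
#' @param n_classes Number of classes.
#' @return A `cvep_mdm`.
#' @export
mdm_train_pooled <- function(source_covsets, target_train,
                             metric = "log_euclidean",
                             n_classes = max(target_train$labels, na.rm = TRUE)) {
  pool <- do.call(pool_covsets, c(unname(source_covsets), list(target_train)))
  mdm_train(pool, metric = metric, n_classes = n_classes)
}

#' @export
print.cvep_tss <- function(x, ...) {
  cat(sprintf("<cvep_tss> selected %d of %d source subjects: %s (pooled training accuracy %.3f)\n",
              x$C, nrow(x$per_source), paste(x$selected, collapse = ", "),
              x$pooled$accuracy[x$C]))
  invisible(x)
}

#' @export
print.cvep_mdm <- function(x, ...) {
  cat(sprintf("<cvep_mdm> %d class means of dimension %d x %d, %s metric\n",
              x$n_classes, x$d, x$d, x$metric))
  invisible(x)
}
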