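# Leave-one-subject-out evaluation of the four decoding pipelines (SSL,
# TL-ASS, TL-LEDA-ASS, TL-LEDA-TSS), the Wolpaw information transfer rate,
# and one-parameter sweeps.

#' Experiment configuration
#'
#' @param algorithm One of `"SSL"` (subject-specific baseline: MDM trained on
#'   the target's own shifted training trials), `"TL-ASS"` (pool all source
#'   subjects, no alignment), `"TL-LEDA-ASS"` (pool all source subjects after
#'   LEDA), `"TL-LEDA-TSS"` (LEDA plus training-accuracy-based source
#'   selection).
#' @param n_train Training trials per class for the target subject (drawn from
#'   the reference-target block and shifted to every class).
#' @param cycle_multiple Data length per trial in stimulus cycles; trials are
#'   truncated to `round(cycle_multiple * fs * period_s)` samples.
#' @param n_channels Number of channels used, taken as a prefix of the channel
#'   order in the dataset; `NULL` means all.
#' @param shrinkage A [shrinkage_config()] for the super-trial covariances.
#' @param alignment_stage `"raw_trials"` (align Nc x Nt trials, then rebuild
#'   templates and super-trials from aligned data — the pipeline's processing
#'   order) or `"super_trials"` (align the stacked super-trials instead).
#' @param metric MDM distance metric.
#' @param filter A [filter_spec()] applied per trial before anything else, or
#'   `NULL` to skip filtering.
#' @param pool_target Pool the target's training covariances inside the TSS
#'   retraining loop (see [tss_select()]).
#' @param source_templates Whose templates enter source subjects' super-trials:
#'   `"target"` (default — the target subject's templates, so pooled source
#'   covariances and the target's test covariances share one template-block
#'   geometry; recomputed per fold) or `"own"` (each source's templates from
#'   its own calibration block, so no target data are needed to process a
#'   source, at the cost of a template-block mismatch between source and
#'   target feature spaces).
#' @param gaze_shift_s Seconds of gaze-shifting time added to the selection
#'   time when computing ITR.
#' @param seed Master seed; when non-`NULL`, each fold's training trials are a
#'   seeded random draw from the reference block instead of the first
#'   `n_train`.
#' @return An object of class `cvep_config`.
#' @export
experiment_config <- function(algorithm = c("SSL", "TL-ASS", "TL-LEDA-ASS",
                                            "TL-LEDA-TSS"),
                              n_train = 20, cycle_multiple = 1,
                              n_channels = NULL,
                              shrinkage = shrinkage_config(),
                              alignment_stage = c("raw_trials", "super_trials"),
                              metric = c("log_euclidean", "affine_invariant"),
                              filter = filter_spec(),
                              pool_target = FALSE,
                              source_templates = c("target", "own"),
                              gaze_shift_s = 1, seed = NULL) {
  algorithm <- match.arg(algorithm)
  alignment_stage <- match.arg(alignment_stage)
  metric <- match.arg(metric)
  source_templates <- match.arg(source_templates)
  stopifnot(n_train >= 1, cycle_multiple > 0)
  structure(list(algorithm = algorithm, n_train = n_train,
                 cycle_multiple = cycle_multiple, n_channels = n_channels,
                 shrinkage = shrinkage, alignment_stage = alignment_stage,
                 metric = metric, filter = filter, pool_target = pool_target,
                 source_templates = source_templates,
                 gaze_shift_s = gaze_shift_s, seed = seed),
            class = "cvep_config")
}

# Channel prefix, data-length truncation and band-pass for one subject.
preprocess_subject <- function(subject, config) {
  trials <- subject$trials
  if (!is.null(config$n_channels)) {
    if (config$n_channels > dim(trials)[1]) {
      stop("n_channels exceeds the channels in the dataset", call. = FALSE)
    }
    trials <- trials[seq_len(config$n_channels), , , drop = FALSE]
  }
  nt_use <- round(config$cycle_multiple * subject$fs * subject$codebook$period_s)
  if (nt_use > dim(trials)[2]) {
    stop(sprintf("cycle_multiple %.2f needs %d samples but trials have %d",
                 config$cycle_multiple, nt_use, dim(trials)[2]), call. = FALSE)
  }
  trials <- trials[, seq_len(nt_use), , drop = FALSE]
  if (!is.null(config$filter)) {
    trials <- bandpass_trials(trials, subject$fs, config$filter)
  }
  subject$trials <- trials
  subject
}

# Class templates of one subject from its reference-target calibration block:
# the mean reference trial, circularly shifted to every class (shifting
# commutes with averaging). Falls back to per-class means of the given
# labelled trials when the subject has no calibration block.
calibration_templates <- function(subject, fallback_trials, fallback_labels) {
  cb <- subject$codebook
  z <- cb$n_targets
  ref_idx <- which(subject$role == "train_reference")
  if (length(ref_idx) == 0) {
    return(class_templates(fallback_trials, fallback_labels, n_classes = z))
  }
  ref <- subject$trials[, , ref_idx, drop = FALSE]
  nc <- dim(ref)[1]; nt <- dim(ref)[2]
  ref_mean <- matrix(rowMeans(matrix(ref, nc * nt, length(ref_idx))), nc, nt)
  tpl <- array(0, c(nc, nt, z))
  for (zz in seq_len(z)) {
    tpl[, , zz] <- shift_trials(ref_mean, cb, zz, subject$fs)
  }
  structure(list(templates = tpl, n_per_class = rep(length(ref_idx), z)),
            class = "cvep_templates")
}

align_templates <- function(model, templates) {
  tpl <- templates$templates
  for (zz in seq_len(dim(tpl)[3])) {
    tpl[, , zz] <- model$references[[as.character(zz)]] %*% tpl[, , zz]
  }
  templates$templates <- tpl
  templates
}

# Labelled transfer features of one source subject: covariances from its test
# block (5 trials per target in the reference setup), optionally LEDA-aligned
# by class. Super-trials use the subject's own templates, built from its
# calibration block so the transferred covariances carry no template
# self-match; `templates` overrides them (the target-template sensitivity
# variant).
source_features <- function(subject, config, aligned, templates = NULL) {
  idx <- which(subject$role == "test")
  trials <- subject$trials[, , idx, drop = FALSE]
  labels <- subject$labels[idx]
  z <- subject$codebook$n_targets
  keep_covs <- config$metric == "affine_invariant"
  if (config$alignment_stage == "raw_trials") {
    if (aligned) {
      model <- leda_fit(trials, labels, n_classes = z)
      trials <- leda_apply(model, trials, labels)
      tpl <- if (is.null(templates)) {
        align_templates(model, calibration_templates(subject, trials, labels))
      } else {
        templates
      }
    } else {
      tpl <- if (is.null(templates)) {
        calibration_templates(subject, trials, labels)
      } else {
        templates
      }
    }
    super_cov_set(trials, tpl, labels, config$shrinkage, keep_covs = keep_covs)
  } else {
    tpl <- if (is.null(templates)) {
      calibration_templates(subject, trials, labels)
    } else {
      templates
    }
    sts <- stack_supertrials(trials, tpl)
    if (aligned) sts <- leda_apply(leda_fit(sts, labels, n_classes = z), sts, labels)
    covset_from_supertrials(sts, labels, config$shrinkage, keep_covs)
  }
}

# Target-subject features: training covariances from the shifted reference
# block (supervised alignment) and test covariances (unsupervised alignment,
# templates from the training data).
target_features <- function(subject, config, aligned, fold_seed = NULL) {
  cb <- subject$codebook
  z <- cb$n_targets
  keep_covs <- config$metric == "affine_invariant"
  ref_idx <- which(subject$role == "train_reference")
  if (length(ref_idx) < config$n_train) {
    stop(sprintf("subject %s has %d reference trials but n_train = %d",
                 subject$subject_id, length(ref_idx), config$n_train),
         call. = FALSE)
  }
  use <- if (is.null(fold_seed)) {
    ref_idx[seq_len(config$n_train)]
  } else {
    withr::with_seed(fold_seed, sort(sample(ref_idx, config$n_train)))
  }
  ref <- subject$trials[, , use, drop = FALSE]
  nc <- dim(ref)[1]; nt <- dim(ref)[2]
  train <- array(0, c(nc, nt, config$n_train * z))
  train_labels <- rep(seq_len(z), each = config$n_train)
  for (zz in seq_len(z)) {
    train[, , ((zz - 1) * config$n_train + 1):(zz * config$n_train)] <-
      shift_trials(ref, cb, zz, subject$fs)
  }
  test_idx <- which(subject$role == "test")
  test <- subject$trials[, , test_idx, drop = FALSE]
  test_labels <- subject$labels[test_idx]

  if (config$alignment_stage == "raw_trials") {
    if (aligned) {
      train <- leda_apply(leda_fit(train, train_labels, n_classes = z),
                          train, train_labels)
      test <- leda_apply(leda_fit(test), test)
    }
    tpl <- class_templates(train, train_labels, n_classes = z)
    list(
      train = super_cov_set(train, tpl, train_labels, config$shrinkage, keep_covs),
      test = super_cov_set(test, tpl, test_labels, config$shrinkage, keep_covs),
      templates = tpl
    )
  } else {
    tpl <- class_templates(train, train_labels, n_classes = z)
    st_train <- stack_supertrials(train, tpl)
    st_test <- stack_supertrials(test, tpl)
    if (aligned) {
      st_train <- leda_apply(leda_fit(st_train, train_labels, n_classes = z),
                             st_train, train_labels)
      st_test <- leda_apply(leda_fit(st_test), st_test)
    }
    list(
      train = covset_from_supertrials(st_train, train_labels, config$shrinkage, keep_covs),
      test = covset_from_supertrials(st_test, test_labels, config$shrinkage, keep_covs),
      templates = tpl
    )
  }
}

stack_supertrials <- function(trials, templates) {
  n <- dim(trials)[3]
  z <- dim(templates$templates)[3]
  d <- dim(trials)[1] * (z + 1)
  out <- array(0, c(d, dim(trials)[2], n))
  for (i in seq_len(n)) out[, , i] <- super_trial(templates, trials[, , i])
  out
}

covset_from_supertrials <- function(sts, labels, shrinkage, keep_covs) {
  n <- dim(sts)[3]
  d <- dim(sts)[1]
  logs <- array(0, c(d, d, n))
  covs <- if (keep_covs) array(0, c(d, d, n)) else NULL
  for (i in seq_len(n)) {
    P <- shrink_cov(scm(sts[, , i]), shrinkage,
                    data = sts[, , i] - rowMeans(sts[, , i]))
    logs[, , i] <- spd_logm(P, quiet = TRUE)
    if (keep_covs) covs[, , i] <- P
  }
  new_covset(logs, covs, as.integer(labels))
}

#' Leave-one-subject-out evaluation of a decoding pipeline
#'
#' Each subject acts once as the target; the rest are sources. Per fold the
#' harness preprocesses (channel prefix, data-length truncation, band-pass),
#' shifts the target's reference-target training trials to all classes, aligns
#' with LEDA where the algorithm calls for it (supervised by class for
#' training/source data, unsupervised for the target's test batch), builds
#' templates and super-trial covariances with the configured shrinkage, runs
#' TSS when configured, trains the pooled MDM model and classifies the
#' target's test trials. A fold that fails is recorded with `NA` accuracy and
#' a diagnostic message rather than aborting the run.
#'
#' @param dataset A `cvep_dataset` with at least 2 subjects.
#' @param config An [experiment_config()].
#' @return A `cvep_loso`: list with `results` (tibble: subject, accuracy,
#'   n_test, n_selected, selected), `config`, `mean_accuracy`, `se`,
#'   `itr_bits_min` (from the mean accuracy at this data length), and
#'   `selection_time_s`.
#' @export
run_loso <- function(dataset, config = experiment_config()) {
  run_loso_suite(dataset, config, algorithms = config$algorithm)[[1]]
}

#' @rdname run_loso
#' @param algorithms Character vector of algorithms to evaluate on shared
#'   preprocessing and features (`run_loso_suite`). Feature computation — the
#'   dominant cost — is done once per alignment variant and reused across
#'   algorithms, so comparing all four pipelines costs little more than
#'   running one.
#' @return `run_loso_suite()` returns a named list of `cvep_loso`, one per
#'   algorithm.
#' @export
run_loso_suite <- function(dataset, config = experiment_config(),
                           algorithms = c("SSL", "TL-ASS", "TL-LEDA-ASS",
                                          "TL-LEDA-TSS")) {
  stopifnot(inherits(dataset, "cvep_dataset"))
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  subjects <- dataset$subjects
  if (length(subjects) < 2) stop("LOSO needs at least 2 subjects", call. = FALSE)
  n_sub <- length(subjects)
  z <- dataset$codebook$n_targets
  need_al <- any(algorithms %in% c("TL-LEDA-ASS", "TL-LEDA-TSS"))
  need_un <- any(algorithms %in% c("SSL", "TL-ASS"))

  pre <- lapply(subjects, preprocess_subject, config = config)
  ids <- vapply(pre, function(s) s$subject_id, character(1))
  own_tpl <- config$source_templates == "own"
  src_al <- src_un <- NULL
  if (own_tpl && need_al) {
    src_al <- lapply(pre, source_features, config = config, aligned = TRUE)
    names(src_al) <- ids
  }
  if (own_tpl && "TL-ASS" %in% algorithms) {
    src_un <- lapply(pre, source_features, config = config, aligned = FALSE)
    names(src_un) <- ids
  }

  rows <- stats::setNames(
    replicate(length(algorithms), vector("list", n_sub), simplify = FALSE),
    algorithms)
  for (i in seq_len(n_sub)) {
    id <- ids[i]
    fold_seed <- if (is.null(config$seed)) NULL else
      (config$seed + 104729L * i) %% .Machine$integer.max
    tf_al <- if (need_al)
      target_features(pre[[i]], config, aligned = TRUE, fold_seed = fold_seed)
    tf_un <- if (need_un)
      target_features(pre[[i]], config, aligned = FALSE, fold_seed = fold_seed)
    if (!own_tpl) {
      if (need_al) {
        src_al <- stats::setNames(lapply(pre, source_features, config = config,
                                         aligned = TRUE,
                                         templates = tf_al$templates), ids)
      }
      if ("TL-ASS" %in% algorithms) {
        src_un <- stats::setNames(lapply(pre, source_features, config = config,
                                         aligned = FALSE,
                                         templates = tf_un$templates), ids)
      }
    }
    for (algo in algorithms) {
      rows[[algo]][[i]] <- tryCatch({
        sel <- character(0)
        tf <- if (algo %in% c("SSL", "TL-ASS")) tf_un else tf_al
        model <- switch(algo,
          "SSL" = mdm_train(tf$train, metric = config$metric, n_classes = z),
          "TL-ASS" = {
            sel <- ids[-i]
            mdm_train_pooled(src_un[-i], tf$train, metric = config$metric,
                             n_classes = z)
          },
          "TL-LEDA-ASS" = {
            sel <- ids[-i]
            mdm_train_pooled(src_al[-i], tf$train, metric = config$metric,
                             n_classes = z)
          },
          "TL-LEDA-TSS" = {
            tss <- tss_select(src_al[-i], tf$train, metric = config$metric,
                              n_classes = z, pool_target = config$pool_target)
            sel <- tss$selected
            mdm_train_pooled(src_al[sel], tf$train, metric = config$metric,
                             n_classes = z)
          })
        pred <- mdm_classify(model, tf$test)$labels
        tibble::tibble(subject = id,
                       accuracy = mean(pred == tf$test$labels),
                       n_test = tf$test$n,
                       n_selected = length(sel),
                       selected = list(sel))
      }, error = function(e) {
        message(sprintf("fold %s (%s) failed: %s", id, algo, conditionMessage(e)))
        tibble::tibble(subject = id, accuracy = NA_real_, n_test = NA_integer_,
                       n_selected = NA_integer_, selected = list(character(0)))
      })
    }
  }
  t_sel <- config$cycle_multiple * dataset$codebook$period_s + config$gaze_shift_s
  out <- lapply(algorithms, function(algo) {
    results <- dplyr::bind_rows(rows[[algo]])
    acc <- results$accuracy[!is.na(results$accuracy)]
    cfg <- config
    cfg$algorithm <- algo
    structure(
      list(results = results, config = cfg,
           mean_accuracy = mean(acc),
           se = stats::sd(acc) / sqrt(length(acc)),
           itr_bits_min = itr(z, mean(acc), t_sel),
           selection_time_s = t_sel,
           n_targets = z),
      class = "cvep_loso"
    )
  })
  stats::setNames(out, algorithms)
}

#' Wolpaw information transfer rate
#'
#' `ITR = (log2 M + P log2 P + (1 - P) log2((1 - P)/(M - 1))) * 60 / T`
#' bits/minute, with `x log2 x = 0` at `x = 0`. The selection time `T`
#' includes gaze-shifting. Accuracies at or below chance give a non-positive
#' bracket; the returned rate is clamped at 0 with the raw value kept in the
#' `"raw"` attribute.
#'
#' @param M Number of targets (>= 2).
#' @param P Classification accuracy in `[0, 1]`.
#' @param T_s Seconds per selection (> 0).
#' @return Bits per minute.
#' @examples
#' itr(16, 1, 2.05)  # 4 * 60 / 2.05
#' @export
itr <- function(M, P, T_s) {
  stopifnot(M >= 2, T_s > 0)
  if (P < 0 || P > 1) stop("accuracy P must lie in [0, 1]", call. = FALSE)
  xlog2 <- function(x) ifelse(x > 0, x * log2(x), 0)
  bits <- log2(M) + xlog2(P) + ifelse(P < 1, (1 - P) * log2((1 - P) / (M - 1)), 0)
  raw <- bits * 60 / T_s
  out <- max(raw, 0)
  attr(out, "raw") <- raw
  out
}

#' Sweep one experiment parameter across a grid
#'
#' Runs [run_loso()] once per value of `parameter`, holding everything else in
#' `config` fixed (shared seed policy), and returns one summary row per value.
#'
#' @param dataset A `cvep_dataset`.
#' @param config Base [experiment_config()].
#' @param parameter `"cycle_multiple"`, `"n_channels"` or `"n_train"`.
#' @param values Grid of parameter values (nonempty).
#' @return A `cvep_sweep` tibble: one row per value with the summary columns
#'   of [glance.cvep_loso()] plus `parameter`/`value`; per-subject results are
#'   kept in the `fold_results` list-column.
#' @export
sweep_loso <- function(dataset, config, parameter = c("cycle_multiple",
                                                      "n_channels", "n_train"),
                       values) {
  parameter <- match.arg(parameter)
  stopifnot(length(values) >= 1)
  rows <- lapply(values, function(v) {
    cfg <- config
    cfg[[parameter]] <- v
    res <- run_loso(dataset, cfg)
    out <- glance(res)
    out$parameter <- parameter
    out$value <- v
    out$fold_results <- list(res$results)
    out
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cvep_sweep", class(out))
  out
}

#' Paired comparison of two LOSO runs
#'
#' Two-sided paired t-test across subjects of the per-fold accuracies of two
#' runs on the same dataset (no multiple-testing correction, matching the
#' single-comparison reporting convention of the evaluation design).
#'
#' @param a,b `cvep_loso` results on the same subjects.
#' @return One-row tibble: the two algorithms, mean accuracies, mean paired
#'   difference, t statistic, p value.
#' @export
compare_loso <- function(a, b) {
  stopifnot(inherits(a, "cvep_loso"), inherits(b, "cvep_loso"),
            identical(a$results$subject, b$results$subject))
  tt <- tryCatch(
    stats::t.test(a$results$accuracy, b$results$accuracy, paired = TRUE),
    error = function(e) NULL  # constant differences: no test statistic
  )
  tibble::tibble(
    algorithm_a = a$config$algorithm, algorithm_b = b$config$algorithm,
    mean_a = a$mean_accuracy, mean_b = b$mean_accuracy,
    mean_diff = mean(a$results$accuracy - b$results$accuracy, na.rm = TRUE),
    statistic = if (is.null(tt)) NA_real_ else unname(tt$statistic),
    p_value = if (is.null(tt)) NA_real_ else tt$p.value
  )
}

#' @export
print.cvep_loso <- function(x, ...) {
  cat(sprintf("<cvep_loso> %s: mean accuracy %.3f (SE %.3f) over %d subjects, ITR %.1f bits/min\n",
              x$config$algorithm, x$mean_accuracy, x$se, nrow(x$results),
              x$itr_bits_min))
  invisible(x)
}
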