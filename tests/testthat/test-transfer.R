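# MDM classification and training-accuracy-based subject selection.

# Covariance sets built directly from SPD matrices.
covset_of <- function(mats, labels) {
  d <- nrow(mats[[1]])
  logs <- array(0, c(d, d, length(mats)))
  covs <- array(0, c(d, d, length(mats)))
  for (i in seq_along(mats)) {
    covs[, , i] <- mats[[i]]
    logs[, , i] <- spd_logm(mats[[i]], quiet = TRUE)
  }
  cvepriem:::new_covset(logs, covs, as.integer(labels))
}

test_that("MDM class means and nearest-mean assignment on toy cases", {
  cs <- covset_of(list(diag(2), 4 * diag(2)), c(1, 2))
  model <- mdm_train(cs)
  expect_equal(model$logmeans[, , 1], spd_logm(diag(2)))
  expect_equal(model$logmeans[, , 2], spd_logm(4 * diag(2)))
  # a covariance equal to a class mean is assigned there with distance 0
  out <- mdm_classify(model, covset_of(list(4 * diag(2)), NA))
  expect_identical(out$labels, 2L)
  expect_equal(out$distances[1, 2], 0)
  # 1.5 I is closer to I than to 4I in log space
  out2 <- mdm_classify(model, covset_of(list(1.5 * diag(2)), NA))
  expect_identical(out2$labels, 1L)
  # duplicating the training set leaves the model unchanged
  model2 <- mdm_train(covset_of(list(diag(2), diag(2), 4 * diag(2),
                                     4 * diag(2)), c(1, 1, 2, 2)))
  expect_equal(model2$logmeans, model$logmeans)
  expect_error(mdm_train(covset_of(list(diag(2)), 1), n_classes = 2), "2")
})

test_that("classification equals brute-force nearest mean", {
  set.seed(61)
  train <- covset_of(lapply(1:12, function(i) rand_spd(4)),
                     rep(1:4, each = 3))
  test <- covset_of(lapply(1:6, function(i) rand_spd(4)), rep(NA, 6))
  for (metric in c("log_euclidean", "affine_invariant")) {
    model <- mdm_train(train, metric = metric)
    got <- mdm_classify(model, test)$labels
    meanmats <- lapply(1:4, function(z) {
      if (metric == "log_euclidean") {
        mean_le(lapply(which(train$labels == z), function(i) train$covs[, , i]))
      } else {
        mean_ai(lapply(which(train$labels == z), function(i) train$covs[, , i]))
      }
    })
    dfun <- if (metric == "log_euclidean") dist_le else dist_ai
    want <- vapply(1:6, function(i) {
      which.min(vapply(meanmats, dfun, numeric(1), P1 = test$covs[, , i]))
    }, integer(1))
    expect_identical(got, want)
  }
})

test_that("classification is congruence-invariant", {
  set.seed(62)
  train <- covset_of(lapply(1:9, function(i) rand_spd(4)), rep(1:3, each = 3))
  test <- covset_of(lapply(1:5, function(i) rand_spd(4)), rep(NA, 5))
  transform_cs <- function(cs, U) {
    covset_of(lapply(seq_len(cs$n), function(i) U %*% cs$covs[, , i] %*% t(U)),
              cs$labels)
  }
  # log-Euclidean: orthogonal congruence
  Q <- rand_orth(4)
  m1 <- mdm_train(train); m2 <- mdm_train(transform_cs(train, Q))
  expect_identical(mdm_classify(m2, transform_cs(test, Q))$labels,
                   mdm_classify(m1, test)$labels)
  # affine-invariant: any invertible congruence
  U <- matrix(rnorm(16), 4)
  m3 <- mdm_train(train, metric = "affine_invariant")
  m4 <- mdm_train(transform_cs(train, U), metric = "affine_invariant")
  expect_identical(mdm_classify(m4, transform_cs(test, U))$labels,
                   mdm_classify(m3, test)$labels)
})

test_that("train_then_test scores exactly", {
  cs <- covset_of(list(diag(3), 5 * diag(3)), c(1, 2))
  expect_equal(train_then_test(cs, cs), 1)
  one <- covset_of(list(1.2 * diag(3)), 1)
  expect_true(train_then_test(cs, one) %in% c(0, 1))
})

test_that("TSS ranks, pools and breaks ties as specified", {
  set.seed(63)
  target <- covset_of(lapply(rep(c(1, 9), 3), function(v) v * rand_spd(3) / 3 + v * diag(3)),
                      rep(1:2, 3))
  # identical sources: flat pooled accuracy, so the tie rule gives C = 1
  good <- covset_of(list(diag(3), 9 * diag(3)), c(1, 2))
  tss <- tss_select(list(a = good, b = good, c = good), target)
  expect_identical(tss$C, 1L)
  expect_identical(tss$selected, "a")  # stable tie-break by list order
  expect_true(all(tss$pooled$accuracy == tss$pooled$accuracy[1]))
  # single candidate is always selected
  tss1 <- tss_select(list(only = good), target)
  expect_identical(tss1$C, 1L)
  expect_identical(tss1$selected, "only")
  # the selected pool never scores below the c = 1 pool (argmax construction)
  expect_gte(tss$pooled$accuracy[tss$C], tss$pooled$accuracy[1])
})

test_that("a same-cluster source outranks pure-noise sources", {
  cb <- tiny_codebook()
  good_model <- subject_model(noise_sd = 3, n_channels = 3, fs = 300)
  noise_model <- subject_model(noise_sd = 3, mixing = rep(0, 3),
                               n_channels = 3, fs = 300)
  target <- simulate_subject(good_model, cb, n_train = 6,
                             n_test_per_target = 3, fs = 300, seed = 1)
  srcs <- list(
    good = simulate_subject(good_model, cb, n_train = 0,
                            n_test_per_target = 3, fs = 300, seed = 2),
    noise1 = simulate_subject(noise_model, cb, n_train = 0,
                              n_test_per_target = 3, fs = 300, seed = 3),
    noise2 = simulate_subject(noise_model, cb, n_train = 0,
                              n_test_per_target = 3, fs = 300, seed = 4)
  )
  # target training features: shifted reference trials, own templates
  ref <- target$trials[, , target$role == "train_reference"]
  train <- array(0, c(3, 150, 6 * 4))
  for (z in 1:4) train[, , ((z - 1) * 6 + 1):(z * 6)] <-
    shift_trials(ref, cb, z, fs = 300)
  tlab <- rep(1:4, each = 6)
  tpl <- class_templates(train, tlab)
  target_train <- super_cov_set(train, tpl, tlab)
  src_sets <- lapply(srcs, function(s) {
    idx <- which(s$role == "test")
    super_cov_set(s$trials[, , idx], tpl, s$labels[idx])
  })
  tss <- tss_select(src_sets, target_train, n_classes = 4)
  expect_identical(tss$per_source$rank[tss$per_source$source == "good"], 1L)
  expect_identical(tss$selected[1], "good")
})

test_that("pooled transfer models reduce and permute correctly", {
  set.seed(64)
  target <- covset_of(lapply(1:4, function(i) rand_spd(3)), c(1, 2, 1, 2))
  s1 <- covset_of(lapply(1:4, function(i) rand_spd(3)), c(1, 2, 1, 2))
  s2 <- covset_of(lapply(1:4, function(i) rand_spd(3)), c(1, 2, 1, 2))
  # empty selection: the pooled model is the subject-specific model
  m0 <- mdm_train_pooled(list(), target)
  expect_equal(m0$logmeans, mdm_train(target)$logmeans)
  # pooling order does not matter
  m12 <- mdm_train_pooled(list(s1, s2), target)
  m21 <- mdm_train_pooled(list(s2, s1), target)
  expect_equal(m12$logmeans, m21$logmeans)
})

test_that("tidiers expose the selection table", {
  set.seed(65)
  target <- covset_of(lapply(1:4, function(i) rand_spd(3)), c(1, 2, 1, 2))
  srcs <- list(a = covset_of(lapply(1:2, function(i) rand_spd(3)), c(1, 2)),
               b = covset_of(lapply(1:2, function(i) rand_spd(3)), c(1, 2)))
  tss <- tss_select(srcs, target)
  td <- tidy(tss)
  expect_s3_class(td, "tbl_df")
  expect_setequal(td$source, c("a", "b"))
  expect_identical(sum(td$selected), tss$C)
  g <- glance(tss)
  expect_identical(g$n_sources, 2L)
  expect_equal(g$best_pooled_accuracy, max(tss$pooled$accuracy))
})
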