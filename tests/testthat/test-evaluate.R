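# LOSO harness, ITR and sweeps (small 4-target geometry).

test_that("zero-noise LOSO decodes perfectly with one training trial", {
  ds <- tiny_population(n_subjects = 2, snr_range = c(Inf, Inf), seed = 2,
                        n_train = 2)
  res <- run_loso(ds, experiment_config("SSL", n_train = 1))
  expect_true(all(res$results$accuracy == 1))
  expect_equal(res$mean_accuracy, 1)
})

test_that("run_loso is deterministic given data and config", {
  ds <- tiny_population(n_subjects = 3, seed = 4)
  cfg <- experiment_config("TL-LEDA-TSS", n_train = 3)
  r1 <- run_loso(ds, cfg)
  r2 <- run_loso(ds, cfg)
  expect_identical(r1$results$accuracy, r2$results$accuracy)
  expect_identical(r1$results$selected, r2$results$selected)
  # seeded training-trial subsampling is reproducible too
  cfg_s <- experiment_config("SSL", n_train = 3, seed = 99)
  expect_identical(run_loso(ds, cfg_s)$results$accuracy,
                   run_loso(ds, cfg_s)$results$accuracy)
})

test_that("TSS with a single source reduces to all-source transfer", {
  ds <- tiny_population(n_subjects = 2, seed = 6)
  cfg <- function(a) experiment_config(a, n_train = 3)
  res <- run_loso_suite(ds, cfg("SSL"),
                        algorithms = c("TL-LEDA-ASS", "TL-LEDA-TSS"))
  expect_identical(res[["TL-LEDA-TSS"]]$results$accuracy,
                   res[["TL-LEDA-ASS"]]$results$accuracy)
  expect_true(all(res[["TL-LEDA-TSS"]]$results$n_selected == 1))
})

test_that("ITR closed forms, limits and monotonicity", {
  expect_equal(as.numeric(itr(16, 1, 2.05)), 4 * 60 / 2.05)
  expect_equal(as.numeric(itr(16, 1 / 16, 2.05)), 0)
  expect_equal(as.numeric(itr(16, 1 / 16, 10)), 0)
  # independent evaluation of the rate formula at P = 0.9
  p <- 0.9; M <- 16
  bits <- log2(M) + p * log2(p) + (1 - p) * log2((1 - p) / (M - 1))
  expect_equal(as.numeric(itr(16, 0.9, 2.05)), bits * 60 / 2.05)
  # P = 0 is a defined limit (x log x -> 0)
  expect_equal(attr(itr(2, 0, 1), "raw"), 60)  # log2(2) + 0 + 1*log2(1/1) = 1
  expect_error(itr(16, 1.2, 2), "\\[0, 1\\]")
  # strictly increasing in P above chance, strictly decreasing in T
  ps <- seq(1 / 16 + 0.01, 1, length.out = 25)
  vals <- vapply(ps, function(p) as.numeric(itr(16, p, 2.05)), numeric(1))
  expect_true(all(diff(vals) > 0))
  ts <- seq(1.05, 4.15, by = 0.25)
  vals_t <- vapply(ts, function(tt) as.numeric(itr(16, 0.9, tt)), numeric(1))
  expect_true(all(diff(vals_t) < 0))
})

test_that("sweeps run one LOSO per value and echo the config", {
  ds <- tiny_population(n_subjects = 2, seed = 8, cycle_multiple = 2,
                        snr_range = c(0.4, 0.4))
  sw <- sweep_loso(ds, experiment_config("SSL", n_train = 2),
                   parameter = "n_train", values = c(1, 3))
  expect_identical(nrow(sw), 2L)
  expect_identical(sw$value, c(1, 3))
  expect_identical(sw$n_train, c(1, 3))
  expect_identical(sw$parameter, rep("n_train", 2))
  expect_s3_class(sw$fold_results[[1]], "tbl_df")
  # data-length sweep: ITR at one cycle exceeds ITR at two cycles here
  # (accuracy is near ceiling at this SNR, so the shorter selection wins)
  sw2 <- sweep_loso(ds, experiment_config("SSL", n_train = 3),
                    parameter = "cycle_multiple", values = c(1, 2))
  expect_gt(sw2$itr_bits_min[1], sw2$itr_bits_min[2])
  # channel-count sweep takes channel prefixes
  sw3 <- sweep_loso(ds, experiment_config("SSL", n_train = 2),
                    parameter = "n_channels", values = c(2, 3))
  expect_identical(nrow(sw3), 2L)
})

test_that("label-shuffled evaluation sits at chance", {
  cb <- tiny_codebook()
  ds <- tiny_population(n_subjects = 3, seed = 12, n_test_per_target = 8,
                        n_train = 3)
  hits <- 0; n <- 0
  for (k in seq_along(ds$subjects)) {
    s <- ds$subjects[[k]]
    n_train <- 3
    ref <- s$trials[, , which(s$role == "train_reference")[1:n_train],
                    drop = FALSE]
    z <- cb$n_targets
    train <- array(0, c(dim(ref)[1], dim(ref)[2], n_train * z))
    for (zz in seq_len(z)) {
      train[, , ((zz - 1) * n_train + 1):(zz * n_train)] <-
        shift_trials(ref, cb, zz, s$fs)
    }
    tl <- rep(seq_len(z), each = n_train)
    tpl <- class_templates(train, tl)
    test_idx <- which(s$role == "test")
    pred <- mdm_classify(
      mdm_train(super_cov_set(train, tpl, tl), n_classes = z),
      super_cov_set(s$trials[, , test_idx], tpl)
    )$labels
    shuffled <- withr::with_seed(77 + k, sample(s$labels[test_idx]))
    hits <- hits + sum(pred == shuffled)
    n <- n + length(pred)
  }
  p0 <- 1 / 4
  band <- 2.58 * sqrt(p0 * (1 - p0) / n)
  expect_lt(abs(hits / n - p0), band)
})

test_that("result objects tidy, glance, compare and plot", {
  ds <- tiny_population(n_subjects = 2, seed = 14)
  a <- run_loso(ds, experiment_config("SSL", n_train = 2))
  b <- run_loso(ds, experiment_config("TL-ASS", n_train = 2))
  td <- tidy(a)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), 2L)
  expect_identical(td$algorithm, rep("SSL", 2))
  g <- glance(a)
  expect_identical(g$n_subjects, 2L)
  expect_equal(g$mean_accuracy, mean(td$accuracy))
  cmp <- compare_loso(a, b)
  expect_identical(cmp$algorithm_a, "SSL")
  expect_true(is.na(cmp$p_value) || (cmp$p_value >= 0 && cmp$p_value <= 1))
  expect_s3_class(autoplot(a), "ggplot")
  sw <- sweep_loso(ds, experiment_config("SSL", n_train = 2),
                   parameter = "n_train", values = c(1, 2))
  expect_s3_class(autoplot(sw), "ggplot")
})

test_that("super-trial-stage alignment is a working configuration", {
  ds <- tiny_population(n_subjects = 2, seed = 16)
  res <- run_loso(ds, experiment_config("TL-LEDA-ASS", n_train = 2,
                                        alignment_stage = "super_trials"))
  expect_true(all(res$results$accuracy >= 0 & res$results$accuracy <= 1))
  expect_false(any(is.na(res$results$accuracy)))
})
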