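# SPD geometry: sample covariance, matrix functions, distances, means,
# shrinkage.

test_that("scm is the centered sample covariance", {
  expect_equal(scm(matrix(c(1, -1), 1)), matrix(2, 1, 1), ignore_attr = TRUE)
  X <- matrix(rnorm(5 * 30), 5)
  P <- scm(X)
  expect_equal(P, t(P))
  expect_true(all(eigen(P, symmetric = TRUE, only.values = TRUE)$values > -1e-12))
  expect_equal(P, stats::cov(t(X)), ignore_attr = TRUE)
  # rank deficiency is flagged when channels exceed samples - 1
  expect_true(isTRUE(attr(scm(matrix(rnorm(6 * 4), 6)), "rank_deficient")))
  expect_error(scm(matrix(1, 3, 1)), "at least 2")
})

test_that("matrix functions invert each other and invsqrt whitens", {
  expect_equal(spd_invsqrt(diag(3)), diag(3))
  expect_equal(spd_invsqrt(4 * diag(2)), 0.5 * diag(2))
  set.seed(11)
  for (i in 1:5) {
    P <- rand_spd(6)
    M <- spd_invsqrt(P)
    expect_lt(max(abs(M %*% P %*% M - diag(6))), 1e-8)
    expect_lt(max(abs(spd_expm(spd_logm(P)) - P)), 1e-8)
  }
})

test_that("closed-form distance identities hold", {
  expect_equal(dist_ai(diag(3), 2 * diag(3)), sqrt(3) * log(2))
  expect_equal(dist_le(diag(c(1, exp(2))), diag(2)), 2)
  P <- rand_spd(4)
  expect_equal(dist_ai(P, P), 0)
  expect_equal(dist_le(P, P), 0)
  # commuting (diagonal) pairs: the two metrics agree
  D1 <- diag(c(1, 3, 7)); D2 <- diag(c(2, 5, 0.3))
  expect_equal(dist_ai(D1, D2), dist_le(D1, D2))
  expect_error(dist_ai(diag(c(1, -1)), diag(2)), "symmetric|positive")
})

test_that("distances are metrics on random triples", {
  set.seed(21)
  for (i in 1:20) {
    A <- rand_spd(4); B <- rand_spd(4); C <- rand_spd(4)
    for (d in list(dist_ai, dist_le)) {
      expect_gte(d(A, B), 0)
      expect_equal(d(A, B), d(B, A))
      expect_lte(d(A, C), d(A, B) + d(B, C) + 1e-10)
    }
  }
})

test_that("congruence invariance holds per metric", {
  set.seed(31)
  for (i in 1:10) {
    P1 <- rand_spd(5); P2 <- rand_spd(5)
    U <- matrix(rnorm(25), 5)  # generic invertible
    expect_equal(dist_ai(U %*% P1 %*% t(U), U %*% P2 %*% t(U)),
                 dist_ai(P1, P2), tolerance = 1e-8)
    Q <- rand_orth(5)
    expect_equal(dist_le(Q %*% P1 %*% t(Q), Q %*% P2 %*% t(Q)),
                 dist_le(P1, P2), tolerance = 1e-8)
  }
})

test_that("log-Euclidean mean is the closed-form minimizer", {
  expect_equal(mean_le(list(diag(c(1, 4)), diag(c(4, 1)))), diag(c(2, 2)))
  P <- rand_spd(3)
  expect_equal(mean_le(list(P)), P)
  # objective at the mean is below 100 random perturbations
  set.seed(41)
  mats <- lapply(1:5, function(i) rand_spd(3))
  M <- mean_le(mats)
  f0 <- sum(vapply(mats, function(P) dist_le(P, M)^2, numeric(1)))
  for (i in 1:100) {
    E <- matrix(rnorm(9, sd = 0.05), 3); E <- (E + t(E)) / 2
    Mp <- spd_expm(spd_logm(M) + E)
    fp <- sum(vapply(mats, function(P) dist_le(P, Mp)^2, numeric(1)))
    expect_gte(fp, f0)
  }
})

test_that("affine-invariant mean: closed forms and stationarity", {
  P <- rand_spd(4)
  expect_equal(mean_ai(list(P, P)), P, tolerance = 1e-9)
  expect_equal(mean_ai(list(diag(c(1, 4)), diag(c(4, 1)))), diag(c(2, 2)),
               tolerance = 1e-9)
  # N = 2: geodesic midpoint closed form
  set.seed(51)
  P1 <- rand_spd(3); P2 <- rand_spd(3)
  iS <- spd_invsqrt(P1); S <- spd_sqrtm(P1)
  expect_equal(mean_ai(list(P1, P2)),
               S %*% spd_sqrtm(iS %*% P2 %*% iS) %*% S, tolerance = 1e-9)
  # N = 3: Karcher stationarity, gradient norm below tolerance
  mats <- lapply(1:3, function(i) rand_spd(3))
  M <- mean_ai(mats)
  iS <- spd_invsqrt(M)
  G <- Reduce(`+`, lapply(mats, function(P) spd_logm(iS %*% P %*% iS))) / 3
  expect_lt(sqrt(sum(G^2)), 1e-9)
  # commuting family: agrees with the log-Euclidean mean
  dmats <- list(diag(c(1, 2, 8)), diag(c(4, 1, 2)), diag(c(2, 4, 1)))
  expect_equal(mean_ai(dmats), mean_le(dmats), tolerance = 1e-8)
  expect_error(mean_le(list()), "nonempty")
})

test_that("shrinkage endpoints, hand example and SPD guarantee", {
  P <- diag(c(1, 3))
  expect_equal(shrink_cov(P, shrinkage_config("blankertz", lambda = 0)), P,
               ignore_attr = TRUE)
  expect_equal(shrink_cov(P, shrinkage_config("blankertz", lambda = 1)),
               2 * diag(2), ignore_attr = TRUE)
  expect_equal(shrink_cov(P, shrinkage_config("blankertz", lambda = 0.5)),
               diag(c(1.5, 2.5)), ignore_attr = TRUE)
  # the printed Ledoit-Wolf target scales with the full trace
  expect_equal(shrink_cov(P, shrinkage_config("ledoit_wolf", lambda = 0.5)),
               0.5 * (4 * diag(2)) + 0.5 * P, ignore_attr = TRUE)
  # rank-deficient input becomes SPD under the analytic diagonal target
  X <- matrix(rnorm(6 * 4), 6)
  P6 <- scm(X)
  S <- shrink_cov(P6, shrinkage_config("schafer_strimmer"),
                  data = X - rowMeans(X))
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  expect_gt(attr(S, "lambda"), 0)
  expect_lte(attr(S, "lambda"), 1)
  # eigenvalues bounded below by lambda * min eigenvalue of the target
  S2 <- shrink_cov(P6, shrinkage_config("schafer_strimmer", lambda = 0.3))
  ev2 <- eigen(S2, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev2), 0.3 * min(diag(P6)) - 1e-12)
  expect_error(shrink_cov(P, shrinkage_config("schafer_strimmer")), "data")
  expect_error(shrinkage_config(lambda = 1.5), "\\[0, 1\\]")
})
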