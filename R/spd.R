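# Symmetric positive definite (SPD) matrix algebra: matrix functions,
# Riemannian distances and means, sample covariance and shrinkage estimation.

.spd_sym_tol <- 1e-10

assert_spd_input <- function(P, arg = "P") {
  if (!is.matrix(P) || nrow(P) != ncol(P) || !is.numeric(P)) {
    stop(sprintf("`%s` must be a square numeric matrix", arg), call. = FALSE)
  }
  rel <- max(abs(P - t(P))) / max(max(abs(P)), .Machine$double.eps)
  if (rel > .spd_sym_tol) {
    stop(sprintf("`%s` is not symmetric (relative asymmetry %.3g)", arg, rel),
         call. = FALSE)
  }
  invisible(P)
}

# Eigendecomposition with an eigenvalue floor at 1e-12 * largest eigenvalue.
# Near-singular inputs are regularized at the floor; every such event is
# reported via a message so it is visible in logs.
spd_eigen <- function(P, floor_rel = 1e-12, quiet = FALSE) {
  assert_spd_input(P)
  e <- eigen((P + t(P)) / 2, symmetric = TRUE)
  lmax <- max(e$values)
  if (lmax <= 0) {
    stop("matrix has no positive eigenvalue; not positive definite", call. = FALSE)
  }
  if (min(e$values) < -1e-8 * lmax) {
    stop(sprintf(
      "matrix is not positive semi-definite (smallest eigenvalue %.3g)",
      min(e$values)), call. = FALSE)
  }
  floor_abs <- floor_rel * lmax
  n_floored <- sum(e$values < floor_abs)
  if (n_floored > 0) {
    if (!quiet) {
      message(sprintf("regularized %d eigenvalue(s) below floor %.3g", n_floored, floor_abs))
    }
    e$values <- pmax(e$values, floor_abs)
  }
  e
}

spd_fun <- function(P, f, floor_rel = 1e-12, quiet = FALSE) {
  e <- spd_eigen(P, floor_rel = floor_rel, quiet = quiet)
  M <- e$vectors %*% (f(e$values) * t(e$vectors))
  (M + t(M)) / 2
}

#' Matrix logarithm, exponential and inverse square root of an SPD matrix
#'
#' Matrix functions computed through the eigendecomposition of a symmetric
#' positive definite matrix. Eigenvalues below `1e-12` times the largest
#' eigenvalue are floored there (with a message), so nearly singular
#' covariance estimates can still be mapped through `log`.
#'
#' @param P Symmetric positive definite matrix.
#' @param quiet Suppress the message emitted when eigenvalues are floored.
#' @return A symmetric matrix of the same dimension.
#' @examples
#' P <- diag(c(1, 4))
#' spd_logm(P)
#' spd_invsqrt(P)  # diag(1, 0.5)
#' @export
spd_logm <- function(P, quiet = FALSE) spd_fun(P, log, quiet = quiet)

#' @rdname spd_logm
#' @param S Symmetric matrix (a tangent-space element).
#' @export
spd_expm <- function(S) {
  assert_spd_input(S, "S")
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  M <- e$vectors %*% (exp(e$values) * t(e$vectors))
  (M + t(M)) / 2
}

#' @rdname spd_logm
#' @export
spd_invsqrt <- function(P, quiet = FALSE) spd_fun(P, function(l) 1 / sqrt(l), quiet = quiet)

#' @rdname spd_logm
#' @export
spd_sqrtm <- function(P, quiet = FALSE) spd_fun(P, sqrt, quiet = quiet)

#' Sample covariance matrix of a multichannel trial
#'
#' Computes `X Xᵀ / (Nt - 1)` after subtracting each channel's mean, where
#' rows of `X` are channels and columns are time samples. The per-row mean is
#' removed even though band-passed EEG is already near zero mean, so the
#' estimator is an exact sample covariance. When there are fewer samples than
#' channels the result is rank deficient; it is still returned (flagged via
#' the `"rank_deficient"` attribute) and should be shrunk before use on the
#' SPD manifold.
#'
#' @param X Numeric matrix, channels x samples, with at least 2 samples.
#' @return Symmetric positive semi-definite matrix, channels x channels.
#' @examples
#' scm(matrix(c(1, -1), 1))  # variance 2
#' @export
scm <- function(X) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  nt <- ncol(X)
  if (nt < 2) stop("need at least 2 time samples to estimate a covariance", call. = FALSE)
  Xc <- X - rowMeans(X)
  P <- tcrossprod(Xc) / (nt - 1)
  P <- (P + t(P)) / 2
  if (nrow(X) > nt - 1) attr(P, "rank_deficient") <- TRUE
  P
}

#' Shrinkage configuration for covariance estimation
#'
#' Shrinkage replaces a sample covariance `P` by `lambda * Gamma +
#' (1 - lambda) * P`, pulling it toward a well-conditioned target `Gamma`.
#' Three targets are supported:
#' \describe{
#'   \item{`ledoit_wolf`}{`Gamma = tr(P) I`.}
#'   \item{`blankertz`}{`Gamma = (tr(P)/n) I` (the average eigenvalue).}
#'   \item{`schafer_strimmer`}{`Gamma = diag(P)` — the diagonal,
#'     unequal-variance target; off-diagonals are shrunk toward zero. This is
#'     the default, matching the estimator used for super-trial covariances.}
#' }
#' When `lambda` is `NULL` the analytic intensity is used: the ratio of the
#' summed estimated variances of the covariance entries to the summed squared
#' deviations from the target (off-diagonal entries only for the
#' `schafer_strimmer` target), clipped to `[0, 1]`. A fixed `lambda` may be
#' any value in `[0, 1]`; `lambda = 0` returns `P` unchanged and `lambda = 1`
#' returns the target.
#'
#' @param method One of `"schafer_strimmer"`, `"ledoit_wolf"`, `"blankertz"`,
#'   `"none"`.
#' @param lambda Optional fixed shrinkage weight in `[0, 1]`, overriding the
#'   analytic choice.
#' @return An object of class `shrinkage_config`.
#' @export
shrinkage_config <- function(method = c("schafer_strimmer", "ledoit_wolf",
                                        "blankertz", "none"),
                             lambda = NULL) {
  method <- match.arg(method)
  if (!is.null(lambda)) {
    stopifnot(is.numeric(lambda), length(lambda) == 1)
    if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]", call. = FALSE)
  }
  structure(list(method = method, lambda = lambda), class = "shrinkage_config")
}

shrink_target <- function(P, method) {
  n <- nrow(P)
  switch(method,
    ledoit_wolf = diag(sum(diag(P)), n),
    blankertz = diag(sum(diag(P)) / n, n),
    schafer_strimmer = diag(diag(P), n),
    stop("no shrinkage target for method ", method, call. = FALSE)
  )
}

# Analytic shrinkage intensity: var-hat(s_ij) summed over the shrunk entries,
# divided by the summed squared distance of those entries from the target.
# Xc is the row-centered data matrix used to form P.
shrink_lambda_analytic <- function(P, Xc, method) {
  nt <- ncol(Xc)
  W2 <- tcrossprod(Xc^2)              # sum_k w_kij^2 with w_kij = x_ki x_kj
  wbar <- tcrossprod(Xc) / nt
  var_s <- nt / (nt - 1)^3 * (W2 - nt * wbar^2)
  Gamma <- shrink_target(P, method)
  D2 <- (P - Gamma)^2
  if (method == "schafer_strimmer") {
    off <- !diag(nrow(P))
    num <- sum(var_s[off]); den <- sum(P[off]^2)
  } else {
    num <- sum(var_s); den <- sum(D2)
  }
  if (den <= 0) return(0)
  min(1, max(0, num / den))
}

#' Shrink a covariance matrix toward a structured target
#'
#' @param P Symmetric positive semi-definite matrix (e.g. from [scm()]).
#' @param config A [shrinkage_config()].
#' @param data Optional row-centered data matrix (channels x samples) from
#'   which `P` was estimated; required to compute the analytic shrinkage
#'   intensity when `config$lambda` is `NULL`.
#' @return The shrunk matrix, with attributes `lambda` and `method` recording
#'   what was applied. With any `lambda > 0` the result is symmetric positive
#'   definite even when `P` is rank deficient (the targets are positive
#'   definite and shrinkage is a convex combination).
#' @examples
#' shrink_cov(diag(c(1, 3)), shrinkage_config("blankertz", lambda = 0.5))
#' # diag(1.5, 2.5): target is 2 I
#' @export
shrink_cov <- function(P, config = shrinkage_config(), data = NULL) {
  assert_spd_input(P)
  if (config$method == "none") {
    attr(P, "lambda") <- 0; attr(P, "method") <- "none"
    return(P)
  }
  lambda <- config$lambda
  if (is.null(lambda)) {
    if (is.null(data)) {
      stop("analytic shrinkage intensity needs `data` (the centered data matrix); ",
           "supply it or set a fixed lambda", call. = FALSE)
    }
    lambda <- shrink_lambda_analytic(P, data, config$method)
  }
  Gamma <- shrink_target(P, config$method)
  out <- lambda * Gamma + (1 - lambda) * P
  attr(out, "lambda") <- lambda
  attr(out, "method") <- config$method
  attr(out, "rank_deficient") <- NULL
  out
}

#' Riemannian distances between SPD matrices
#'
#' `dist_ai()` is the affine-invariant distance
#' `sqrt(sum(log^2 eigenvalues(P1^{-1} P2)))`, invariant under congruence by
#' any invertible matrix. `dist_le()` is the log-Euclidean distance, the
#' Frobenius norm of `log(P1) - log(P2)`, invariant under orthogonal
#' congruence (and under any congruence for commuting pairs).
#'
#' @param P1,P2 Symmetric positive definite matrices of equal dimension.
#' @return Non-negative scalar distance.
#' @examples
#' dist_ai(diag(3), 2 * diag(3))  # sqrt(3) * log(2)
#' dist_le(diag(c(1, exp(2))), diag(2))  # 2
#' @export
dist_ai <- function(P1, P2) {
  assert_spd_input(P1, "P1"); assert_spd_input(P2, "P2")
  if (!all(dim(P1) == dim(P2))) stop("dimension mismatch", call. = FALSE)
  iS <- spd_invsqrt(P1, quiet = TRUE)
  ev <- eigen(iS %*% P2 %*% iS, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("P2 is not positive definite relative to P1", call. = FALSE)
  sqrt(sum(log(ev)^2))
}

#' @rdname dist_ai
#' @export
dist_le <- function(P1, P2) {
  assert_spd_input(P1, "P1"); assert_spd_input(P2, "P2")
  if (!all(dim(P1) == dim(P2))) stop("dimension mismatch", call. = FALSE)
  sqrt(sum((spd_logm(P1, quiet = TRUE) - spd_logm(P2, quiet = TRUE))^2))
}

as_spd_list <- function(mats) {
  if (is.array(mats) && length(dim(mats)) == 3) {
    mats <- lapply(seq_len(dim(mats)[3]), function(i) mats[, , i])
  }
  if (is.matrix(mats)) mats <- list(mats)
  if (!is.list(mats) || length(mats) == 0) {
    stop("need a nonempty list (or 3-d array) of SPD matrices", call. = FALSE)
  }
  dims <- vapply(mats, dim, integer(2))
  if (any(dims != dims[, 1])) {
    stop("matrices must share a common dimension", call. = FALSE)
  }
  mats
}

#' Riemannian means of SPD matrices
#'
#' `mean_le()` is the log-Euclidean mean `exp(mean(log(P_i)))`, the closed-form
#' minimizer of the summed squared log-Euclidean distances. `mean_ai()` is the
#' affine-invariant (geometric) mean: the geodesic midpoint
#' `P1^{1/2} (P1^{-1/2} P2 P1^{-1/2})^{1/2} P1^{1/2}` for two matrices, and a
#' fixed-point iteration on the manifold for more, run until the Frobenius norm
#' of the Riemannian gradient falls below `tol`.
#'
#' @param mats List of SPD matrices (or a 3-d array with matrices in the third
#'   dimension).
#' @param tol Convergence tolerance on the gradient norm (`mean_ai`).
#' @param max_iter Maximum fixed-point iterations (`mean_ai`).
#' @return An SPD matrix.
#' @examples
#' mean_le(list(diag(c(1, 4)), diag(c(4, 1))))  # diag(2, 2)
#' @export
mean_le <- function(mats) {
  mats <- as_spd_list(mats)
  L <- Reduce(`+`, lapply(mats, spd_logm, quiet = TRUE)) / length(mats)
  spd_expm(L)
}

#' @rdname mean_le
#' @export
mean_ai <- function(mats, tol = 1e-9, max_iter = 100) {
  mats <- as_spd_list(mats)
  N <- length(mats)
  if (N == 1) return(mats[[1]])
  if (N == 2) {
    iS <- spd_invsqrt(mats[[1]], quiet = TRUE)
    S <- spd_sqrtm(mats[[1]], quiet = TRUE)
    return(S %*% spd_sqrtm(iS %*% mats[[2]] %*% iS, quiet = TRUE) %*% S)
  }
  M <- mean_le(mats)
  for (it in seq_len(max_iter)) {
    iS <- spd_invsqrt(M, quiet = TRUE)
    S <- spd_sqrtm(M, quiet = TRUE)
    G <- Reduce(`+`, lapply(mats, function(P) spd_logm(iS %*% P %*% iS, quiet = TRUE))) / N
    gnorm <- sqrt(sum(G^2))
    if (gnorm < tol) return(M)
    M <- S %*% spd_expm(G) %*% S
    M <- (M + t(M)) / 2
  }
  stop(sprintf(
    "affine-invariant mean did not converge in %d iterations (gradient norm %.3g)",
    max_iter, gnorm), call. = FALSE)
}
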