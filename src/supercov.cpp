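// Batch construction of shrunk super-trial covariances and their matrix
// logarithms. The template rows of every super-trial in a set are identical,
// so their Gram blocks are computed once; per trial only the trial rows'
// cross products are formed. This is the decoding pipeline's hot loop.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static mat sym_logm_floored(const mat& S, double floor_rel) {
  vec eval;
  mat evec;
  eig_sym(eval, evec, 0.5 * (S + S.t()), "dc");
  double lmax = eval.max();
  if (lmax <= 0.0) {
    Rcpp::stop("matrix has no positive eigenvalue; not positive definite");
  }
  eval = clamp(eval, floor_rel * lmax, datum::inf);
  mat L = evec * diagmat(log(eval)) * evec.t();
  return 0.5 * (L + L.t());
}

static mat shrink_target_cpp(const mat& P, const std::string& method) {
  const uword d = P.n_rows;
  if (method == "ledoit_wolf") return eye(d, d) * trace(P);
  if (method == "blankertz") return eye(d, d) * (trace(P) / double(d));
  return diagmat(P.diag());  // schafer_strimmer
}

// trials: nc x nt x n cube; Tm: centered stacked template rows (dt x nt).
// method: none / schafer_strimmer / ledoit_wolf / blankertz.
// fixed_lambda < 0 requests the analytic intensity.
// [[Rcpp::export]]
Rcpp::List supercov_logs_cpp(const arma::cube& trials, const arma::mat& Tm,
                             const std::string method, const double fixed_lambda,
                             const bool keep_covs, const double floor_rel) {
  const uword nc = trials.n_rows, nt = trials.n_cols, n = trials.n_slices;
  const uword dt = Tm.n_rows, d = dt + nc;
  if (Tm.n_cols != nt) Rcpp::stop("template and trial lengths differ");
  if (nt < 2) Rcpp::stop("need at least 2 time samples");
  const double ntm1 = double(nt - 1);

  const mat TT = Tm * Tm.t();
  const mat T2m = square(Tm);
  const bool analytic = (method != "none") && (fixed_lambda < 0.0);
  const bool fast_ss = analytic && method == "schafer_strimmer";
  double sumW2_tpl = 0.0, sumG2_tpl = 0.0;
  mat T2;
  if (analytic) {
    T2 = T2m * T2m.t();
    sumW2_tpl = accu(T2) - trace(T2);
    sumG2_tpl = accu(square(TT)) - accu(square(TT.diag()));
  }

  cube logs(d, d, n);
  cube covs;
  if (keep_covs) covs.set_size(d, d, n);
  vec lambdas(n, fill::zeros);

  mat P(d, d, fill::zeros);
  P.submat(0, 0, dt - 1, dt - 1) = TT / ntm1;

  for (uword i = 0; i < n; ++i) {
    mat X = trials.slice(i);
    X.each_col() -= mean(X, 1);
    const mat cross = X * Tm.t();
    const mat XX = X * X.t();
    P.submat(dt, 0, d - 1, dt - 1) = cross / ntm1;
    P.submat(0, dt, dt - 1, d - 1) = cross.t() / ntm1;
    P.submat(dt, dt, d - 1, d - 1) = XX / ntm1;

    double lambda = 0.0;
    mat Ps;
    if (method == "none") {
      Ps = P;
    } else if (fixed_lambda >= 0.0) {
      lambda = fixed_lambda;
      Ps = lambda * shrink_target_cpp(P, method) + (1.0 - lambda) * P;
    } else if (fast_ss) {
      const mat X2 = square(X);
      const mat cross2 = X2 * T2m.t();
      const mat XX2 = X2 * X2.t();
      const double sumW2_off =
          sumW2_tpl + 2.0 * accu(cross2) + accu(XX2) - trace(XX2);
      const double sumP2_off =
          (sumG2_tpl + 2.0 * accu(square(cross)) + accu(square(XX)) -
           accu(square(XX.diag()))) / (ntm1 * ntm1);
      const double num = double(nt) / std::pow(ntm1, 3) *
          (sumW2_off - ntm1 * ntm1 / double(nt) * sumP2_off);
      lambda = (sumP2_off <= 0.0)
          ? 0.0 : std::min(1.0, std::max(0.0, num / sumP2_off));
      Ps = (1.0 - lambda) * P;
      Ps.diag() = P.diag();
    } else {
      // Analytic intensity for identity-scaled targets needs the full
      // entrywise second-moment matrix.
      const mat Xc = join_cols(Tm, X);
      const mat X2c = square(Xc);
      const mat W2 = X2c * X2c.t();
      const mat wbar = Xc * Xc.t() / double(nt);
      const mat var_s =
          double(nt) / std::pow(ntm1, 3) * (W2 - double(nt) * square(wbar));
      const mat Gamma = shrink_target_cpp(P, method);
      const double num = accu(var_s);
      const double den = accu(square(P - Gamma));
      lambda = (den <= 0.0) ? 0.0 : std::min(1.0, std::max(0.0, num / den));
      Ps = lambda * Gamma + (1.0 - lambda) * P;
    }
    lambdas(i) = lambda;
    logs.slice(i) = sym_logm_floored(Ps, floor_rel);
    if (keep_covs) covs.slice(i) = Ps;
  }
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("logs") = logs,
      Rcpp::Named("lambdas") = lambdas);
  if (keep_covs) out["covs"] = covs;
  return out;
}
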