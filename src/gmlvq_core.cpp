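#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

constexpr double kEps = 1e-12;

struct EvalResult {
  double cost = 0.0;
  arma::vec mu, dp, dm;
  arma::mat gradW, gradOmega;
};

// GLVQ relative-distance cost (and gradients) under the angular
// dissimilarity d = (1 - cos)/2 on omega-transformed vectors.
// Returns false when a transformed sample or prototype is degenerate
// (near-zero norm) and `may_fail` allows reporting it.
bool eval_cost_grad(const arma::mat& W, const arma::mat& omega,
                    const arma::mat& X, const arma::ivec& y_idx,
                    const arma::ivec& proto_class, const bool gradients,
                    EvalResult& out, std::string& err) {
  const arma::uword n = X.n_rows, K = W.n_rows;
  arma::mat U = X * omega.t();
  arma::mat V = W * omega.t();
  arma::vec nu = arma::sqrt(arma::sum(arma::square(U), 1));
  arma::vec nv = arma::sqrt(arma::sum(arma::square(V), 1));
  if (nu.min() < kEps) {
    err = "degenerate sample(s): zero norm after relevance transform";
    return false;
  }
  if (nv.min() < kEps) {
    err = "degenerate prototype: zero norm after relevance transform";
    return false;
  }

  arma::mat C = U * V.t();
  C.each_col() /= nu;
  C.each_row() /= nv.t();
  C = arma::clamp(C, -1.0, 1.0);
  arma::mat D = (1.0 - C) / 2.0;

  out.dp.set_size(n);
  out.dm.set_size(n);
  out.mu.set_size(n);
  arma::uvec jp(n), jm(n);
  for (arma::uword i = 0; i < n; ++i) {
    double bp = arma::datum::inf, bm = arma::datum::inf;
    arma::uword ip = 0, im = 0;
    for (arma::uword k = 0; k < K; ++k) {
      const double d = D(i, k);
      if (proto_class[k] == y_idx[i]) {
        if (d < bp) { bp = d; ip = k; }
      } else {
        if (d < bm) { bm = d; im = k; }
      }
    }
    out.dp[i] = bp; out.dm[i] = bm; jp[i] = ip; jm[i] = im;
    const double dd = bp + bm;
    out.mu[i] = dd > kEps ? (bp - bm) / dd : 0.0;
  }
  out.cost = arma::accu(out.mu);
  if (!gradients) return true;

  // dcost/dcos lands only on the two winning prototypes of each sample;
  // the -1/2 factor from d(d)/d(cos) is folded in.
  arma::mat G(n, K, arma::fill::zeros);
  for (arma::uword i = 0; i < n; ++i) {
    const double dd = out.dp[i] + out.dm[i];
    if (dd <= kEps) continue;
    const double dd2 = dd * dd;
    G(i, jp[i]) += -out.dm[i] / dd2;
    G(i, jm[i]) += out.dp[i] / dd2;
  }

  arma::mat Gn = G;
  Gn.each_col() /= nu;
  arma::mat gradV(K, U.n_cols, arma::fill::zeros);
  out.gradOmega.zeros(omega.n_rows, omega.n_cols);
  arma::rowvec sGC = arma::sum(G % C, 0);
  for (arma::uword k = 0; k < K; ++k) {
    const arma::vec a_k = U.t() * Gn.col(k) / nv[k];
    const double b_k = sGC[k] / (nv[k] * nv[k]);
    gradV.row(k) = (a_k - b_k * V.row(k).t()).t();
    const arma::vec xg_k = X.t() * Gn.col(k);
    out.gradOmega += V.row(k).t() * xg_k.t() / nv[k]
                   + a_k * W.row(k)
                   - b_k * (V.row(k).t() * W.row(k));
  }
  arma::vec h = arma::sum(G % C, 1) / arma::square(nu);
  arma::mat Uh = U;
  Uh.each_col() %= h;
  out.gradOmega -= Uh.t() * X;
  out.gradW = gradV * omega;
  return true;
}

}  // namespace

// [[Rcpp::export]]
List gmlvq_cost_grad_cpp(const arma::mat& W, const arma::mat& omega,
                         const arma::mat& X, const arma::ivec& y_idx,
                         const arma::ivec& proto_class,
                         const bool gradients) {
  EvalResult out;
  std::string err;
  if (!eval_cost_grad(W, omega, X, y_idx, proto_class, gradients, out, err))
    stop(err);
  NumericVector mu(out.mu.begin(), out.mu.end());
  NumericVector dp(out.dp.begin(), out.dp.end());
  NumericVector dm(out.dm.begin(), out.dm.end());
  if (!gradients) {
    return List::create(_["cost"] = out.cost, _["mu"] = mu,
                        _["dp"] = dp, _["dm"] = dm);
  }
  return List::create(_["cost"] = out.cost, _["mu"] = mu,
                      _["dp"] = dp, _["dm"] = dm,
                      _["gradW"] = out.gradW,
                      _["gradOmega"] = out.gradOmega);
}

// Full-batch gradient descent with backtracking step halving; omega is
// rescaled to unit Frobenius norm (trace(Lambda) = 1) after every trial
// update. Accepted costs are non-increasing by construction.
// [[Rcpp::export]]
List gmlvq_fit_loop_cpp(arma::mat W, arma::mat omega, const arma::mat& X,
                        const arma::ivec& y_idx,
                        const arma::ivec& proto_class,
                        const int max_iter, const double tol,
                        const double eta_w, const double eta_o,
                        const int max_halvings) {
  EvalResult eg;
  std::string err;
  if (!eval_cost_grad(W, omega, X, y_idx, proto_class, true, eg, err))
    stop(err);
  double cost = eg.cost;
  std::vector<double> history;
  history.reserve(max_iter + 1);
  history.push_back(cost);
  double step = 1.0;
  bool converged = false;

  EvalResult eg_try;
  for (int iter = 0; iter < max_iter; ++iter) {
    bool accepted = false;
    double s = step;
    for (int h = 0; h <= max_halvings; ++h) {
      s = step / std::pow(2.0, h);
      arma::mat W_try = W - s * eta_w * eg.gradW;
      arma::mat O_try = omega - s * eta_o * eg.gradOmega;
      O_try /= arma::norm(O_try, "fro");
      if (!eval_cost_grad(W_try, O_try, X, y_idx, proto_class, true,
                          eg_try, err))
        continue;
      if (eg_try.cost <= cost) {
        W = W_try;
        omega = O_try;
        accepted = true;
        break;
      }
    }
    if (!accepted) {
      converged = true;
      break;
    }
    const double delta = cost - eg_try.cost;
    eg = eg_try;
    cost = eg.cost;
    history.push_back(cost);
    step = std::min(std::max(s * 1.2, 1e-6), 4.0);
    if (delta < tol) {
      converged = true;
      break;
    }
  }

  return List::create(_["W"] = W, _["omega"] = omega,
                      _["training_history"] = history,
                      _["converged"] = converged);
}
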