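// EM core for the piecewise growth mixture model.
//
// Model per subject i and class k: y_i ~ N(Lambda_o mu_k,
// psi * J + theta * I) on the observed coordinates o. Latent variables
// in the EM are the class membership and the subject intercept
// deviation b_i ~ N(0, psi); both E and M steps are closed-form.
// Subjects are grouped by missingness pattern so all per-subject work
// is dense linear algebra per block.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct PatternBlock {
  arma::mat y;        // n_p x t_o
  arma::mat lambda;   // t_o x 3
  arma::mat ltl;      // 3 x 3
  arma::vec ysum;     // n_p
  arma::vec yss;      // n_p
  int t_o;
};

// rs and rss (n_p x K) of residuals y - lambda * mu per class.
void resid_stats(const PatternBlock& pb, const arma::mat& mu,
                 arma::mat& rs, arma::mat& rss) {
  arma::mat means = pb.lambda * mu;                 // t_o x K
  arma::mat cross = pb.y * means;                   // n_p x K
  arma::rowvec msum = arma::sum(means, 0);
  arma::rowvec mss = arma::sum(arma::square(means), 0);
  rs = arma::repmat(pb.ysum, 1, mu.n_cols);
  rs.each_row() -= msum;
  rss = -2.0 * cross;
  rss.each_col() += pb.yss;
  rss.each_row() += mss;
}

}  // namespace

// One EM run from a single start. Returns the fitted parameters, the
// observed-data log-likelihood path, and flags for convergence and
// class-weight degeneracy (weight below floor_w aborts the start).
// [[Rcpp::export]]
List em_one_cpp(List patterns, arma::vec pi0, arma::mat mu0, double psi0,
                double theta0, int max_iter, double tol, double floor_w) {
  const int n_pat = patterns.size();
  std::vector<PatternBlock> blocks(n_pat);
  int n = 0;
  double total_t = 0.0;
  for (int j = 0; j < n_pat; ++j) {
    List p = patterns[j];
    PatternBlock& pb = blocks[j];
    pb.y = as<arma::mat>(p["y"]);
    pb.lambda = as<arma::mat>(p["lambda"]);
    pb.ltl = as<arma::mat>(p["ltl"]);
    pb.ysum = arma::sum(pb.y, 1);
    pb.yss = arma::sum(arma::square(pb.y), 1);
    pb.t_o = pb.lambda.n_rows;
    n += pb.y.n_rows;
    total_t += static_cast<double>(pb.t_o) * pb.y.n_rows;
  }

  const int K = pi0.n_elem;
  const double log2pi = std::log(2.0 * M_PI);
  arma::vec pi_k = pi0;
  arma::mat mu = mu0;
  double psi = std::max(psi0, 1e-8);
  double theta = std::max(theta0, 1e-8);

  std::vector<double> ll_path;
  double ll_old = -arma::datum::inf;
  double ll = ll_old;
  bool converged = false;
  bool degenerate = false;
  int iter = 0;

  std::vector<arma::mat> post(n_pat), m_ik(n_pat), rs_l(n_pat),
      rss_l(n_pat);
  std::vector<double> v_l(n_pat);

  while (iter < max_iter) {
    ++iter;
    // E-step: per-pattern log-densities, posteriors, total LL
    ll = 0.0;
    arma::vec pi_acc(K, arma::fill::zeros);
    for (int j = 0; j < n_pat; ++j) {
      PatternBlock& pb = blocks[j];
      resid_stats(pb, mu, rs_l[j], rss_l[j]);
      const double denom = theta + psi * pb.t_o;
      arma::mat quad = (rss_l[j] - (psi / denom) * arma::square(rs_l[j]))
                       / theta;
      arma::mat logw = -0.5 * (pb.t_o * log2pi +
                               (pb.t_o - 1) * std::log(theta) +
                               std::log(denom) + quad);
      logw.each_row() += arma::log(pi_k).t();
      arma::vec m = arma::max(logw, 1);
      logw.each_col() -= m;
      arma::mat w = arma::exp(logw);
      arma::vec rsum = arma::sum(w, 1);
      ll += arma::accu(m + arma::log(rsum));
      w.each_col() /= rsum;
      post[j] = w;
      pi_acc += arma::sum(w, 0).t();
    }
    ll_path.push_back(ll);

    arma::vec pi_new = pi_acc / n;
    if (pi_new.min() < floor_w) {
      degenerate = true;
      break;
    }
    if (std::isfinite(ll_old) &&
        std::fabs(ll - ll_old) <= tol * (std::fabs(ll_old) + 1e-10)) {
      converged = true;
      break;
    }
    if (iter >= max_iter) break;
    ll_old = ll;

    // M-step: E[b_i | y, class], then mu / psi update
    double psi_acc = 0.0;
    std::vector<arma::mat> a_k(K, arma::mat(3, 3, arma::fill::zeros));
    arma::mat b_k(3, K, arma::fill::zeros);
    for (int j = 0; j < n_pat; ++j) {
      PatternBlock& pb = blocks[j];
      const double v_p = 1.0 / (1.0 / psi + pb.t_o / theta);
      v_l[j] = v_p;
      m_ik[j] = (v_p / theta) * rs_l[j];
      const arma::mat& w = post[j];
      arma::rowvec w_tot = arma::sum(w, 0);
      psi_acc += arma::accu(w % arma::square(m_ik[j])) +
                 v_p * arma::accu(w_tot);
      for (int k = 0; k < K; ++k) {
        a_k[k] += w_tot(k) * pb.ltl;
        arma::vec yw = pb.y.t() * w.col(k);
        yw -= arma::accu(w.col(k) % m_ik[j].col(k));
        b_k.col(k) += pb.lambda.t() * yw;
      }
    }
    arma::mat mu_new(3, K);
    bool solve_ok = true;
    for (int k = 0; k < K; ++k) {
      arma::vec sol;
      if (!arma::solve(sol, a_k[k], b_k.col(k))) { solve_ok = false; break; }
      mu_new.col(k) = sol;
    }
    if (!solve_ok) { degenerate = true; break; }
    double psi_new = std::max(psi_acc / n, 1e-10);

    // theta update with the refreshed class means
    double theta_acc = 0.0;
    for (int j = 0; j < n_pat; ++j) {
      PatternBlock& pb = blocks[j];
      arma::mat rs2, rss2;
      resid_stats(pb, mu_new, rs2, rss2);
      arma::mat term = rss2 - 2.0 * (m_ik[j] % rs2) +
                       pb.t_o * (arma::square(m_ik[j]) + v_l[j]);
      theta_acc += arma::accu(post[j] % term);
    }
    double theta_new = std::max(theta_acc / total_t, 1e-10);

    pi_k = pi_new;
    mu = mu_new;
    psi = psi_new;
    theta = theta_new;
  }

  return List::create(
      _["pi"] = pi_k, _["mu"] = mu, _["psi"] = psi, _["theta"] = theta,
      _["loglik"] = ll, _["iter"] = iter, _["converged"] = converged,
      _["degenerate"] = degenerate,
      _["ll_path"] = NumericVector(ll_path.begin(), ll_path.end()));
}
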