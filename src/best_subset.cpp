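// Exact best-subset search under Mallow's Cp.
//
// Works on the centred (and internally column-standardized) Gram system so
// the intercept is implicit:
//   RSS(S) = y'y - g_S' G_SS^{-1} g_S,  Cp(S) = RSS(S)/s2 + 2(|S|+1) - n.
// Branch-and-bound over include/exclude decisions on a sweep-operator
// tableau (O(k^2) per pivot). Two valid lower bounds on the RSS increase of
// dropping m free variables are combined:
//   * order statistic: any dropped set contains a variable whose single-drop
//     cost is >= the m-th smallest cost, and dropping a superset can only
//     raise RSS further;
//   * spectral: the increase beta_D' (Ainv_DD)^{-1} beta_D is at least
//     lambda_min(G) * sum_{j in D} beta_j^2 by eigenvalue interlacing.
// Ties in Cp resolve toward the smaller, then lexicographically earlier,
// subset.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

namespace {

struct Problem {
  arma::mat G;
  arma::vec g;
  double yy;
  int n;
  int k;
  int maxf;
  double s2;
  double eps;
  double lam_min;  // smallest eigenvalue of G
};

struct Incumbent {
  bool set = false;
  double cp = 0.0;
  std::vector<int> sel;  // sorted 0-based indices
};

bool lex_less(const std::vector<int>& a, const std::vector<int>& b) {
  std::size_t m = std::min(a.size(), b.size());
  for (std::size_t i = 0; i < m; ++i) {
    if (a[i] != b[i]) return a[i] < b[i];
  }
  return a.size() < b.size();
}

double subset_rss(const Problem& pb, const std::vector<int>& S) {
  if (S.empty()) return pb.yy;
  arma::uvec idx(S.size());
  for (std::size_t i = 0; i < S.size(); ++i) idx[i] = S[i];
  arma::mat Gs = pb.G.submat(idx, idx);
  arma::vec gs = pb.g.elem(idx);
  arma::vec b;
  bool ok = arma::solve(b, Gs, gs,
                        arma::solve_opts::likely_sympd + arma::solve_opts::no_approx);
  if (!ok) b = arma::pinv(Gs) * gs;
  double r = pb.yy - arma::dot(gs, b);
  return r < 0.0 ? 0.0 : r;
}

inline double cp_value(const Problem& pb, double rss, int n_feat) {
  return rss / pb.s2 + 2.0 * (n_feat + 1) - pb.n;
}

// exact RSS is recomputed before an incumbent update so sweep round-off
// never contaminates the reported optimum; the sort is deferred until the
// candidate is actually competitive
void consider(const Problem& pb, Incumbent& inc, std::vector<int> S,
              double rss_hint) {
  if (S.empty() || static_cast<int>(S.size()) > pb.maxf) return;
  double cp_hint = cp_value(pb, rss_hint, static_cast<int>(S.size()));
  if (inc.set && cp_hint > inc.cp + pb.eps) return;
  std::sort(S.begin(), S.end());
  double cp = cp_value(pb, subset_rss(pb, S), static_cast<int>(S.size()));
  if (!inc.set) {
    inc.set = true;
    inc.cp = cp;
    inc.sel = S;
    return;
  }
  if (cp < inc.cp - pb.eps) {
    inc.cp = cp;
    inc.sel = S;
  } else if (std::abs(cp - inc.cp) <= pb.eps) {
    if (S.size() < inc.sel.size() ||
        (S.size() == inc.sel.size() && lex_less(S, inc.sel))) {
      inc.cp = cp;
      inc.sel = S;
    }
  }
}

class SweepSearcher {
 public:
  const Problem& pb;
  Incumbent inc;
  long long nodes = 0;

  explicit SweepSearcher(const Problem& p) : pb(p), kk_(p.k + 1) {
    T_.set_size(kk_, kk_);
    T_.submat(0, 0, pb.k - 1, pb.k - 1) = pb.G;
    for (int j = 0; j < pb.k; ++j) {
      T_(j, pb.k) = pb.g[j];
      T_(pb.k, j) = pb.g[j];
    }
    T_(pb.k, pb.k) = pb.yy;
    for (int j = 0; j < pb.k; ++j) sweep(j);  // full model at the root
  }

  void run() {
    vars_.resize(pb.k);
    for (int j = 0; j < pb.k; ++j) vars_[j] = j;
    cost_.resize(pb.k);
    oc_.resize(pb.k);
    sc_.resize(pb.k);
    save_.assign(pb.k + 1, arma::mat());
    search(0, pb.k, 0);
  }

 private:
  arma::mat T_;
  int kk_;
  // vars_[0..n_in) are forced in, vars_[n_in..n_in+n_free) are free; the
  // active set is always the union of the two ranges
  std::vector<int> vars_;
  std::vector<double> cost_, oc_, sc_;
  std::vector<arma::mat> save_;

  void sweep(int j) {
    double d = T_(j, j);
    if (std::abs(d) < 1e-300) d = d >= 0 ? 1e-300 : -1e-300;
    arma::vec col = T_.col(j);
    T_ -= (col * col.t()) / d;
    T_.col(j) = col / d;
    T_.row(j) = col.t() / d;
    T_(j, j) = -1.0 / d;
  }

  void search(int n_in, int n_free, int depth) {
    ++nodes;
    const double rss_active = T_(pb.k, pb.k);
    const int a = n_in + n_free;

    if (!inc.set ||
        cp_value(pb, rss_active, a) <= inc.cp + pb.eps) {
      consider(pb, inc, std::vector<int>(vars_.begin(), vars_.begin() + a),
               rss_active);
    }

    if (n_free == 0) return;
    if (n_in >= pb.maxf) {
      std::vector<int> in_set(vars_.begin(), vars_.begin() + n_in);
      consider(pb, inc, in_set, subset_rss(pb, in_set));
      return;
    }

    for (int i = 0; i < n_free; ++i) {
      int j = vars_[n_in + i];
      double denom = -T_(j, j);
      double b = T_(j, pb.k);
      cost_[i] = denom > 1e-300 ? b * b / denom : 0.0;
      sc_[i] = pb.lam_min * b * b;
    }

    if (inc.set) {
      // per-size lower bound combining the order-statistic and spectral
      // drop costs
      std::copy(cost_.begin(), cost_.begin() + n_free, oc_.begin());
      std::sort(oc_.begin(), oc_.begin() + n_free);
      std::sort(sc_.begin(), sc_.begin() + n_free);
      double lb = std::numeric_limits<double>::infinity();
      double sc_cum = 0.0;
      for (int m = 0; m <= n_free; ++m) {
        if (m > 0) sc_cum += sc_[m - 1];
        int p = a - m;
        if (p > pb.maxf || p < 1) continue;
        double add = std::max(m == 0 ? 0.0 : oc_[m - 1], sc_cum);
        double b = cp_value(pb, rss_active + add, p);
        if (b < lb) lb = b;
      }
      if (lb > inc.cp + pb.eps) return;
    }

    // branch on the free variable with the largest single-drop cost
    int best_i = 0;
    for (int i = 1; i < n_free; ++i) {
      if (cost_[i] > cost_[best_i]) best_i = i;
    }
    int best_j = vars_[n_in + best_i];

    // child 1: best_j forced in (tableau unchanged); swap it to the front
    // of the free range so it joins the in range
    std::swap(vars_[n_in + best_i], vars_[n_in]);
    search(n_in + 1, n_free - 1, depth + 1);

    // child 2: best_j forced out; swap it to the back of the free range,
    // un-sweep it, recurse, copy-restore the tableau (avoids cumulative
    // round-off from sweep/un-sweep pairs)
    std::swap(vars_[n_in], vars_[n_in + n_free - 1]);
    save_[depth] = T_;
    sweep(best_j);
    search(n_in, n_free - 1, depth + 1);
    T_ = save_[depth];
    // restore the partition order for the caller
    std::swap(vars_[n_in], vars_[n_in + n_free - 1]);
    std::swap(vars_[n_in + best_i], vars_[n_in]);
  }
};

}  // namespace

// [[Rcpp::export]]
Rcpp::List cpp_best_subset(const arma::mat& X, const arma::vec& y,
                           int max_features, std::string method,
                           double tie_eps) {
  const int n = X.n_rows;
  const int k = X.n_cols;
  if (n <= k + 1) Rcpp::stop("need n > number of features + 1");

  Problem pb;
  arma::rowvec xm = arma::mean(X, 0);
  arma::mat Xc = X.each_row() - xm;
  // standardize columns: Cp, the selected set and tie order are invariant,
  // and the spectral bound tightens considerably
  arma::rowvec xs = arma::stddev(Xc, 0, 0);
  for (int j = 0; j < k; ++j) {
    if (xs[j] <= 0) Rcpp::stop("constant column in x; prune first");
  }
  Xc.each_row() /= xs;
  arma::vec yc = y - arma::mean(y);
  pb.G = Xc.t() * Xc;
  pb.g = Xc.t() * yc;
  pb.yy = arma::dot(yc, yc);
  pb.n = n;
  pb.k = k;
  pb.maxf = std::min(max_features, k);
  pb.eps = tie_eps;
  arma::vec eigval;
  if (!arma::eig_sym(eigval, pb.G)) {
    pb.lam_min = 0.0;
  } else {
    pb.lam_min = std::max(eigval.min(), 0.0);
  }

  std::vector<int> all(k);
  for (int j = 0; j < k; ++j) all[j] = j;
  pb.s2 = 1.0;  // placeholder so subset_rss is usable
  double rss_full = subset_rss(pb, all);
  double s2 = rss_full / (n - k - 1);
  if (s2 <= 0.0 || !std::isfinite(s2)) {
    Rcpp::stop("full-model residual variance is zero; the response is fit "
               "perfectly - check that noise is present");
  }
  pb.s2 = s2;

  Incumbent inc;
  long long nodes = 0;
  if (method == "exhaustive") {
    if (k > 25) Rcpp::stop("exhaustive search is limited to 25 features");
    Incumbent einc;
    const unsigned long long lim = 1ULL << k;
    for (unsigned long long mask = 1; mask < lim; ++mask) {
      std::vector<int> S;
      for (int j = 0; j < k; ++j)
        if (mask & (1ULL << j)) S.push_back(j);
      if (static_cast<int>(S.size()) > pb.maxf) continue;
      consider(pb, einc, S, subset_rss(pb, S));
      ++nodes;
    }
    inc = einc;
  } else {
    SweepSearcher s(pb);
    // warm start: forward selection seeds a good first incumbent
    {
      std::vector<int> cur;
      std::vector<int> rest = all;
      while (!rest.empty() && static_cast<int>(cur.size()) < pb.maxf) {
        double best_rss = std::numeric_limits<double>::infinity();
        int best_v = -1;
        for (int v : rest) {
          std::vector<int> trial = cur;
          trial.push_back(v);
          double r = subset_rss(pb, trial);
          if (r < best_rss) {
            best_rss = r;
            best_v = v;
          }
        }
        cur.push_back(best_v);
        rest.erase(std::find(rest.begin(), rest.end(), best_v));
        consider(pb, s.inc, cur, best_rss);
      }
    }
    s.run();
    inc = s.inc;
    nodes = s.nodes;
  }

  if (!inc.set) Rcpp::stop("no admissible subset found");
  double rss_sel = subset_rss(pb, inc.sel);

  Rcpp::IntegerVector selected(inc.sel.begin(), inc.sel.end());
  return Rcpp::List::create(
      Rcpp::Named("selected") = selected + 1,
      Rcpp::Named("cp") = inc.cp,
      Rcpp::Named("rss") = rss_sel,
      Rcpp::Named("rss_full") = rss_full,
      Rcpp::Named("sigma2_full") = s2,
      Rcpp::Named("nodes") = static_cast<double>(nodes));
}
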