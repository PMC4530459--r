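// Likelihood engine: Felsenstein pruning over a fixed unrooted binary tree
// with discrete-gamma rate categories, per-edge Brent branch-length
// optimization on exact conditional (up/down) partials, and the prefix-sum
// max-t window scanner used for boundary estimation.
//
// Conventions shared with the R wrappers:
//  * node ids are 1-based ape ids (tips 1..ntip, root ntip+1), edge matrix in
//    postorder;
//  * tip states are 0-based model-state indices, -1 for gap/unknown;
//  * P(t) = U diag(exp(lambda * t * rate)) W from the symmetric
//    eigendecomposition of the reversible rate matrix.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

const double SCALE_LO = 1e-120;

struct Engine {
  imat edge;                 // E x 2 (parent, child), postorder, 1-based
  vec el;                    // edge lengths
  int ntip, nnode_tot, nsites, s, ncat, root;
  mat U, W;
  vec lambda, pi, rates, weights;

  std::vector<std::vector<int> > child_edges;  // per node (0-based idx)
  std::vector<int> parent_edge;                // per node, -1 if root
  std::vector<mat> D;                          // partials, s x (nsites*ncat)
  std::vector<vec> sD;                         // per-site log scale factors
  std::vector<mat> Ue;                         // per edge: outside partial
  std::vector<vec> sU;
  mat tipD;                                    // s x (ntip*nsites) base tip blocks

  Engine(const imat& edge_, const vec& el_, int ntip_, const imat& tipstates,
         const mat& U_, const mat& W_, const vec& lambda_, const vec& pi_,
         const vec& rates_, const vec& weights_)
      : edge(edge_), el(el_), ntip(ntip_), U(U_), W(W_), lambda(lambda_),
        pi(pi_), rates(rates_), weights(weights_) {
    nsites = tipstates.n_cols;
    s = pi.n_elem;
    ncat = rates.n_elem;
    int maxn = edge.max();
    nnode_tot = maxn;
    root = edge(edge.n_rows - 1, 0);
    child_edges.assign(nnode_tot, std::vector<int>());
    parent_edge.assign(nnode_tot, -1);
    for (unsigned e = 0; e < edge.n_rows; ++e) {
      child_edges[edge(e, 0) - 1].push_back((int)e);
      parent_edge[edge(e, 1) - 1] = (int)e;
    }
    D.assign(nnode_tot, mat());
    sD.assign(nnode_tot, vec());
    Ue.assign(edge.n_rows, mat());
    sU.assign(edge.n_rows, vec());
    tipD.set_size(s, ntip * nsites);
    tipD.zeros();
    for (int t = 0; t < ntip; ++t)
      for (int i = 0; i < nsites; ++i) {
        int st = tipstates(t, i);
        if (st < 0)
          tipD.col(t * nsites + i).ones();
        else
          tipD(st, t * nsites + i) = 1.0;
      }
  }

  mat Pmat(double t, double rate) const {
    mat P = U * diagmat(exp(lambda * (t * rate))) * W;
    P.transform([](double x) { return x < 0.0 ? 0.0 : x; });
    return P;
  }

  bool is_tip(int node1) const { return node1 <= ntip; }

  // child partial block for category c of the node at the child end of edge e
  // (tips share one block across categories)
  void child_block(int e, int cat, mat& out) const {
    int c = edge(e, 1);
    if (is_tip(c))
      out = tipD.cols((c - 1) * nsites, c * nsites - 1);
    else
      out = D[c - 1].cols(cat * nsites, (cat + 1) * nsites - 1);
  }

  // conditional rescale of an s x (nsites*ncat) block, adding to scale
  void rescale(mat& M, vec& scale) const {
    for (int i = 0; i < nsites; ++i) {
      double m = 0.0;
      for (int c = 0; c < ncat; ++c) {
        double mc = M.col(c * nsites + i).max();
        if (mc > m) m = mc;
      }
      if (m > 0.0 && m < SCALE_LO) {
        for (int c = 0; c < ncat; ++c) M.col(c * nsites + i) /= m;
        scale(i) += std::log(m);
      }
    }
  }

  // recompute down partial of internal node v (1-based) from its children
  void computeD(int v1) {
    mat& Dv = D[v1 - 1];
    Dv.set_size(s, nsites * ncat);
    Dv.ones();
    vec& sc = sD[v1 - 1];
    sc.zeros(nsites);
    mat blk;
    for (size_t k = 0; k < child_edges[v1 - 1].size(); ++k) {
      int e = child_edges[v1 - 1][k];
      int c = edge(e, 1);
      for (int cat = 0; cat < ncat; ++cat) {
        mat P = Pmat(el(e), rates(cat));
        child_block(e, cat, blk);
        Dv.cols(cat * nsites, (cat + 1) * nsites - 1) %= P * blk;
      }
      if (!is_tip(c)) sc += sD[c - 1];
    }
    rescale(Dv, sc);
  }

  void computeD_rec(int v1) {
    for (size_t k = 0; k < child_edges[v1 - 1].size(); ++k) {
      int c = edge(child_edges[v1 - 1][k], 1);
      if (!is_tip(c)) computeD_rec(c);
    }
    computeD(v1);
  }

  void computeD_all() { computeD_rec(root); }

  // site log likelihoods from the root partial
  vec site_loglik() const {
    const mat& Dr = D[root - 1];
    vec out(nsites);
    for (int i = 0; i < nsites; ++i) {
      double L = 0.0;
      for (int c = 0; c < ncat; ++c)
        L += weights(c) * dot(pi, Dr.col(c * nsites + i));
      out(i) = std::log(L) + sD[root - 1](i);
    }
    return out;
  }

  // outside ("up") partial for edge e = (p, c): likelihood of everything
  // except subtree(c), as a function of the state at p, including the prior.
  void computeU(int e) {
    int p = edge(e, 0);
    mat& Um = Ue[e];
    Um.set_size(s, nsites * ncat);
    vec& sc = sU[e];
    sc.zeros(nsites);
    if (p == root) {
      for (int cat = 0; cat < ncat; ++cat)
        Um.cols(cat * nsites, (cat + 1) * nsites - 1) = repmat(pi, 1, nsites);
    } else {
      int pe = parent_edge[p - 1];
      for (int cat = 0; cat < ncat; ++cat) {
        mat P = Pmat(el(pe), rates(cat));
        Um.cols(cat * nsites, (cat + 1) * nsites - 1) =
            P.t() * Ue[pe].cols(cat * nsites, (cat + 1) * nsites - 1);
      }
      sc = sU[pe];
    }
    mat blk;
    for (size_t k = 0; k < child_edges[p - 1].size(); ++k) {
      int f = child_edges[p - 1][k];
      if (f == e) continue;
      int d = edge(f, 1);
      for (int cat = 0; cat < ncat; ++cat) {
        mat P = Pmat(el(f), rates(cat));
        child_block(f, cat, blk);
        Um.cols(cat * nsites, (cat + 1) * nsites - 1) %= P * blk;
      }
      if (!is_tip(d)) sc += sD[d - 1];
    }
    rescale(Um, sc);
  }

  // total log likelihood as a function of the length of edge e, holding the
  // rest of the tree fixed (requires valid Ue[e] and child partials)
  double edge_loglik(int e, double t) const {
    int c = edge(e, 1);
    rowvec acc(nsites, fill::zeros);
    mat blk;
    for (int cat = 0; cat < ncat; ++cat) {
      mat P = Pmat(t, rates(cat));
      child_block(e, cat, blk);
      acc += weights(cat) *
             sum(Ue[e].cols(cat * nsites, (cat + 1) * nsites - 1) % (P * blk), 0);
    }
    double extra = accu(sU[e]);
    if (!is_tip(c)) extra += accu(sD[c - 1]);
    double ll = 0.0;
    for (int i = 0; i < nsites; ++i) ll += std::log(acc(i));
    return ll + extra;
  }

  // bounded Brent maximization of edge_loglik over [lo, hi]
  double brent_edge(int e, double lo, double hi, double tol, int maxit) {
    const double gold = 0.3819660112501051;
    double a = lo, b = hi;
    double x = std::min(std::max(el(e), lo), hi);
    double w = x, v = x;
    double fx = -edge_loglik(e, x), fw = fx, fv = fx;
    double d = 0.0, ee = 0.0;
    for (int it = 0; it < maxit; ++it) {
      double xm = 0.5 * (a + b);
      double tol1 = tol * std::fabs(x) + 1e-7, tol2 = 2.0 * tol1;
      if (std::fabs(x - xm) <= tol2 - 0.5 * (b - a)) break;
      bool golden = true;
      if (std::fabs(ee) > tol1) {
        double r = (x - w) * (fx - fv);
        double q = (x - v) * (fx - fw);
        double pp = (x - v) * q - (x - w) * r;
        q = 2.0 * (q - r);
        if (q > 0.0) pp = -pp;
        q = std::fabs(q);
        double etemp = ee;
        ee = d;
        if (std::fabs(pp) < std::fabs(0.5 * q * etemp) && pp > q * (a - x) &&
            pp < q * (b - x)) {
          d = pp / q;
          double u = x + d;
          if (u - a < tol2 || b - u < tol2) d = (xm - x >= 0 ? tol1 : -tol1);
          golden = false;
        }
      }
      if (golden) {
        ee = (x >= xm ? a - x : b - x);
        d = gold * ee;
      }
      double u = (std::fabs(d) >= tol1 ? x + d : x + (d >= 0 ? tol1 : -tol1));
      double fu = -edge_loglik(e, u);
      if (fu <= fx) {
        if (u >= x) a = x; else b = x;
        v = w; w = x; x = u;
        fv = fw; fw = fx; fx = fu;
      } else {
        if (u < x) a = u; else b = u;
        if (fu <= fw || w == x) { v = w; w = u; fv = fw; fw = fu; }
        else if (fu <= fv || v == x || v == w) { v = u; fv = fu; }
      }
    }
    // never accept a worse length than the current one
    double f_old = edge_loglik(e, el(e));
    if (-fx > f_old) el(e) = x;
    return std::max(-fx, f_old);
  }

  // one Euler-tour sweep below node p (whose parent-edge U, if any, is valid)
  void sweep_node(int p1, double lo, double hi, double tol) {
    for (size_t k = 0; k < child_edges[p1 - 1].size(); ++k) {
      int e = child_edges[p1 - 1][k];
      int c = edge(e, 1);
      computeU(e);
      brent_edge(e, lo, hi, tol, 40);
      if (!is_tip(c)) {
        sweep_node(c, lo, hi, tol);
        computeD(c);  // refresh with the new subtree lengths
      }
    }
  }
};

imat as_imat(const Rcpp::IntegerMatrix& m) {
  imat out(m.nrow(), m.ncol());
  for (int i = 0; i < m.nrow(); ++i)
    for (int j = 0; j < m.ncol(); ++j) out(i, j) = m(i, j);
  return out;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List cpp_site_loglik(Rcpp::IntegerMatrix edge, arma::vec el, int ntip,
                           Rcpp::IntegerMatrix tipstates, arma::mat U,
                           arma::mat W, arma::vec lambda, arma::vec pi,
                           arma::vec rates, arma::vec weights) {
  Engine eng(as_imat(edge), el, ntip, as_imat(tipstates), U, W, lambda, pi,
             rates, weights);
  eng.computeD_all();
  arma::vec site = eng.site_loglik();
  return Rcpp::List::create(Rcpp::Named("site") = site,
                            Rcpp::Named("total") = arma::accu(site));
}

// [[Rcpp::export]]
Rcpp::List cpp_optim_edges(Rcpp::IntegerMatrix edge, arma::vec el, int ntip,
                           Rcpp::IntegerMatrix tipstates, arma::mat U,
                           arma::mat W, arma::vec lambda, arma::vec pi,
                           arma::vec rates, arma::vec weights, double lo,
                           double hi, double tol, int max_sweeps) {
  Engine eng(as_imat(edge), el, ntip, as_imat(tipstates), U, W, lambda, pi,
             rates, weights);
  eng.computeD_all();
  double prev = arma::accu(eng.site_loglik());
  double cur = prev;
  int sweeps = 0;
  for (int it = 0; it < max_sweeps; ++it) {
    eng.sweep_node(eng.root, lo, hi, std::min(1e-4, tol));
    eng.computeD_all();
    cur = arma::accu(eng.site_loglik());
    ++sweeps;
    if (cur - prev < tol) break;
    prev = cur;
  }
  return Rcpp::List::create(Rcpp::Named("el") = eng.el,
                            Rcpp::Named("loglik") = cur,
                            Rcpp::Named("sweeps") = sweeps);
}

// ---------------------------------------------------------------------------
// max-t window scanner (prefix sums; Welch-form t per window)

namespace {

// t statistic for window [i, i+w-1] (0-based) from prefix sums
inline double t_from_prefix(const std::vector<double>& S,
                            const std::vector<double>& S2, int i, int w,
                            int L) {
  double sum_in = S[i + w] - S[i];
  double ss_in = S2[i + w] - S2[i];
  double n_in = w, n_out = L - w;
  double sum_out = S[L] - sum_in;
  double ss_out = S2[L] - ss_in;
  double m_in = sum_in / n_in, m_out = sum_out / n_out;
  double v_in = (ss_in - n_in * m_in * m_in) / (n_in - 1.0);
  double v_out = (ss_out - n_out * m_out * m_out) / (n_out - 1.0);
  if (v_in < 0) v_in = 0;
  if (v_out < 0) v_out = 0;
  double den = std::sqrt(v_in / n_in + v_out / n_out);
  double num = m_in - m_out;
  if (den <= 0.0) {
    if (num == 0.0) return 0.0;
    return num > 0 ? 1e300 : -1e300;
  }
  return num / den;
}

void prefixes(const std::vector<double>& x, std::vector<double>& S,
              std::vector<double>& S2) {
  int L = x.size();
  S.assign(L + 1, 0.0);
  S2.assign(L + 1, 0.0);
  for (int i = 0; i < L; ++i) {
    S[i + 1] = S[i] + x[i];
    S2[i + 1] = S2[i] + x[i] * x[i];
  }
}

}  // namespace

// t statistics for every start position of one window width
// [[Rcpp::export]]
Rcpp::NumericVector cpp_tscan(Rcpp::NumericVector x, int width) {
  int L = x.size();
  std::vector<double> xv(x.begin(), x.end()), S, S2;
  prefixes(xv, S, S2);
  Rcpp::NumericVector out(L - width + 1);
  for (int i = 0; i + width <= L; ++i)
    out[i] = t_from_prefix(S, S2, i, width, L);
  return out;
}

// largest t over all windows of one width: returns c(t_max, start) (1-based)
// [[Rcpp::export]]
Rcpp::NumericVector cpp_max_t(Rcpp::NumericVector x, int width) {
  int L = x.size();
  std::vector<double> xv(x.begin(), x.end()), S, S2;
  prefixes(xv, S, S2);
  double best = -1e308;
  int arg = 0;
  for (int i = 0; i + width <= L; ++i) {
    double t = t_from_prefix(S, S2, i, width, L);
    if (t > best) { best = t; arg = i; }
  }
  return Rcpp::NumericVector::create(best, arg + 1);
}

// permutation null of the per-width max t: n_perm maxima, each from a
// uniform shuffle of x (uses R's RNG so seeding is controlled from R)
// [[Rcpp::export]]
Rcpp::NumericVector cpp_perm_max_t(Rcpp::NumericVector x, int width,
                                   int n_perm) {
  int L = x.size();
  std::vector<double> xv(x.begin(), x.end()), S, S2;
  Rcpp::NumericVector out(n_perm);
  Rcpp::RNGScope scope;
  for (int p = 0; p < n_perm; ++p) {
    for (int i = L - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(xv[i], xv[j]);
    }
    prefixes(xv, S, S2);
    double best = -1e308;
    for (int i = 0; i + width <= L; ++i) {
      double t = t_from_prefix(S, S2, i, width, L);
      if (t > best) best = t;
    }
    out[p] = best;
  }
  return out;
}
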