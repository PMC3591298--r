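#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Felsenstein pruning over an arbitrary reversible substitution model,
// one pass per mixture class, with per-node rescaling against underflow.
//
// Qs       list of distinct S x S rate generators, all reversible w.r.t. pi
// pi       equilibrium distribution (length S)
// edge     E x 2 (parent, child), 1-based node ids, postorder
// len      E branch lengths (expected substitutions per site/codon)
// q_index  K x E, 1-based index into Qs for (class, edge)
// rate     K multipliers applied to branch lengths (e.g. gamma categories)
// tips     n_tip x P integer states (1-based), 0 = missing -> flat partial
// n_node   total node count (tips + internal)
//
// Returns K x P per-class, per-pattern log-likelihoods.
//
// Transition probabilities use the spectral decomposition of the
// pi-symmetrized generator: with D = diag(pi), S* = D^{1/2} Q D^{-1/2}
// is symmetric, S* = U L U', and P(t) = D^{-1/2} U exp(Lt) U' D^{1/2}.
// [[Rcpp::export(name = ".class_site_loglik")]]
Rcpp::NumericMatrix class_site_loglik(const Rcpp::List& Qs,
                                      const arma::vec& pi,
                                      const arma::imat& edge,
                                      const arma::vec& len,
                                      const arma::imat& q_index,
                                      const arma::vec& rate,
                                      const arma::imat& tips,
                                      int n_node) {
  const int S = pi.n_elem;
  const int E = edge.n_rows;
  const int K = rate.n_elem;
  const int P = tips.n_cols;
  const int n_tip = tips.n_rows;
  const int nQ = Qs.size();

  vec sq = sqrt(pi);
  std::vector<mat> A(nQ), B(nQ);
  std::vector<vec> lam(nQ);
  for (int i = 0; i < nQ; ++i) {
    mat Q = Rcpp::as<mat>(Qs[i]);
    mat sym = diagmat(sq) * Q * diagmat(1.0 / sq);
    sym = 0.5 * (sym + sym.t());
    vec eval;
    mat evec;
    if (!eig_sym(eval, evec, sym))
      Rcpp::stop("eigendecomposition of the symmetrized generator failed");
    A[i] = diagmat(1.0 / sq) * evec;
    B[i] = evec.t() * diagmat(sq);
    lam[i] = eval;
  }

  const int root = edge(E - 1, 0) - 1;
  Rcpp::NumericMatrix out(K, P);
  mat tippart(S, P);

  for (int k = 0; k < K; ++k) {
    std::vector<mat> part(n_node);
    std::vector<bool> seen(n_node, false);
    rowvec logscale(P, fill::zeros);

    for (int e = 0; e < E; ++e) {
      const int par = edge(e, 0) - 1;
      const int ch = edge(e, 1) - 1;
      const int qi = q_index(k, e) - 1;
      const double t = len(e) * rate(k);

      mat Pm = A[qi] * diagmat(exp(lam[qi] * t)) * B[qi];
      Pm = clamp(Pm, 0.0, datum::inf);

      mat msg;
      if (ch < n_tip) {
        tippart.zeros();
        for (int p = 0; p < P; ++p) {
          const int s = tips(ch, p);
          if (s <= 0)
            tippart.col(p).ones();
          else
            tippart(s - 1, p) = 1.0;
        }
        msg = Pm * tippart;
      } else {
        msg = Pm * part[ch];
        part[ch].reset();
      }

      if (!seen[par]) {
        part[par] = msg;
        seen[par] = true;
      } else {
        part[par] %= msg;
      }

      rowvec m = max(part[par], 0);
      m.transform([](double v) { return v > 0.0 ? v : 1.0; });
      part[par].each_row() /= m;
      logscale += log(m);
    }

    rowvec lik = pi.t() * part[root];
    for (int p = 0; p < P; ++p)
      out(k, p) = std::log(lik(p)) + logscale(p);
  }
  return out;
}
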