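// Felsenstein pruning for GY94-style codon models with site categories and
// branch-specific effective omega (omega^k on test branches).  The rate
// matrix, its symmetric eigendecomposition, the per-edge transition
// probabilities and the pruning recursion all live here: the optimizers call
// this once per likelihood evaluation.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Decomp {
  arma::vec values;
  arma::mat C;     // Q = C diag(values) Cinv
  arma::mat Cinv;
};

// Build the scaled GY94 rate matrix for (kappa, omega, pi) and return its
// eigendecomposition via the pi^(1/2) symmetrization.
Decomp decompose(double kappa, double omega, const arma::vec& pi,
                 const arma::imat& pairs) {
  const int n = pi.n_elem;
  arma::mat Q(n, n, arma::fill::zeros);
  const double fac_tab[4] = {1.0, kappa, omega, kappa * omega};
  for (arma::uword r = 0; r < pairs.n_rows; ++r) {
    int i = pairs(r, 0) - 1, j = pairs(r, 1) - 1;
    double f = fac_tab[pairs(r, 2) - 1];
    Q(i, j) = f * pi(j);
    Q(j, i) = f * pi(i);
  }
  Q.diag() = -arma::sum(Q, 1);
  double rate = -arma::dot(pi, Q.diag());
  if (rate <= 0) stop("degenerate rate matrix: zero total rate");
  Q /= rate;

  arma::vec s = arma::sqrt(pi);
  arma::mat B = Q;
  B.each_col() %= s;
  B.each_row() /= s.t();
  B = 0.5 * (B + B.t());
  Decomp d;
  arma::mat V;
  if (!arma::eig_sym(d.values, V, B)) stop("eigendecomposition failed");
  d.C = V;
  d.C.each_col() /= s;
  d.Cinv = V.t();
  d.Cinv.each_row() %= s.t();
  return d;
}

// Decompositions depend only on (pi, kappa, omega); successive optimizer
// evaluations mostly perturb one parameter at a time, so most are reusable.
// The cache is invalidated when pi changes (tracked via a dot-product hash)
// and capped to bound memory.
struct DecompCache {
  double token = std::numeric_limits<double>::quiet_NaN();
  std::map<std::pair<double, double>, Decomp> store;

  const Decomp& get(double kappa, double omega, const arma::vec& pi,
                    const arma::imat& pairs) {
    double tok = 0.0;
    for (arma::uword i = 0; i < pi.n_elem; ++i) tok += pi(i) * (i + 1.0);
    if (tok != token || store.size() > 512) {
      store.clear();
      token = tok;
    }
    auto key = std::make_pair(kappa, omega);
    auto it = store.find(key);
    if (it == store.end())
      it = store.emplace(key, decompose(kappa, omega, pi, pairs)).first;
    return it->second;
  }
};

DecompCache g_cache;

inline arma::mat pmat(const Decomp& d, double t) {
  arma::mat P = d.C * arma::diagmat(arma::exp(d.values * t)) * d.Cinv;
  P.transform([](double x) { return x < 0 ? 0.0 : x; });
  return P;
}

}  // namespace

// Pruning log-likelihood.
//   edge:       postorder edge matrix (parent, child), 1-based ape numbering
//   lengths:    branch lengths, one per edge row
//   tipstates:  ntip x npat, 0-based sense-codon index, -1 = missing
//   weights:    pattern multiplicities
//   pi:         61 stationary frequencies
//   omega_eff:  ncat x nedges effective omega (already k-transformed)
//   cat_probs:  mixing proportions of the site categories
//   pairs:      single-nucleotide sense-codon pair table from genetic_code()
// [[Rcpp::export]]
double cpp_codon_loglik(const arma::imat& edge,
                        const arma::vec& lengths,
                        const arma::imat& tipstates,
                        const arma::vec& weights,
                        const arma::vec& pi,
                        double kappa,
                        const arma::mat& omega_eff,
                        const arma::vec& cat_probs,
                        const arma::imat& pairs) {
  const int nstate = pi.n_elem;
  const int nedge = edge.n_rows;
  const int npat = tipstates.n_cols;
  const int ntip = tipstates.n_rows;
  const int ncat = omega_eff.n_rows;
  const int root = edge(nedge - 1, 0);
  int nnode = root;
  for (int e = 0; e < nedge; ++e) nnode = std::max(nnode, edge(e, 1));

  // one decomposition per distinct effective omega (cached across calls;
  // copied locally so a cache reset cannot invalidate them mid-evaluation)
  std::map<double, Decomp> decomps;
  for (int c = 0; c < ncat; ++c)
    for (int e = 0; e < nedge; ++e) {
      double w = omega_eff(c, e);
      if (!decomps.count(w)) decomps[w] = g_cache.get(kappa, w, pi, pairs);
    }

  arma::mat site_loglik(npat, ncat);
  for (int c = 0; c < ncat; ++c) {
    std::vector<arma::mat> part(nnode + 1);
    std::vector<bool> seen(nnode + 1, false);
    arma::vec logscale(npat, arma::fill::zeros);

    for (int e = 0; e < nedge; ++e) {
      const int parent = edge(e, 0), child = edge(e, 1);
      const Decomp& d = decomps[omega_eff(c, e)];
      arma::mat P = pmat(d, lengths(e));
      arma::mat M(nstate, npat);
      if (child <= ntip) {
        for (int s = 0; s < npat; ++s) {
          int st = tipstates(child - 1, s);
          if (st >= 0) M.col(s) = P.col(st); else M.col(s).ones();
        }
      } else {
        M = P * part[child];
        part[child].reset();
      }
      if (!seen[parent]) {
        part[parent] = M;
        seen[parent] = true;
      } else {
        part[parent] %= M;
        // column rescaling against underflow on deep trees
        for (int s = 0; s < npat; ++s) {
          double m = part[parent].col(s).max();
          if (m > 0 && m < 1e-200) {
            part[parent].col(s) /= m;
            logscale(s) += std::log(m);
          }
        }
      }
    }
    for (int s = 0; s < npat; ++s) {
      double lik = arma::dot(pi, part[root].col(s));
      site_loglik(s, c) =
          (lik > 0 ? std::log(lik) : -std::numeric_limits<double>::infinity())
          + logscale(s);
    }
  }

  // mix categories per site in log space
  double total = 0.0;
  arma::vec logp = arma::log(cat_probs);
  for (int s = 0; s < npat; ++s) {
    double mx = -std::numeric_limits<double>::infinity();
    for (int c = 0; c < ncat; ++c)
      mx = std::max(mx, site_loglik(s, c) + logp(c));
    double acc = 0.0;
    for (int c = 0; c < ncat; ++c)
      acc += std::exp(site_loglik(s, c) + logp(c) - mx);
    total += weights(s) * (mx + std::log(acc));
  }
  return total;
}
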