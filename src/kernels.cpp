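// Numerical kernels used by the ensemble-similarity stage: all-vs-all
// least-squares-fitted RMSD, affinity-propagation clustering, and
// stochastic proximity embedding.  Kept in C++ because each is O(n^2)
// or worse in the pooled frame count.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Best-fit (Kabsch) RMSD between two centred n x 3 point sets, via the
// singular values of the 3x3 cross-covariance: the optimal superposition
// satisfies rmsd^2 = (G1 + G2 - 2*(s1 + s2 + sign(det C) * s3)) / n.
static double kabsch_rmsd(const arma::mat& X, const arma::mat& Y,
                          double Gx, double Gy) {
  arma::mat C = X.t() * Y; // 3 x 3
  arma::vec s;
  arma::mat U, V;
  arma::svd(U, s, V, C);
  double sgn = (arma::det(C) < 0.0) ? -1.0 : 1.0;
  double tr = s(0) + s(1) + sgn * s(2);
  double msd = (Gx + Gy - 2.0 * tr) / static_cast<double>(X.n_rows);
  if (msd < 0.0) msd = 0.0;
  return std::sqrt(msd);
}

static arma::mat frame_as_points(const arma::mat& xyz, arma::uword i) {
  arma::uword natom = xyz.n_cols / 3;
  arma::mat P(natom, 3);
  for (arma::uword a = 0; a < natom; ++a) {
    P(a, 0) = xyz(i, 3 * a);
    P(a, 1) = xyz(i, 3 * a + 1);
    P(a, 2) = xyz(i, 3 * a + 2);
  }
  P.each_row() -= arma::mean(P, 0);
  return P;
}

// [[Rcpp::export(name = ".pairwise_rmsd_cpp")]]
arma::mat pairwise_rmsd_cpp(const arma::mat& xyz) {
  arma::uword m = xyz.n_rows;
  std::vector<arma::mat> pts(m);
  arma::vec G(m);
  for (arma::uword i = 0; i < m; ++i) {
    pts[i] = frame_as_points(xyz, i);
    G(i) = arma::accu(pts[i] % pts[i]);
  }
  arma::mat D(m, m, arma::fill::zeros);
  for (arma::uword i = 0; i + 1 < m; ++i) {
    for (arma::uword j = i + 1; j < m; ++j) {
      double r = kabsch_rmsd(pts[i], pts[j], G(i), G(j));
      D(i, j) = r;
      D(j, i) = r;
    }
  }
  return D;
}

// [[Rcpp::export(name = ".rmsd_to_ref_cpp")]]
arma::vec rmsd_to_ref_cpp(const arma::mat& xyz, const arma::rowvec& ref) {
  arma::mat all = arma::join_cols(arma::mat(ref), xyz);
  arma::uword m = xyz.n_rows;
  arma::mat R = frame_as_points(all, 0);
  double Gr = arma::accu(R % R);
  arma::vec out(m);
  for (arma::uword i = 0; i < m; ++i) {
    arma::mat P = frame_as_points(all, i + 1);
    out(i) = kabsch_rmsd(R, P, Gr, arma::accu(P % P));
  }
  return out;
}

// Affinity propagation (responsibility/availability message passing) on a
// similarity matrix whose diagonal already holds the preference values.
// Convergence: the exemplar set unchanged for `convits` sweeps.
// [[Rcpp::export(name = ".affinity_propagation_cpp")]]
List affinity_propagation_cpp(const arma::mat& S, double damping,
                              int maxit, int convits) {
  arma::uword n = S.n_rows;
  arma::mat R(n, n, arma::fill::zeros);
  arma::mat A(n, n, arma::fill::zeros);
  arma::uvec exemplar_flag(n, arma::fill::zeros);
  int stable = 0;
  int it = 0;
  bool converged = false;
  for (it = 1; it <= maxit; ++it) {
    // responsibilities
    arma::mat AS = A + S;
    arma::mat Rnew(n, n);
    for (arma::uword i = 0; i < n; ++i) {
      double max1 = -arma::datum::inf, max2 = -arma::datum::inf;
      arma::uword k1 = 0;
      for (arma::uword k = 0; k < n; ++k) {
        double v = AS(i, k);
        if (v > max1) { max2 = max1; max1 = v; k1 = k; }
        else if (v > max2) { max2 = v; }
      }
      for (arma::uword k = 0; k < n; ++k)
        Rnew(i, k) = S(i, k) - ((k == k1) ? max2 : max1);
    }
    R = damping * R + (1.0 - damping) * Rnew;

    // availabilities
    arma::mat Rp = arma::max(R, arma::mat(n, n, arma::fill::zeros));
    for (arma::uword k = 0; k < n; ++k) Rp(k, k) = R(k, k);
    arma::rowvec cs = arma::sum(Rp, 0);
    arma::mat Anew(n, n);
    for (arma::uword k = 0; k < n; ++k) {
      double tot = cs(k);
      for (arma::uword i = 0; i < n; ++i) {
        double v = tot - Rp(i, k);
        Anew(i, k) = (i == k) ? (tot - Rp(k, k)) : std::min(0.0, v);
      }
    }
    A = damping * A + (1.0 - damping) * Anew;

    arma::uvec flag(n);
    for (arma::uword k = 0; k < n; ++k)
      flag(k) = (A(k, k) + R(k, k) > 0.0) ? 1u : 0u;
    if (arma::accu(flag) > 0 && arma::all(flag == exemplar_flag)) {
      if (++stable >= convits) { converged = true; break; }
    } else {
      stable = 0;
      exemplar_flag = flag;
    }
  }

  arma::uvec ex = arma::find(exemplar_flag == 1u);
  if (ex.n_elem == 0) {
    // degenerate fallback: most self-supporting point as single exemplar
    arma::vec diag = A.diag() + R.diag();
    ex = arma::uvec{ diag.index_max() };
  }
  arma::uvec assign(n);
  for (arma::uword i = 0; i < n; ++i) {
    double best = -arma::datum::inf;
    arma::uword bk = ex(0);
    for (arma::uword e = 0; e < ex.n_elem; ++e) {
      if (S(i, ex(e)) > best) { best = S(i, ex(e)); bk = ex(e); }
    }
    assign(i) = bk;
  }
  for (arma::uword e = 0; e < ex.n_elem; ++e) assign(ex(e)) = ex(e);
  return List::create(_["assignment"] = assign + 1, // 1-based cluster exemplar
                      _["exemplars"] = ex + 1,
                      _["iterations"] = it,
                      _["converged"] = converged);
}

// Stochastic proximity embedding: iterative pairwise updates matching the
// embedded distances to the input dissimilarities, with the learning rate
// and neighbourhood radius annealed over cycles.  Uses R's RNG so results
// are reproducible under set.seed().
// [[Rcpp::export(name = ".spe_embed_cpp")]]
arma::mat spe_embed_cpp(const arma::mat& D, int dim, int n_cycles,
                        int steps_per_cycle, double lambda0, double lambda1,
                        double r0, double r1) {
  arma::uword n = D.n_rows;
  double dmax = D.max();
  if (dmax <= 0.0) dmax = 1.0;
  arma::mat X(n, dim);
  for (arma::uword i = 0; i < n; ++i)
    for (int j = 0; j < dim; ++j)
      X(i, j) = unif_rand() * dmax;
  const double eps = 1e-10;
  for (int c = 0; c < n_cycles; ++c) {
    double f = (n_cycles > 1) ? static_cast<double>(c) / (n_cycles - 1) : 0.0;
    double lambda = lambda0 + f * (lambda1 - lambda0);
    double rc = r0 + f * (r1 - r0);
    for (int s = 0; s < steps_per_cycle; ++s) {
      arma::uword i = static_cast<arma::uword>(unif_rand() * n);
      arma::uword j = static_cast<arma::uword>(unif_rand() * n);
      if (i >= n) i = n - 1;
      if (j >= n) j = n - 1;
      if (i == j) continue;
      double dij = D(i, j);
      arma::rowvec diff = X.row(i) - X.row(j);
      double dcur = std::sqrt(arma::accu(diff % diff));
      // within the neighbourhood radius always match; beyond it only
      // push apart points that sit closer than their target distance
      if (dij <= rc || dcur < dij) {
        double coef = lambda * 0.5 * (dij - dcur) / (dcur + eps);
        X.row(i) += coef * diff;
        X.row(j) -= coef * diff;
      }
    }
  }
  return X;
}
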