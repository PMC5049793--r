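// Batch evaluation of the homogeneous (S_Hom) and heterogeneous (S_Het)
// combined statistics over the rows of a Z panel.
//
// Both statistics are quadratic forms of the per-SNP vector of panel Z
// statistics T against the null correlation matrix R of those statistics:
//   S = (a' R^-1 T)^2 / (a' R^-1 a)
// with a = W^-1 e for S_Hom and, for S(tau), a restricted to the active
// set {|T| > tau} with sign-aligned entries a = sign(T) / w.  S_Het is the
// maximum of S(tau) over the finite grid of thresholds just below each
// distinct |T| (S(tau) is piecewise constant between order statistics of
// |T|, so this grid attains the supremum).  Missing panels are handled by
// subsetting T, R and W to the observed entries.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export(name = ".cpassoc_batch")]]
List cpassoc_batch(const arma::mat& Z, const arma::mat& W,
                   const arma::mat& R, bool do_hom, bool do_het,
                   double tau_eps) {
  const arma::uword M = Z.n_rows, P = Z.n_cols;
  arma::vec s_hom(M), s_het(M), tau_star(M);
  arma::ivec n_active(M), n_used(M), hom_fail(M, arma::fill::zeros);
  s_hom.fill(arma::datum::nan);
  s_het.fill(arma::datum::nan);
  tau_star.fill(arma::datum::nan);

  for (arma::uword i = 0; i < M; ++i) {
    // observed panels for this SNP
    arma::uvec obs = arma::find_finite(Z.row(i).t());
    n_used(i) = obs.n_elem;
    n_active(i) = 0;
    if (obs.n_elem == 0) continue;
    arma::vec t = Z.row(i).t();  t = t.elem(obs);
    arma::vec w = W.row(i).t();  w = w.elem(obs);
    arma::mat Rsub = R.submat(obs, obs);

    if (do_hom) {
      arma::vec a = 1.0 / w;
      arma::mat x;
      if (arma::solve(x, Rsub, arma::join_rows(a, t),
                      arma::solve_opts::no_approx)) {
        double den = arma::dot(a, x.col(0));
        double num = arma::dot(a, x.col(1));
        if (den > 0) s_hom(i) = num * num / den;
        else hom_fail(i) = 1;
      } else {
        hom_fail(i) = 1;
      }
    }

    if (do_het) {
      arma::vec abst = arma::abs(t);
      if (arma::all(abst == 0)) {
        s_het(i) = 0.0;
        tau_star(i) = NA_REAL;
        n_active(i) = 0;
        continue;
      }
      // distinct non-zero |T| in decreasing order; active sets are nested
      arma::vec grid = arma::sort(abst.elem(arma::find(abst > 0)), "descend");
      double best = -1.0, best_tau = NA_REAL;
      int best_k = 0;
      double prev = arma::datum::inf;
      for (arma::uword g = 0; g < grid.n_elem; ++g) {
        if (grid(g) == prev) continue;  // duplicated |T|
        prev = grid(g);
        double tau = grid(g) - tau_eps;
        arma::uvec act = arma::find(abst > tau);
        arma::vec ta = t.elem(act);
        arma::vec a = arma::sign(ta) / w.elem(act);
        arma::mat Ra = Rsub.submat(act, act);
        arma::mat x;
        if (!arma::solve(x, Ra, arma::join_rows(a, ta),
                         arma::solve_opts::no_approx))
          continue;  // singular restricted R: skip this tau
        double den = arma::dot(a, x.col(0));
        if (den <= 0) continue;
        double num = arma::dot(a, x.col(1));
        double s = num * num / den;
        // ties broken toward smaller tau (larger active set): later g wins
        if (s >= best) { best = s; best_tau = tau; best_k = act.n_elem; }
      }
      if (best >= 0) {
        s_het(i) = best;
        tau_star(i) = best_tau;
        n_active(i) = best_k;
      }
    }
  }

  return List::create(_["s_hom"] = s_hom, _["s_het"] = s_het,
                      _["tau_star"] = tau_star, _["n_active"] = n_active,
                      _["n_used"] = n_used, _["hom_fail"] = hom_fail);
}
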