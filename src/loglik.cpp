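#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export(name = ".expm_dense")]]
arma::mat expm_dense(const arma::mat& M) {
  return arma::expmat(M);
}

// Weighted interval-censored log-likelihood for a finite-state CTMC.
//
// Intervals are grouped by unique (elapsed time, covariate profile); one
// matrix exponential is evaluated per group and looked up per interval.
// logq: baseline log-intensities per allowed transition (length m);
// beta:  m x k log-hazard-ratio matrix (k may be 0);
// afrom/ato: 1-based allowed transition endpoints;
// from/to/w/grp: per-interval observed states, weight, 1-based group id;
// gdt/gX: per-group elapsed years and covariate row.
// Returns -Inf (not an error) when an observed interval has zero
// probability under the structure, so optimisers can back off.
// [[Rcpp::export(name = ".panel_loglik")]]
double panel_loglik(const arma::vec& logq, const arma::mat& beta,
                    const arma::ivec& afrom, const arma::ivec& ato,
                    const arma::ivec& from, const arma::ivec& to,
                    const arma::vec& w, const arma::ivec& grp,
                    const arma::vec& gdt, const arma::mat& gX,
                    const int nstate) {
  const arma::uword m = logq.n_elem;
  const arma::uword G = gdt.n_elem;
  const arma::uword n = from.n_elem;
  const arma::uword k = beta.n_cols;

  arma::cube P(nstate, nstate, G);
  arma::mat Q(nstate, nstate);
  for (arma::uword g = 0; g < G; ++g) {
    Q.zeros();
    for (arma::uword j = 0; j < m; ++j) {
      double lq = logq[j];
      for (arma::uword c = 0; c < k; ++c) lq += beta(j, c) * gX(g, c);
      if (lq > 50.0) return R_NegInf;  // guard against overflow excursions
      Q(afrom[j] - 1, ato[j] - 1) = std::exp(lq);
    }
    Q.diag() = -arma::sum(Q, 1);
    arma::mat Pg = arma::expmat(Q * gdt[g]);
    // guard: expmat of an extreme generator can lose stochasticity; treat
    // such parameter values as having zero likelihood
    for (arma::uword e = 0; e < Pg.n_elem; ++e) {
      const double p = Pg[e];
      if (!std::isfinite(p) || p > 1.0 + 1e-8 || p < -1e-8) return R_NegInf;
    }
    P.slice(g) = Pg;
  }

  double ll = 0.0;
  for (arma::uword i = 0; i < n; ++i) {
    const double p = P(from[i] - 1, to[i] - 1, grp[i] - 1);
    if (!(p > 0.0)) return R_NegInf;
    ll += w[i] * std::log(p);
  }
  return std::isfinite(ll) ? ll : R_NegInf;
}
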