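#include <Rcpp.h>
using namespace Rcpp;

// Per-cell mixture statistics for the composite likelihood
//   sum_ij log( sum_kl p_ik * pi_l * phi(x_ij; mu_kl, sigma_kl) ).
//
// x: n x m expression, logp: n x K log genotype prior, logpi: length L,
// mu, sigma: K x L block parameters. One pass per cell with a log-sum-exp
// over the K*L components; no n x m x K x L array is materialised.
//
// Returns the composite log-likelihood and, when want_stats is true, the
// block-wise responsibility sums S0 = sum t, S1 = sum t*x, S2 = sum t*x^2
// (each K x L) plus the row- and column-marginal responsibilities
// row_post (n x K, averaged over columns) and col_post (m x L, averaged
// over rows).
// [[Rcpp::export(.cl_cell_stats)]]
List cl_cell_stats(NumericMatrix x, NumericMatrix logp, NumericVector logpi,
                   NumericMatrix mu, NumericMatrix sigma, bool want_stats) {
  const int n = x.nrow(), m = x.ncol();
  const int K = mu.nrow(), L = mu.ncol();
  const int C = K * L;
  const double LOG_SQRT_2PI = 0.9189385332046727417803297;

  // per-component constants: cst = log pi_l - log sqrt(2*pi) - log sigma
  std::vector<double> cst(C), isig(C), mloc(C);
  {
    const double *pmu = REAL(mu), *psig = REAL(sigma), *ppi = REAL(logpi);
    for (int l = 0; l < L; ++l)
      for (int k = 0; k < K; ++k) {
        const int c = k + K * l;
        cst[c] = ppi[l] - LOG_SQRT_2PI - std::log(psig[c]);
        isig[c] = 1.0 / psig[c];
        mloc[c] = pmu[c];
      }
  }

  NumericMatrix S0(K, L), S1(K, L), S2(K, L);
  NumericMatrix rowpost(n, K), colpost(m, L);
  double *s0 = REAL(S0), *s1 = REAL(S1), *s2 = REAL(S2);
  double *rp = REAL(rowpost), *cp = REAL(colpost);
  const double *px = REAL(x), *plogp = REAL(logp);
  double logcl = 0.0;
  std::vector<double> a(C);

  for (int j = 0; j < m; ++j) {
    const double *xj = px + (size_t)j * n;
    for (int i = 0; i < n; ++i) {
      const double xij = xj[i];
      double amax = R_NegInf;
      for (int c = 0; c < C; ++c) {
        const double zr = (xij - mloc[c]) * isig[c];
        const double v = plogp[i + n * (c % K)] + cst[c] - 0.5 * zr * zr;
        a[c] = v;
        if (v > amax) amax = v;
      }
      double s = 0.0;
      for (int c = 0; c < C; ++c) { a[c] = std::exp(a[c] - amax); s += a[c]; }
      logcl += amax + std::log(s);
      if (want_stats) {
        const double inv = 1.0 / s;
        for (int c = 0; c < C; ++c) {
          const double t = a[c] * inv;
          s0[c] += t;
          s1[c] += t * xij;
          s2[c] += t * xij * xij;
          rp[i + n * (c % K)] += t;
          cp[j + m * (c / K)] += t;
        }
      }
    }
  }

  if (want_stats) {
    for (int c = 0; c < n * K; ++c) rp[c] /= m;
    for (int c = 0; c < m * L; ++c) cp[c] /= n;
  }

  return List::create(_["logcl"] = logcl,
                      _["S0"] = S0, _["S1"] = S1, _["S2"] = S2,
                      _["row_post"] = rowpost, _["col_post"] = colpost);
}
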