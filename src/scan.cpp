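#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <set>
#include <vector>
using namespace Rcpp;

// Grid-search maximization of the spatial sweep-model composite
// log-likelihood for each target window.
//
// X          : windows x K truncated counts (one chromosome)
// z          : window coordinates (same order as rows of X)
// p          : background spectrum (length K)
// Q          : n_combo x K distorted spectra, rows ordered by (m, eps)
//              ascending (the tie-break order)
// m_of_row   : m for each row of Q
// eps_of_row : eps for each row of Q
// A_values   : increasing decay-rate grid
// targets    : 1-based row indices of target windows
//
// Two evaluation strategies produce results identical (to floating-point
// rounding) to the literal triple loop over (m, A, eps) and all windows:
//  * windows at identical distance from a target are pooled before the
//    grid loop, and mixture terms whose weight alpha is small enough that
//    p + alpha*(q - p) rounds to p in double precision are replaced by
//    their (then identical) null terms;
//  * when the distinct target-window distances genome-wide form a small
//    set (e.g. regularly spaced coordinates), the per-(A, distance, m,
//    eps, k) log-mixture values are computed once per A value and shared
//    across targets.

namespace {

struct Best {
  double ll = R_NegInf;
  int c = -1, a = -1;
};

// tie-break: larger ll wins; on exact ties smaller (m, A, eps), i.e.
// smaller combo row (m-major, eps-minor) after smaller A
inline void update_best(Best &b, double ll, int c, int a,
                        const IntegerVector &m_of_row) {
  if (ll > b.ll) {
    b.ll = ll;
    b.c = c;
    b.a = a;
  } else if (ll == b.ll && b.c >= 0) {
    int m_new = m_of_row[c], m_old = m_of_row[b.c];
    if (m_new < m_old || (m_new == m_old && (a < b.a ||
        (a == b.a && c < b.c)))) {
      b.c = c;
      b.a = a;
    }
  }
}

}  // namespace

// [[Rcpp::export]]
List salti_scan_cpp(NumericMatrix X, NumericVector z, NumericVector p,
                    NumericMatrix Q, IntegerVector m_of_row,
                    NumericVector eps_of_row, NumericVector A_values,
                    IntegerVector targets) {
  const int I = X.nrow(), K = X.ncol();
  const int n_combo = Q.nrow(), n_A = A_values.size();
  const int n_t = targets.size();

  std::vector<double> logp(K);
  double minp = p[0];
  for (int k = 0; k < K; ++k) {
    logp[k] = std::log(p[k]);
    minp = std::min(minp, p[k]);
  }

  // delta rows and the largest |q_k - p_k| anywhere on the grid
  std::vector<double> delta((size_t)n_combo * K);
  double max_abs_delta = 0.0;
  for (int c = 0; c < n_combo; ++c)
    for (int k = 0; k < K; ++k) {
      double d = Q(c, k) - p[k];
      delta[(size_t)c * K + k] = d;
      max_abs_delta = std::max(max_abs_delta, std::fabs(d));
    }
  // alpha below this cannot move any mixture entry by half an ulp of p_k
  const double alpha_cut =
      max_abs_delta > 0 ? minp * 1e-18 / max_abs_delta : 1.0;

  NumericVector lambda(n_t), A_hat(n_t), eps_hat(n_t);
  IntegerVector m_hat(n_t);

  for (int t = 0; t < n_t; ++t)
    if (targets[t] < 1 || targets[t] > I)
      stop("target index out of range");

  // distinct distances genome-wide across all targets
  const size_t lg_limit = 16000000;  // doubles in the shared log table
  std::set<double> uset;
  bool shared = true;
  for (int t = 0; t < n_t && shared; ++t) {
    const double zs = z[targets[t] - 1];
    for (int i = 0; i < I; ++i) {
      uset.insert(std::fabs(z[i] - zs));
      if ((size_t)n_combo * uset.size() * K > lg_limit) {
        shared = false;
        break;
      }
    }
  }

  if (shared) {
    const std::vector<double> U(uset.begin(), uset.end());
    const int nU = U.size();

    // per-target rows: pooled counts over windows at each distinct
    // distance, ascending distance
    std::vector<std::vector<int>> uidx(n_t);
    std::vector<std::vector<double>> Xc(n_t), nulltail(n_t);
    std::vector<double> ll0(n_t);
    for (int t = 0; t < n_t; ++t) {
      const double zs = z[targets[t] - 1];
      std::vector<double> acc((size_t)nU * K, 0.0);
      std::vector<bool> used(nU, false);
      for (int i = 0; i < I; ++i) {
        const double d = std::fabs(z[i] - zs);
        const int u = std::lower_bound(U.begin(), U.end(), d) - U.begin();
        used[u] = true;
        for (int k = 0; k < K; ++k) acc[(size_t)u * K + k] += X(i, k);
      }
      for (int u = 0; u < nU; ++u)
        if (used[u]) {
          uidx[t].push_back(u);
          for (int k = 0; k < K; ++k)
            Xc[t].push_back(acc[(size_t)u * K + k]);
        }
      const int nr = uidx[t].size();
      nulltail[t].assign(nr + 1, 0.0);
      for (int j = nr - 1; j >= 0; --j) {
        double s = 0.0;
        for (int k = 0; k < K; ++k) s += Xc[t][(size_t)j * K + k] * logp[k];
        nulltail[t][j] = nulltail[t][j + 1] + s;
      }
      ll0[t] = nulltail[t][0];
    }

    std::vector<Best> best(n_t);
    std::vector<double> LG((size_t)n_combo * nU * K);
    for (int a = 0; a < n_A; ++a) {
      const double A = A_values[a];
      int cutU = nU;
      std::vector<double> alpha(nU);
      for (int u = 0; u < nU; ++u) {
        alpha[u] = std::exp(-A * U[u]);
        if (alpha[u] < alpha_cut && cutU == nU) cutU = u;
      }
      for (int c = 0; c < n_combo; ++c) {
        const double *dl = &delta[(size_t)c * K];
        double *lg = &LG[(size_t)c * nU * K];
        for (int u = 0; u < cutU; ++u) {
          const double al = alpha[u];
          for (int k = 0; k < K; ++k)
            lg[(size_t)u * K + k] = std::log(p[k] + al * dl[k]);
        }
      }
      for (int t = 0; t < n_t; ++t) {
        const int nr = uidx[t].size();
        int jcut = 0;
        while (jcut < nr && uidx[t][jcut] < cutU) ++jcut;
        const double tail = nulltail[t][jcut];
        const double *xc = Xc[t].data();
        for (int c = 0; c < n_combo; ++c) {
          const double *lg = &LG[(size_t)c * nU * K];
          double ll = tail;
          for (int j = 0; j < jcut; ++j) {
            const double *lgr = &lg[(size_t)uidx[t][j] * K];
            const double *xr = &xc[(size_t)j * K];
            double s = 0.0;
            for (int k = 0; k < K; ++k) s += xr[k] * lgr[k];
            ll += s;
          }
          update_best(best[t], ll, c, a, m_of_row);
        }
      }
    }
    for (int t = 0; t < n_t; ++t) {
      lambda[t] = 2.0 * (best[t].ll - ll0[t]);
      m_hat[t] = m_of_row[best[t].c];
      A_hat[t] = A_values[best[t].a];
      eps_hat[t] = eps_of_row[best[t].c];
    }
    return List::create(_["lambda"] = lambda, _["m_hat"] = m_hat,
                        _["A_hat"] = A_hat, _["eps_hat"] = eps_hat);
  }

  // fallback: independent evaluation per target
  for (int t = 0; t < n_t; ++t) {
    const int istar = targets[t] - 1;

    // pool windows by exact distance from the target
    std::vector<int> ord(I);
    for (int i = 0; i < I; ++i) ord[i] = i;
    const double zs = z[istar];
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      return std::fabs(z[a] - zs) < std::fabs(z[b] - zs);
    });
    std::vector<double> dist;
    std::vector<double> Xc;  // D x K, row-major
    for (int j = 0; j < I; ++j) {
      const int i = ord[j];
      const double d = std::fabs(z[i] - zs);
      if (dist.empty() || d != dist.back()) {
        dist.push_back(d);
        Xc.insert(Xc.end(), K, 0.0);
      }
      double *row = &Xc[(dist.size() - 1) * K];
      for (int k = 0; k < K; ++k) row[k] += X(i, k);
    }
    const int D = dist.size();

    std::vector<double> nullterm(D), nulltail(D + 1, 0.0);
    for (int d = 0; d < D; ++d) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) s += Xc[(size_t)d * K + k] * logp[k];
      nullterm[d] = s;
    }
    for (int d = D - 1; d >= 0; --d)
      nulltail[d] = nulltail[d + 1] + nullterm[d];
    const double ll0 = nulltail[0];

    std::vector<double> alpha((size_t)n_A * D);
    std::vector<int> dcut(n_A);
    for (int a = 0; a < n_A; ++a) {
      int cut = D;
      for (int d = 0; d < D; ++d) {
        double al = std::exp(-A_values[a] * dist[d]);
        alpha[(size_t)a * D + d] = al;
        if (al < alpha_cut && cut == D) cut = d;
      }
      dcut[a] = cut;
    }

    Best best;
    for (int a = 0; a < n_A; ++a) {
      const double *al_row = &alpha[(size_t)a * D];
      const int cut = dcut[a];
      const double tail = nulltail[cut];
      for (int c = 0; c < n_combo; ++c) {
        const double *dl = &delta[(size_t)c * K];
        double ll = tail;
        for (int d = 0; d < cut; ++d) {
          const double al = al_row[d];
          const double *xr = &Xc[(size_t)d * K];
          double s = 0.0;
          for (int k = 0; k < K; ++k)
            s += xr[k] * std::log(p[k] + al * dl[k]);
          ll += s;
        }
        update_best(best, ll, c, a, m_of_row);
      }
    }

    lambda[t] = 2.0 * (best.ll - ll0);
    m_hat[t] = m_of_row[best.c];
    A_hat[t] = A_values[best.a];
    eps_hat[t] = eps_of_row[best.c];
  }

  return List::create(_["lambda"] = lambda, _["m_hat"] = m_hat,
                      _["A_hat"] = A_hat, _["eps_hat"] = eps_hat);
}
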