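#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Flat-vector right-hand sides for the competition models, mirroring the R
// reference implementations in R/rhs.R. State layout: s[0..m-1], then the
// off-diagonal subpopulations p[i][j] in row-major order. Abundances are
// clipped at zero inside the evaluation only. Hot loops work on raw
// column-major buffers; matrices are indexed as M[i + m*j].

// [[Rcpp::export]]
NumericVector rhs_classic_flat(NumericVector y, NumericVector mu,
                               NumericMatrix G, double D) {
  const int m = y.size();
  const double *yp = y.begin(), *mup = mu.begin(), *g = G.begin();
  NumericVector ds(m);
  std::vector<double> sc(m);
  for (int i = 0; i < m; ++i) sc[i] = yp[i] > 0 ? yp[i] : 0.0;
  for (int i = 0; i < m; ++i) {
    double comp = 1.0;
    const double *gi = g + (size_t)m * i; // column i: G[j, i]
    for (int j = 0; j < m; ++j) comp -= gi[j] * sc[j];
    ds[i] = mup[i] * sc[i] * comp - D * sc[i];
  }
  return ds;
}

// eta_arr is either an m x m donor-by-recipient matrix (eta_is_matrix) or a
// full m x m x m tensor in R array order [j, k, i].
// [[Rcpp::export]]
NumericVector rhs_hgt_flat(NumericVector y, NumericVector mu,
                           NumericMatrix L, NumericMatrix G,
                           NumericMatrix Dk, double D,
                           NumericVector eta_arr, bool eta_is_matrix,
                           bool multiplicative) {
  const int m = mu.size();
  const size_t mm = (size_t)m * m;
  const double *yp = y.begin(), *mup = mu.begin();
  const double *l = L.begin(), *g = G.begin(), *dk = Dk.begin();
  const double *ev = eta_arr.begin();

  std::vector<double> sc(m), comp(m), mue(m);
  std::vector<double> P(mm), r(mm), one(mm), pref(mm), T(mm);

  for (int i = 0; i < m; ++i) sc[i] = yp[i] > 0 ? yp[i] : 0.0;
  int pos = m;
  for (int i = 0; i < m; ++i) {
    P[i + (size_t)m * i] = sc[i];
    for (int j = 0; j < m; ++j) {
      if (i == j) continue;
      double v = yp[pos++];
      P[i + (size_t)m * j] = v > 0 ? v : 0.0;
    }
  }
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < m; ++i) {
      if (sc[i] <= 0) { r[i + (size_t)m * j] = 0.0; continue; }
      double q = P[i + (size_t)m * j] / sc[i];
      r[i + (size_t)m * j] = q < 0 ? 0.0 : (q > 1 ? 1.0 : q);
    }
  }
  for (int i = 0; i < m; ++i) {
    if (sc[i] > 0) r[i + (size_t)m * i] = 1.0;
  }

  for (int i = 0; i < m; ++i) {
    double c = 1.0;
    const double *gi = g + (size_t)m * i;
    for (int j = 0; j < m; ++j) c -= gi[j] * sc[j];
    comp[i] = c;
  }

  if (multiplicative) {
    std::vector<double> rp(m);
    for (int i = 0; i < m; ++i) {
      double prod = 1.0;
      for (int j = 0; j < m; ++j) {
        double o = 1.0 + l[i + (size_t)m * j] * r[i + (size_t)m * j];
        if (o < 1e-300) o = 1e-300;
        one[i + (size_t)m * j] = o;
        prod *= o;
      }
      rp[i] = prod;
      const double oii = one[i + (size_t)m * i];
      mue[i] = mup[i] * prod / oii;
      for (int j = 0; j < m; ++j) {
        pref[i + (size_t)m * j] = mup[i] * (1.0 + l[i + (size_t)m * j]) *
          rp[i] / (oii * one[i + (size_t)m * j]);
      }
    }
  } else {
    for (int i = 0; i < m; ++i) {
      double tot = 0.0;
      for (int j = 0; j < m; ++j) tot += l[i + (size_t)m * j] * r[i + (size_t)m * j];
      tot -= l[i + (size_t)m * i] * r[i + (size_t)m * i];
      mue[i] = mup[i] + tot;
      for (int j = 0; j < m; ++j) {
        pref[i + (size_t)m * j] = mup[i] + l[i + (size_t)m * j] + tot -
          l[i + (size_t)m * j] * r[i + (size_t)m * j];
      }
    }
  }

  // transfer inflow T[i, j] = sum_k eta[j, k, i] * P[k, j]
  if (eta_is_matrix) {
    for (int j = 0; j < m; ++j) {
      const double *Pj = P.data() + (size_t)m * j;
      for (int i = 0; i < m; ++i) {
        const double *ei = ev + (size_t)m * i; // column i: eta[k, i]
        double acc = 0.0;
        for (int k = 0; k < m; ++k) acc += ei[k] * Pj[k];
        T[i + (size_t)m * j] = acc;
      }
    }
  } else {
    for (int j = 0; j < m; ++j) {
      const double *Pj = P.data() + (size_t)m * j;
      for (int i = 0; i < m; ++i) {
        double acc = 0.0;
        for (int k = 0; k < m; ++k) {
          acc += ev[j + (size_t)m * (k + (size_t)m * i)] * Pj[k];
        }
        T[i + (size_t)m * j] = acc;
      }
    }
  }

  NumericVector out(mm);
  double *op = out.begin();
  for (int i = 0; i < m; ++i) {
    op[i] = mue[i] * sc[i] * comp[i] - D * sc[i];
  }
  pos = m;
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < m; ++j) {
      if (i == j) continue;
      const size_t ij = i + (size_t)m * j;
      op[pos++] = pref[ij] * P[ij] * comp[i] +
        (sc[i] - P[ij]) * T[ij] - dk[ij] * P[ij];
    }
  }
  return out;
}
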