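// Contact counting and gyration statistics over snapshot arrays.
// A contact is a strict minimum-image center distance below the threshold t.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

inline double mi(double d, double L, double hL) {
  if (d > hL) d -= L;
  else if (d < -hL) d += L;
  return d;
}

void snap_dims(const NumericVector& snaps, int& n, int& S) {
  IntegerVector dim = snaps.attr("dim");
  if (dim.size() != 3 || dim[1] != 3) stop("snapshot array must be n x 3 x S");
  n = dim[0];
  S = dim[2];
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".contact_hist_cpp")]]
IntegerMatrix contact_hist_cpp(NumericVector snaps, IntegerVector idx,
                               double L, double t, int exclude_window) {
  int n, S;
  snap_dims(snaps, n, S);
  const int K = idx.size();
  const double t2 = t * t, hL = 0.5 * L;
  IntegerMatrix H(K, K);
  std::vector<int> id(K);
  for (int k = 0; k < K; ++k) {
    id[k] = idx[k] - 1;
    if (id[k] < 0 || id[k] >= n) stop("index out of range");
  }
  for (int s = 0; s < S; ++s) {
    const double* x = &snaps[(R_xlen_t)s * n * 3];
    const double* y = x + n;
    const double* z = y + n;
    for (int a = 0; a < K; ++a) {
      const int i = id[a];
      for (int b = a + 1; b < K; ++b) {
        if (b - a <= exclude_window) continue;
        const int j = id[b];
        const double dx = mi(x[i] - x[j], L, hL);
        if (std::fabs(dx) >= t) continue;
        const double dy = mi(y[i] - y[j], L, hL);
        const double dz = mi(z[i] - z[j], L, hL);
        if (dx * dx + dy * dy + dz * dz < t2) {
          ++H(a, b);
          ++H(b, a);
        }
      }
    }
  }
  return H;
}

//' @noRd
// [[Rcpp::export(name = ".cross_contacts_cpp")]]
List cross_contacts_cpp(NumericVector snaps, IntegerVector idxA,
                        IntegerVector idxB, double L, double t) {
  int n, S;
  snap_dims(snaps, n, S);
  const int A = idxA.size(), B = idxB.size();
  const double t2 = t * t, hL = 0.5 * L;
  IntegerMatrix counts(A, B);
  long long bound_obs = 0;
  std::vector<int> ia(A), ib(B);
  for (int k = 0; k < A; ++k) {
    ia[k] = idxA[k] - 1;
    if (ia[k] < 0 || ia[k] >= n) stop("index out of range");
  }
  for (int k = 0; k < B; ++k) {
    ib[k] = idxB[k] - 1;
    if (ib[k] < 0 || ib[k] >= n) stop("index out of range");
  }
  for (int s = 0; s < S; ++s) {
    const double* x = &snaps[(R_xlen_t)s * n * 3];
    const double* y = x + n;
    const double* z = y + n;
    for (int a = 0; a < A; ++a) {
      const int i = ia[a];
      bool any = false;
      for (int b = 0; b < B; ++b) {
        const int j = ib[b];
        const double dx = mi(x[i] - x[j], L, hL);
        if (std::fabs(dx) >= t) continue;
        const double dy = mi(y[i] - y[j], L, hL);
        const double dz = mi(z[i] - z[j], L, hL);
        if (dx * dx + dy * dy + dz * dz < t2) {
          ++counts(a, b);
          any = true;
        }
      }
      if (any) ++bound_obs;
    }
  }
  return List::create(_["counts"] = counts,
                      _["bound_obs"] = (double)bound_obs,
                      _["n_obs"] = (double)A * S);
}

//' @noRd
// [[Rcpp::export(name = ".rg_series_cpp")]]
NumericVector rg_series_cpp(NumericVector snaps, IntegerVector chain_idx,
                            double L) {
  int n, S;
  snap_dims(snaps, n, S);
  const int K = chain_idx.size();
  if (K < 2) stop("need at least two chain particles");
  const double hL = 0.5 * L;
  std::vector<int> id(K);
  for (int k = 0; k < K; ++k) {
    id[k] = chain_idx[k] - 1;
    if (id[k] < 0 || id[k] >= n) stop("index out of range");
  }
  NumericVector out(S);
  std::vector<double> ux(K), uy(K), uz(K);
  for (int s = 0; s < S; ++s) {
    const double* x = &snaps[(R_xlen_t)s * n * 3];
    const double* y = x + n;
    const double* z = y + n;
    ux[0] = x[id[0]]; uy[0] = y[id[0]]; uz[0] = z[id[0]];
    for (int k = 1; k < K; ++k) {
      ux[k] = ux[k - 1] + mi(x[id[k]] - x[id[k - 1]], L, hL);
      uy[k] = uy[k - 1] + mi(y[id[k]] - y[id[k - 1]], L, hL);
      uz[k] = uz[k - 1] + mi(z[id[k]] - z[id[k - 1]], L, hL);
    }
    double mx = 0, my = 0, mz = 0;
    for (int k = 0; k < K; ++k) { mx += ux[k]; my += uy[k]; mz += uz[k]; }
    mx /= K; my /= K; mz /= K;
    double s2 = 0;
    for (int k = 0; k < K; ++k) {
      const double dx = ux[k] - mx, dy = uy[k] - my, dz = uz[k] - mz;
      s2 += dx * dx + dy * dy + dz * dz;
    }
    out[s] = std::sqrt(s2 / K);
  }
  return out;
}
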