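#include <Rcpp.h>
using namespace Rcpp;

// Discretized Gaussian linking integral between a backbone loop closed by the
// native contact (i, j) and each terminal tail. The chain of N Calpha positions
// is reduced to N-1 segments with midpoints R_l = (r_l + r_{l+1})/2 and bond
// vectors dR_l = r_{l+1} - r_l; the double sum
//   g = (1/4pi) sum_m sum_n (R_m - R_n) / |R_m - R_n|^3 . (dR_m x dR_n)
// runs over tail segments m and loop segments n = i .. j-1. The N-tail uses
// m = 6 .. i-5 and the C-tail m = j+6 .. N-5 (1-based segment indices); an
// empty range contributes exactly 0.

static inline double seg_pair_term(const double* R, const double* dR,
                                   int m, int n, int M) {
  const double dx = R[m] - R[n];
  const double dy = R[m + M] - R[n + M];
  const double dz = R[m + 2 * M] - R[n + 2 * M];
  const double r2 = dx * dx + dy * dy + dz * dz;
  if (r2 < 1e-12) return 0.0;
  const double inv_r3 = 1.0 / (r2 * std::sqrt(r2));
  const double ax = dR[m], ay = dR[m + M], az = dR[m + 2 * M];
  const double bx = dR[n], by = dR[n + M], bz = dR[n + 2 * M];
  const double cx = ay * bz - az * by;
  const double cy = az * bx - ax * bz;
  const double cz = ax * by - ay * bx;
  return (dx * cx + dy * cy + dz * cz) * inv_r3;
}

static void midpoints_bonds(const NumericMatrix& ca, std::vector<double>& R,
                            std::vector<double>& dR) {
  const int N = ca.nrow();
  const int M = N - 1;
  R.resize(3 * M);
  dR.resize(3 * M);
  for (int l = 0; l < M; ++l) {
    for (int k = 0; k < 3; ++k) {
      R[l + k * M] = 0.5 * (ca(l, k) + ca(l + 1, k));
      dR[l + k * M] = ca(l + 1, k) - ca(l, k);
    }
  }
}

// Sum over one tail range [m_lo, m_hi] (1-based segment indices, inclusive)
// against loop segments [i, j-1].
static double tail_sum(const std::vector<double>& R, const std::vector<double>& dR,
                       int M, int m_lo, int m_hi, int i, int j) {
  if (m_lo > m_hi) return 0.0;
  double s = 0.0;
  for (int m = m_lo; m <= m_hi; ++m)
    for (int n = i; n <= j - 1; ++n)
      s += seg_pair_term(R.data(), dR.data(), m - 1, n - 1, M);
  return s / (4.0 * M_PI);
}

// [[Rcpp::export]]
NumericVector cpp_gauss_link(NumericMatrix ca, int i, int j) {
  const int N = ca.nrow();
  if (i < 1 || j > N || i >= j) stop("loop indices must satisfy 1 <= i < j <= N");
  std::vector<double> R, dR;
  midpoints_bonds(ca, R, dR);
  const int M = N - 1;
  double gN = tail_sum(R, dR, M, 6, i - 5, i, j);
  double gC = tail_sum(R, dR, M, j + 6, N - 5, i, j);
  return NumericVector::create(_["gN"] = gN, _["gC"] = gC);
}

// [[Rcpp::export]]
NumericMatrix cpp_gauss_link_batch(NumericMatrix ca, IntegerMatrix loops) {
  const int N = ca.nrow();
  const int M = N - 1;
  std::vector<double> R, dR;
  midpoints_bonds(ca, R, dR);
  const int L = loops.nrow();
  NumericMatrix out(L, 2);
  for (int l = 0; l < L; ++l) {
    const int i = loops(l, 0), j = loops(l, 1);
    if (i < 1 || j > N || i >= j) stop("invalid loop row %d", l + 1);
    out(l, 0) = tail_sum(R, dR, M, 6, i - 5, i, j);
    out(l, 1) = tail_sum(R, dR, M, j + 6, N - 5, i, j);
  }
  colnames(out) = CharacterVector::create("gN", "gC");
  return out;
}

// Cumulative partial linking along one tail: entry t is the linking value
// after including tail segments up to the t-th segment of the range
// (N-tail: 6..i-5 in increasing order; C-tail: j+6..N-5 in increasing order).
// [[Rcpp::export]]
NumericVector cpp_partial_profile(NumericMatrix ca, int i, int j,
                                  std::string terminus) {
  const int N = ca.nrow();
  const int M = N - 1;
  std::vector<double> R, dR;
  midpoints_bonds(ca, R, dR);
  int m_lo, m_hi;
  if (terminus == "N") { m_lo = 6; m_hi = i - 5; }
  else if (terminus == "C") { m_lo = j + 6; m_hi = N - 5; }
  else stop("terminus must be 'N' or 'C'");
  if (m_lo > m_hi) return NumericVector(0);
  const int T = m_hi - m_lo + 1;
  NumericVector prof(T);
  IntegerVector segs(T);
  double acc = 0.0;
  for (int t = 0; t < T; ++t) {
    const int m = m_lo + t;
    double s = 0.0;
    for (int n = i; n <= j - 1; ++n)
      s += seg_pair_term(R.data(), dR.data(), m - 1, n - 1, M);
    acc += s / (4.0 * M_PI);
    prof[t] = acc;
    segs[t] = m;
  }
  prof.attr("segment") = segs;
  return prof;
}

// Minimum heavy-atom distance contact map from atom coordinates grouped by
// residue. resid: 1-based residue index per atom, sorted by residue.
// Returns rows (i, j, min_dist) with |i-j| > min_seq_sep and min_dist <= cutoff.
// [[Rcpp::export]]
NumericMatrix cpp_contact_map(NumericMatrix xyz, IntegerVector resid,
                              double cutoff, int min_seq_sep) {
  const int A = xyz.nrow();
  if (A == 0) stop("empty structure");
  int N = 0;
  for (int a = 0; a < A; ++a) N = std::max(N, resid[a]);
  // atom index ranges per residue
  std::vector<int> lo(N, A), hi(N, -1);
  for (int a = 0; a < A; ++a) {
    const int r = resid[a] - 1;
    lo[r] = std::min(lo[r], a);
    hi[r] = std::max(hi[r], a);
  }
  const double c2 = cutoff * cutoff;
  std::vector<double> out;
  for (int i = 0; i < N; ++i) {
    if (hi[i] < 0) continue;
    for (int j = i + min_seq_sep + 1; j < N; ++j) {
      if (hi[j] < 0) continue;
      double best = R_PosInf;
      for (int a = lo[i]; a <= hi[i]; ++a)
        for (int b = lo[j]; b <= hi[j]; ++b) {
          const double dx = xyz(a, 0) - xyz(b, 0);
          const double dy = xyz(a, 1) - xyz(b, 1);
          const double dz = xyz(a, 2) - xyz(b, 2);
          const double d2 = dx * dx + dy * dy + dz * dz;
          if (d2 < best) best = d2;
        }
      if (best <= c2) {
        out.push_back(i + 1);
        out.push_back(j + 1);
        out.push_back(std::sqrt(best));
      }
    }
  }
  const int nrow = out.size() / 3;
  NumericMatrix res(nrow, 3);
  for (int r = 0; r < nrow; ++r)
    for (int k = 0; k < 3; ++k) res(r, k) = out[3 * r + k];
  colnames(res) = CharacterVector::create("i", "j", "min_dist");
  return res;
}
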