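#include <Rcpp.h>
using namespace Rcpp;

// Shrake-Rupley solvent-accessible surface area. Test points are placed on
// each expanded sphere (radius + probe) with a deterministic golden-spiral
// lattice; a point is accessible if it lies outside every neighbouring
// expanded sphere. Area = 4*pi*R^2 * accessible fraction.

// [[Rcpp::export]]
NumericVector cpp_sasa(NumericMatrix xyz, NumericVector radii,
                       double probe, int n_points) {
  const int n = xyz.nrow();
  NumericVector area(n);
  if (n == 0) return area;
  // golden spiral unit sphere points
  std::vector<double> px(n_points), py(n_points), pz(n_points);
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int p = 0; p < n_points; ++p) {
    const double z = 1.0 - 2.0 * (p + 0.5) / n_points;
    const double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    const double th = golden * p;
    px[p] = r * std::cos(th);
    py[p] = r * std::sin(th);
    pz[p] = z;
  }
  std::vector<double> R(n);
  double Rmax = 0.0;
  for (int i = 0; i < n; ++i) {
    R[i] = radii[i] + probe;
    Rmax = std::max(Rmax, R[i]);
  }
  std::vector<int> nb;
  for (int i = 0; i < n; ++i) {
    nb.clear();
    const double reach = R[i] + Rmax;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = xyz(j, 0) - xyz(i, 0);
      const double dy = xyz(j, 1) - xyz(i, 1);
      const double dz = xyz(j, 2) - xyz(i, 2);
      if (dx * dx + dy * dy + dz * dz < reach * reach) nb.push_back(j);
    }
    int acc = 0;
    for (int p = 0; p < n_points; ++p) {
      const double qx = xyz(i, 0) + R[i] * px[p];
      const double qy = xyz(i, 1) + R[i] * py[p];
      const double qz = xyz(i, 2) + R[i] * pz[p];
      bool free_pt = true;
      for (int j : nb) {
        const double dx = qx - xyz(j, 0);
        const double dy = qy - xyz(j, 1);
        const double dz = qz - xyz(j, 2);
        if (dx * dx + dy * dy + dz * dz < R[j] * R[j]) {
          free_pt = false;
          break;
        }
      }
      if (free_pt) ++acc;
    }
    area[i] = 4.0 * M_PI * R[i] * R[i] * acc / n_points;
  }
  return area;
}
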