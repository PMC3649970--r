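#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Shrake-Rupley numerical solvent accessible surface area.
// xyz: n x 3 coordinates (Angstrom); radii: van der Waals radii; probe:
// solvent probe radius; pts: m x 3 unit sphere sampling directions
// (deterministic quasi-uniform set supplied from R).
// Returns per-atom accessible area in Angstrom^2.
// [[Rcpp::export]]
NumericVector sasa_cpp(NumericMatrix xyz, NumericVector radii,
                       double probe, NumericMatrix pts) {
  const int n = xyz.nrow();
  const int m = pts.nrow();
  NumericVector area(n);
  std::vector<int> nbr;
  nbr.reserve(128);

  for (int i = 0; i < n; ++i) {
    const double Ri = radii[i] + probe;
    const double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2);

    nbr.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double Rj = radii[j] + probe;
      double dx = xyz(j, 0) - xi, dy = xyz(j, 1) - yi, dz = xyz(j, 2) - zi;
      double cut = Ri + Rj;
      if (dx * dx + dy * dy + dz * dz < cut * cut) nbr.push_back(j);
    }

    int acc = 0;
    for (int k = 0; k < m; ++k) {
      double px = xi + Ri * pts(k, 0);
      double py = yi + Ri * pts(k, 1);
      double pz = zi + Ri * pts(k, 2);
      bool buried = false;
      for (size_t q = 0; q < nbr.size(); ++q) {
        int j = nbr[q];
        double Rj = radii[j] + probe;
        double dx = px - xyz(j, 0), dy = py - xyz(j, 1), dz = pz - xyz(j, 2);
        if (dx * dx + dy * dy + dz * dz < Rj * Rj) { buried = true; break; }
      }
      if (!buried) ++acc;
    }
    area[i] = 4.0 * M_PI * Ri * Ri * (double)acc / (double)m;
  }
  return area;
}
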