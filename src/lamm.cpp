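#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Bernoulli function B(x) = x / (exp(x) - 1), the Scharfetter-Gummel
// exponential-fitting weight. Stable for |x| small and large.
static inline double bern(double x) {
  if (std::fabs(x) < 1e-10) return 1.0 - 0.5 * x;
  if (x > 700.0) return 0.0;            // exp overflow guard; limit is 0
  if (x < -700.0) return -x;            // B(-inf) ~ -x
  return x / std::expm1(x);
}

// Solve the Lamm equation
//   dc/dt = (1/r) d/dr [ r D dc/dr - s w^2 r^2 c ]
// on [rm, rb] with zero-flux ends, by a conservative finite-volume scheme
// with Scharfetter-Gummel (exponentially fitted) face fluxes and
// Crank-Nicolson time stepping.  Initial condition: uniform c = 1.
//
// Returns an n_times x n_cells matrix of cell-centre concentrations.
// [[Rcpp::export]]
NumericMatrix lamm_solve_cpp(double rm, double rb, int n_cells,
                             double s, double D, double omega,
                             NumericVector times, double dt_max) {
  const int n = n_cells;
  const int nt = times.size();
  const double h = (rb - rm) / n;

  std::vector<double> rc(n), rf(n + 1);
  for (int i = 0; i < n; ++i) rc[i] = rm + (i + 0.5) * h;
  for (int j = 0; j <= n; ++j) rf[j] = rm + j * h;

  // Face transport coefficients: flux across interior face j (between cells
  // j-1 and j, 1-indexed faces 1..n-1):
  //   J_j = (D/h) * ( Bm_j * c_left - Bp_j * c_right ),  v_j = s w^2 r_f
  // In the D -> 0 limit this reduces to upwind advection v * c_left.
  std::vector<double> Bm(n + 1, 0.0), Bp(n + 1, 0.0);
  for (int j = 1; j < n; ++j) {
    double v = s * omega * omega * rf[j];
    if (D > 0.0) {
      double P = v * h / D;
      Bm[j] = (D / h) * bern(-P);
      Bp[j] = (D / h) * bern(P);
    } else {
      Bm[j] = (v > 0.0) ? v : 0.0;
      Bp[j] = (v > 0.0) ? 0.0 : -v;
    }
  }

  // Tridiagonal operator A with A c giving dc/dt (zero-flux boundaries):
  // d c_i/dt = -( rf_{i+1} J_{i+1} - rf_i J_i ) / (rc_i h)
  std::vector<double> lo(n, 0.0), di(n, 0.0), up(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double w = 1.0 / (rc[i] * h);
    if (i > 0) {                 // flux in across left face i
      lo[i] += w * rf[i] * Bm[i];
      di[i] -= w * rf[i] * Bp[i];
    }
    if (i < n - 1) {             // flux out across right face i+1
      di[i] -= w * rf[i + 1] * Bm[i + 1];
      up[i] += w * rf[i + 1] * Bp[i + 1];
    }
  }

  NumericMatrix out(nt, n);
  std::vector<double> c(n, 1.0), rhs(n), cp(n), dp(n);

  double t_now = 0.0;
  for (int k = 0; k < nt; ++k) {
    double t_target = times[k];
    if (t_target < t_now - 1e-9) stop("scan times must be non-decreasing");
    double span = t_target - t_now;
    if (span > 1e-12) {
      int nsub = (int)std::ceil(span / dt_max);
      if (nsub < 1) nsub = 1;
      double dt = span / nsub;
      // Crank-Nicolson matrices: M1 = I - dt/2 A (solve), M2 = I + dt/2 A
      std::vector<double> l1(n), d1(n), u1(n);
      for (int i = 0; i < n; ++i) {
        l1[i] = -0.5 * dt * lo[i];
        d1[i] = 1.0 - 0.5 * dt * di[i];
        u1[i] = -0.5 * dt * up[i];
      }
      for (int step = 0; step < nsub; ++step) {
        // rhs = (I + dt/2 A) c
        for (int i = 0; i < n; ++i) {
          double v = (1.0 + 0.5 * dt * di[i]) * c[i];
          if (i > 0) v += 0.5 * dt * lo[i] * c[i - 1];
          if (i < n - 1) v += 0.5 * dt * up[i] * c[i + 1];
          rhs[i] = v;
        }
        // Thomas algorithm
        cp[0] = u1[0] / d1[0];
        dp[0] = rhs[0] / d1[0];
        for (int i = 1; i < n; ++i) {
          double m = d1[i] - l1[i] * cp[i - 1];
          cp[i] = (i < n - 1) ? u1[i] / m : 0.0;
          dp[i] = (rhs[i] - l1[i] * dp[i - 1]) / m;
        }
        c[n - 1] = dp[n - 1];
        for (int i = n - 2; i >= 0; --i) c[i] = dp[i] - cp[i] * c[i + 1];
      }
      t_now = t_target;
    }
    for (int i = 0; i < n; ++i) out(k, i) = c[i];
  }
  return out;
}
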